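gene	s1	s2
ATM	0.91	-0.64
TP53	1.42	-1.05
CDKN1A	0.77	-0.88
MDM2	0.35	-0.41
CDK2	-0.52	0.47
RB1	0.61	-0.39
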