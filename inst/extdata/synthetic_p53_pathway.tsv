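source	target	sign
ATM	TP53	activation
TP53	CDKN1A	activation
TP53	MDM2	activation
MDM2	TP53	inhibition
CDKN1A	CDK2	inhibition
CDK2	RB1	inhibition
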