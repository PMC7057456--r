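---
title: "Scoring pathway routes with chain Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pathway routes with chain Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routescore)
```

## The problem

Curated pathway maps encode *directed, signed* prior knowledge: gene A
activates B, B inhibits C. Given per-sample expression calls (up, down,
missing) and optional mutation calls (function gain, function loss), we want
to know which *routes* — simple directed paths — through a pathway the data
supports as activated or suppressed, and to aggregate route-level evidence
into pathway-level scores with a calibrated false-discovery guarantee.
Working at route resolution, rather than gene-set resolution, is what lets
the method report *where* in the pathway the perturbation propagates.

## The route model

A route of `w` genes becomes a chain Bayesian network: expression variables
$R_1 \dots R_w$, mutation variables $M_1 \dots M_{w-1}$, a uniform prior on
the root expression and on every unobserved mutation, and one conditional
probability table per edge. For an activation edge the table is

| $M_i$ | $R_i$ | $P(R_j{=}{+1})$ | $P(R_j{=}{-1})$ |
|------:|------:|-----------------:|-----------------:|
| +1 | +1 | $1-\varepsilon$ | $\varepsilon$ |
| −1 | +1 | $\gamma$ | $1-\gamma$ |
| +1 | −1 | $1-\gamma$ | $\gamma$ |
| −1 | −1 | $\varepsilon$ | $1-\varepsilon$ |

and the inhibition table swaps the two output columns. Two properties drive
everything downstream: mutation evidence dominates expression when the two
conflict (the $\gamma$ rows), and with no mutation information the marginal
transition $P(R_j{=}{+1} \mid R_i{=}{+1}) = (1+\gamma-\varepsilon)/2$
exceeds $1/2$ exactly because $\gamma > \varepsilon$ — consistent
propagation is always favoured, which forces both the uniform mutation prior
and the ordering constraint $\varepsilon < \gamma < 0.5$.

The route score normalizes the evidence probability by the probability of
the *consistent pseudo-observation*: same pattern of available data, values
replaced by the configuration obtained by anchoring the first observed gene
at its observed state and propagating through the edge signs (observed
mutations are set to the consistent expression of their gene). Missing
expression values and unobserved mutations are summed out identically in the
numerator and the denominator. This reading was chosen deliberately among
the possible interpretations of "probability that the data are consistent":
it is the one under which (a) a fully consistent observation scores exactly
1, and (b) with complete matching mutation evidence the score collapses to
the closed form $(\varepsilon/(1-\varepsilon))^K$ with $K$ the number of
inconsistent edges — both of which the test suite asserts, the second to
$10^{-9}$ over 500 random fixtures. Normalizing instead against the
consistent assignment *under the observed mutation values* breaks (b) as
soon as an interior gene is flipped, which is why we did not adopt it.

```{r score-example}
rt  <- route(c("A", "B", "C"), c(1L, -1L))     # A -> B -| C
hp  <- hyperparams(epsilon = 0.1, gamma = 0.25)
obs <- sample_observation("s", c(A = 1L, B = 1L, C = -1L))
route_score(rt, obs, hp)          # consistent: 1
signed_score(rt, obs, hp)         # +1: activated
obs2 <- sample_observation("s", c(A = 1L, B = 1L, C = 1L),
                           m = c(A = 1L, B = 1L, C = 1L))
route_score(rt, obs2, hp)         # one inconsistent edge: eps/(1-eps)
```

The signed score reads its direction off the *last observed* gene against
the state propagated from a `+1` root; trailing missing genes are skipped
rather than aborting the route (they change neither score nor direction,
because the unobserved tail sums to one in both numerator and denominator).
A consistent but globally down-regulated route therefore scores −1, the
"suppressed" label.

## Numerical choices

Scores are evaluated by a two-state forward recursion with per-step
rescaling (the standard trick from hidden-Markov likelihoods), so routes of
any practically enumerable length stay away from underflow; the score is the
exponential of the difference of the two accumulated log masses, and
identical code paths for numerator and denominator make the consistent case
*exactly* 1 in floating point. All threshold comparisons (score cutoffs, the
pass indicator at `t`) use an absolute tolerance of `1e-9` so boundary cases
like $0.8^1 \ge 0.8$ are decided consistently. Fewer than two observed genes
on a route make the score undefined; such routes raise a typed condition and
are skipped (and counted) during discovery.

## Route discovery

`get_routes()` runs a depth-first search from a start gene, rescoring at
each extension and emitting every qualifying sub-segment independently: the
terminal condition is "last observed gene matches (activated) or
anti-matches (suppressed) the propagated state, and score ≥ cutoff". The
default cutoff of 1 recovers the strict only-fully-consistent behaviour; the
cutoff is exposed because scores meaningfully close to 1 (a single tolerated
error) are often wanted. Because extension can never raise a score, branches
are pruned once the running score drops below `cutoff × ε/(1−ε)`; the suite
checks the emitted set equals a brute-force pass over all simple paths.
Routes are *simple paths only*: KEGG maps contain feedback cycles (our
synthetic `cyclic` topology reproduces this), and forbidding node revisits
is what keeps exhaustive enumeration finite. Enumeration is capped at
`max_len = 12` genes by default — exhaustive simple-path extraction is
exponential in dense graphs — and per-start searches are independent, so the
result is invariant to traversal order and trivially shardable.

## Pathway aggregation and significance

The pathway score is the length-weighted fraction of routes whose mean
unsigned score across samples reaches `t`; length weighting reflects that a
long consistent route is rarer, hence stronger, evidence than a short one.
Under the fair-coin null the probability that a `w`-gene route is fully
consistent is $0.5^{w-1}$ (two consistent assignments among $2^w$), so the
number of passing routes is Poisson-binomial across the `k` routes; we
report the binomial approximation $\mathrm{Binom}(k, \mu/k)$ evaluated at
the observed count, with $\mu$ the Poisson-binomial mean. Taking the
binomial size parameter to be `k` is the only choice that matches the
approximation's mean to $\mu$; the approximation is exact when route lengths
are equal and the suite bounds its total-variation error at mild
heterogeneity. Two printed-as-is conventions worth knowing: the reported
value is a point mass, not a tail (an upper-tail variant is exposed via
`upper_tail = TRUE`), and $\mu$ multiplies the *data-independent* per-route
null probability over samples. Both are exposed knobs rather than silent
choices.

## Calibrating ε and γ

Under the null each edge is inconsistent with probability $1/2$, so
$K \sim \mathrm{Binom}(n_{\text{edges}}, 1/2)$ and the reduced score reaches
`t` only when $K$ is small. Requiring
$P(\text{score} \ge t) < \alpha$ yields the bound
$\varepsilon \le B(t, \alpha) = 1 - 1/(1 + t^{1/q_\alpha})$, with $q_\alpha$
the lower-tail quantile of $K$. We default to the **exact** binomial
quantile (largest $q$ with CDF $\le \alpha$) rather than the normal
approximation: at 9 edges and $\alpha = 0.05$ the normal quantile admits
$K \le 2$, an event of null probability $46/512 \approx 9\%$ — a level
violation the exact quantile avoids ($10/512 \approx 2\%$); the test suite
demonstrates this discrepancy. Edge cases are handled as the mathematics
dictates: at `t = 1` only $K = 0$ routes can qualify regardless of ε
(strict regime), and for routes so short that even $K = 0$ is likelier than
α there is no valid quantile and the static default ε = 0.1, γ = 0.25 — a
setting known to behave well — is used with a warning. γ is the midpoint
$(\varepsilon + 0.5)/2$ of its admissible interval. Calibration is
per-route-length by default (the bound depends on the edge count);
`pathway_score(..., hp_fun =)` and the CLI wire this through, and a single
pathway-level setting can be forced by passing static ε/γ.

```{r calibration}
calibrate(10)                       # 9 edges: epsilon = 4/9
null_exceedance(n_edges = 9, seed = 1)$exceedance
```

## What the synthetic generator does and does not emulate

The fixture module generates chain/tree/dag/cyclic topologies with a
configurable activation fraction (default 0.7, signaling maps being mostly
activating), and observations built from a route's consistent pattern with
independent child flips (default rate 0.1, the error rate the model
tolerates), missing masking (default 0.1), and optional mutation evidence.
The generator records the ground-truth inconsistent-*edge* count: flipping
two adjacent genes leaves their connecting edge consistent, so flipped-gene
and inconsistent-edge counts differ by design, and the recorded `k_true` is
the edge-level truth that the scorer must recover. All generators are pure
functions of their seed, with per-sample seeds derived by offset so adding
samples never changes existing ones. What is *not* simulated: continuous
intensity distributions, normalization artefacts, correlated noise between
neighbouring genes, or realistic mutation spectra — the model consumes signs
only, so passing tests establish correctness of the probabilistic machinery
on its own terms, not robustness of upstream discretization choices on real
microarray or RNA-seq data (log-ratio discretization maps positive to +1,
negative to −1, and exactly-zero or absent to missing; genes to be excluded,
e.g. non-significant ones, should be pre-filtered to NA by the caller).

## Problem sizes used by the test suite

Oracle equivalences run on graphs of ≤ 8 nodes (50 random graphs for
enumeration), exhaustive joint-probability enumeration on routes of ≤ 6
genes, the consistency criterion on 200 routes of 2–12 genes, the
reduced-score identity on 500 fixtures, and the calibration guarantee on
10,000 Monte-Carlo replicates of 9-edge null routes — sizes chosen so each
oracle is literally exhaustive or has negligible Monte-Carlo error while the
whole suite stays interactive.

## Known limitations

KGML entries of type compound or map are ignored (gene regulation only), no
identifier mapping beyond upper-casing is attempted, and conflicting
duplicate signed relations in a KGML file are resolved first-wins with a
warning (the edge-list loader, whose input is user-authored, treats the same
situation as an error). Routes are scored independently: overlapping routes
share evidence, so pathway-level significance should be read as a ranking
device, not a family-wise error rate. The binomial approximation degrades
when route lengths are very heterogeneous; `poisson_binomial_pmf()` provides
the exact distribution when `k` is small enough to care.
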