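---
title: "Models and methods: social influence and social selection on socio-centric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social influence and social selection on socio-centric networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcontagion)
```

## The scientific problem

A binary practice preference — here framed as pro/anti attitudes toward a
sensitive cultural practice, elicited from an approximately complete adult
census of nine neighbouring administrative zones — may cluster on social
networks for two distinct reasons: **social influence** (people become
similar to their contacts; "contagion") or **social selection** (people
choose contacts who are already similar; homophily).  Cross-sectional data
cannot separate the two mechanisms within a single network, so the analysis
assigns each mechanism to the relationship types where it is theoretically
plausible: contagion is assessed in chatting, respect and money-borrowing
networks with an autologistic actor-attribute model (ALAAM), and selection
is assessed in the (largely hypothetical) marriage-advice network with a
combined stochastic block and social relations model.  Two of the
relationship types are *double-sampled* — elicited from both sides ("who
would you go to" / "who would come to you") — and are first reconciled into
a latent directed network.  Every stage is exercised end-to-end on
synthetic data with known ground truth; nothing in this package requires
the restricted field data.

## The ALAAM

The attribute vector $y \in \{0,1\}^n$ on a fixed directed network $X$
follows the exponential-family distribution

$$P(y) \propto \exp\{\theta^\top s(y)\},$$

where $s(y)$ stacks: the intercept statistic $\sum_i y_i$; out-degree
*activity* and in-degree *popularity* statistics (the lower-order effects
required by the hierarchy principle when contagion terms are present);
covariate main effects $\sum_i y_i c_i$; and contagion statistics built on
the symmetrized tie indicator $x^+_{ij} = \max(x_{ij}, x_{ji})$.  The
direct contagion statistic is $\sum_{i<j} y_i y_j x^+_{ij}$.  Four further
variants are available: *reciprocal* ($x_{ij} x_{ji} = 1$), *indirect*
(untied pairs joined by a two-path), *closed indirect* (tied pairs joined
by a two-path), and *transitive* (fully tied triads with all three members
positive).  Symmetrization is used for every contagion statistic because
the pair sum runs over unordered pairs; directed variants would double
count.  The model implies conditional dependence of $y_i, y_j$ exactly
when the pair is tied.

Three computational layers are provided and validated against each other:

- `alaam_exact()` enumerates all $2^n$ states ($n \le 15$) — the oracle;
- `alaam_simulate()` runs a systematic-scan Gibbs sampler whose stationary
  moments are checked against the enumeration;
- `alaam()` samples the doubly-intractable posterior with the exchange
  algorithm: a proposed $\theta'$ is accompanied by an auxiliary draw $y'$
  from the model at $\theta'$, and the acceptance ratio
  $\exp\{(\theta'-\theta)^\top(s(y_{\mathrm{obs}}) - s(y'))\}$ times the
  prior ratio cancels the normalizing constants.

Numerical choices: Gaussian priors $N(0, 5^2)$ on every coefficient;
auxiliary chains of 50 full Gibbs sweeps initialized at the observed
vector (the key approximation knob — we verified on $n = 200$ test
problems that results are indistinguishable from 400-sweep auxiliaries);
an adaptive multivariate random-walk proposal whose empirical-covariance
shape and $2.38/\sqrt{p}$ scaling are frozen after burn-in, preserving
detailed balance for retained draws; zone entering as fixed-effect
indicators against the largest zone.  The exchange posterior was checked
against an exact grid-enumeration posterior on an 8-node fixture
(Kullback–Leibler divergence of the discretized contagion marginal below
0.05).  Posterior summaries report the median, the central 95% interval
and the proportion of draws above zero, the quantity used to read
contagion strength.

A caveat established with the synthetic generator: because the direct
contagion statistic is positively correlated with the degree statistics
that the hierarchy principle requires as controls, the adjusted contagion
coefficient is mildly shrunk toward zero relative to its generating value
(on $n = 500$ single-zone problems, posterior medians average roughly 0.40
when fitting without degree controls and 0.34 with them, for a generating
value of 0.5).  A related interplay arises with zone fixed effects: on
networks whose ties are almost entirely within-zone, contagion-induced
clustering materializes partly as between-zone prevalence dispersion,
which zone indicators absorb.  The parameter-recovery experiments
therefore use a single-zone design, where the contagion coefficient is
identified from tie-level concordance alone; multi-zone fits remain fully
supported, and the adjustment set mirrors the field design, but recovered
contagion coefficients there should be read as conservative.

## Latent networks from double-sampled reports

For a double-sampled generator, each ordered pair $(i, j)$ carries a
latent tie $Y_{ij}$; a dyad prior
$P(y_{ij}, y_{ji}) \propto \exp\{a (y_{ij} + y_{ji}) + m\, y_{ij} y_{ji}\}$
combines a network density log-odds $a$ — estimated, with a Gaussian
prior centred at $\mathrm{logit}(0.005)$ (SD 2) — and a mutuality
log-odds $m$ with an $N(0, 3^2)$ prior.  Estimating the density matters:
fixing $a$ below the network's true density systematically deflates the
posterior tie probability of half-confirmed pairs and can push them
under the binarization threshold.  Each
eligible reporter's statement about a pair — the out-side reporter for
$(i,j)$ is $i$, the in-side reporter is $j$ — is Bernoulli($\lambda_1$) if
the tie exists and Bernoulli($\lambda_0$) otherwise, with Beta(9, 1) and
Beta(1, 99) priors respectively, shared across reporters (per-reporter
rates are not identified at the sample sizes we target).  Gibbs sampling
alternates dyad states (jointly over the four configurations), conjugate
rate updates, and a random-walk update for $m$.  Pairs observable by both
endpoints are thereby weighted by both statements; pairs observable by
neither revert to the prior.  Two fitting scopes are provided: over the
full roster, and over reporters only.

The mutuality estimate is defined concretely as
$\eta_{\mathrm{est}} = E[\,P(Y_{ji} = 1 \mid Y_{ij} = 1)\,]
= E[\,\mathrm{logit}^{-1}(a + m)\,]$ over the posterior — the published
threshold rule takes $\eta$ from a different estimator whose internals we
do not reproduce, so we fix this testable definition.  Binarization
declares a tie where $\rho_{ij} > t_\rho$ with
$t_\rho = 0.33\,\eta_{\mathrm{est}} + 0.10$ (strict inequality; the rule's
endpoints are 0.10 at $\eta = 0$ and 0.43 at $\eta = 1$).  The posterior
$\rho$ was validated against a complete $2^{12}$ enumeration on a 4-node
fixture.  In the degenerate noiseless limit ($\lambda_1 = 1, \lambda_0 =
0$) a pair reported by one side and missed by the other is formally a
zero-probability event; the sampler resolves it in favour of the positive
report (a weaker numerical guard on the impossible miss than on the
impossible false positive), so the estimate converges to the union of
reports, which is the natural limit of the model as $\lambda_0 \to 0$
faster than $1 - \lambda_1$.

Against the deterministic baselines, the latent estimate dominates the
intersection (which discards every unconfirmed report) by a wide margin
of balanced accuracy.  Relative to the union, a structural finding from
the synthetic experiments deserves emphasis: when reporting error is
homogeneous — every reporter sharing one sensitivity and one
false-positive rate, as in our generator — a single positive report
carries identical likelihood whether the underlying tie is real or
spurious, so the posterior can separate the two only through the
mutuality coupling.  Recovering a tie that no reporter named, from its
confirmed reciprocal alone, requires conditional reciprocation of
roughly 0.75 or more under the threshold rule; at the advice network's
reciprocity of about 0.44 the thresholded latent network reproduces the
union's decisions exactly, and dropping below-threshold singleton
positives would always cost more sensitivity than the specificity it
buys (non-ties vastly outnumber ties).  The estimator's advantage over
the union therefore materializes with strongly reciprocal relations or
heterogeneous reporter reliability (the per-reporter extension), not in
the homogeneous-error regime, where matching the union while also
supplying calibrated tie probabilities and mutuality estimates is the
correct behaviour.

## The block + social relations model

Within one zone, the latent ordered-pair tie model is

$$\mathrm{logit}\, P(Y_{ij} = 1) = B^{\mathrm{pref}}[g_i, g_j] +
B^{\mathrm{gender}}[h_i, h_j] + \beta_F^\top x_i + \beta_T^\top x_j +
\beta_D^\top z_{ij} + s_i + r_j + d_{ij},$$

with bivariate-normal sender/receiver effects $(s_i, r_i)$ and dyad
effects $(d_{ij}, d_{ji})$ correlated within the dyad (dyadic
reciprocity).  The preference blocks are the model's target: a homophily
signal appears as a raised $B[\mathrm{pro}, \mathrm{pro}]$.  The block
indicator columns act as per-combination intercepts; because adding a
constant to all offsets and subtracting it from a global intercept leaves
the likelihood unchanged, the sampler works in the redundant
parameterization (proper under the $N(0, 2.5^2)$ priors) and reported
offsets are recentred to sum to zero per draw, with the mean playing the
role of the global intercept.  Contrasts are per-draw differences against
a reference combination (pro-to-pro by default), summarized by medians and
95% highest-posterior-density intervals; the reference's contrast with
itself is exactly zero by construction.

When fitted to raw double-sampled reports the latent $Y$ is estimated
jointly with a shared reporting sensitivity and false-positive rate
(Beta(9, 1) / Beta(1, 99) priors, conjugate updates), avoiding any
pre-estimation of the network; a pre-binarized network can be supplied
instead.  Random-effect SDs carry half-Normal(1) priors; correlations a
uniform prior via the $\tanh$ transform.  The sampler is
Metropolis-within-Gibbs with per-coordinate adaptive scales frozen after
burn-in.  Fits are run independently per zone (`fit_all_zones()`), with
undersized zones (< 10 reporting members) skipped and reported rather
than fatal.

The homophily-recovery experiment simulates one 80-member zone with a
+1.5 log-odds pro-to-pro block offset and checks that the pro-to-pro
offset's posterior median ranks highest.  The zone uses a 25% pro
prevalence: at the study's observed 1–12% zone prevalence an 80-member
zone holds only a handful of pro members and a few dozen pro-pro ordered
pairs, too few to order four block medians reliably; 25% keeps all four
combinations populated while remaining a realistic minority share.  The
population-scale generator keeps the study's 1–12% range.

## The synthetic-data generator

`sim_config()` defaults emulate the study conditions: nine zones of
unequal size totalling about 5,000 adults (the two printed zone sizes are
used exactly; the remainder are plausible interpolations), 49.3% of
respondents flagged as network reporters, up to ten nominations per
generator, four relationship layers with 95% within-zone ties,
layer-specific reciprocity (0.18 chatting, 0.03 respect, 0.42 money, 0.44
advice) and kin fractions, and zone-level preference prevalence spanning
1.4–12.1%, produced by zone-specific intercepts (the emulated study found
demographics do not explain the dispersion).  Reporting error is Bernoulli
per (reporter, alter) pair — sensitivity $\lambda_1 = 0.8$, false-positive
rate $\lambda_0 = 0.002$, false positives confined to the reporter's zone,
cap enforced by uniform subsampling.  No quantitative reporting-error rate
is available for the emulated survey, so the $\lambda$ defaults are fixture
choices, not estimates.  Under the influence regime the preference vector
is a Gibbs draw (1,000 sweeps) from the ALAAM at the configured contagion
coefficient; under the selection regime advice ties are drawn from the
block + social relations generative model; the null regime draws
independent Bernoulli outcomes.  Everything is deterministic given
(config, seed), with stage seeds derived by a fixed splitting rule
(`stage_seed()`).

What the generator deliberately does not emulate: name-to-census matching
failure (alters are exactly matched or absent), preference misreporting,
elicitation-order effects under the nomination cap, kin structure beyond
an exchangeable per-tie flag, and longitudinal tie dynamics.  Passing
recovery tests on this generator therefore demonstrates correctness of
the estimators under the stated measurement model, not robustness to
those field complications.

## Problem sizes and test design

The validation suite runs at sizes chosen to make each check sharp but
cheap: exact oracles at $n \le 12$ (enumeration, grid posteriors,
brute-force loops), ALAAM recovery and null calibration at $n = 500$ with
20 seeded replicates each (2,000 retained exchange iterations, 800
burn-in, 50-sweep auxiliaries), homophily recovery at one 80-member zone,
and latent-network recovery at $n = 300$ with roughly half the roster
reporting.  The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities from scratch at the same sizes, plus the descriptive
surface of a full study-scale simulation (~5,000 respondents).

## Known limitations

- ALAAM fits assume the network is exogenous and fixed; with
  cross-sectional data a contagion signal cannot be distinguished from
  selection operating on the same layer.  This is a design assumption
  inherited from the analysis the package implements.
- The adjusted contagion coefficient is conservative in the presence of
  degree controls and (in multi-zone fits) zone fixed effects, as
  quantified above.
- The latent-network model shares reporting rates across reporters and
  ignores the nomination cap's censoring; with ten allowed nominations
  and the low degrees targeted here the cap rarely binds.
- Per-zone homophily fits cannot see cross-zone ties, mirroring the
  field analysis; the measurement layer assumes reporting error is
  independent of preference.
- The block-SRM's latent-tie mode is weakly identified when the
  reporting false-positive rate and tie density are comparable; the
  informative Beta priors on the rates carry real weight there.
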