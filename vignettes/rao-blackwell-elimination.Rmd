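---
title: "Elimination trials with triangular boundaries and Rao-Blackwell estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elimination trials with triangular boundaries and Rao-Blackwell estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqelim)
```

## The model

Patients on treatment $T_i$ succeed independently with probability
$p_i$; effects are expressed as log-odds ratios
$\theta_{ij} = \log\{p_i(1-p_j)/(p_j(1-p_i))\}$. At each interim
analysis every pair of remaining arms is summarised by the efficient
score and Fisher information

$$Z_{ij} = \frac{n_j S_i - n_i S_j}{n_i + n_j}, \qquad
  V_{ij} = \frac{n_i n_j (S_i+S_j)(n_i+n_j-S_i-S_j)}{(n_i+n_j)^3},$$

computed within stratum and summed when the trial is stratified. For
small $\theta$, $E(Z) \approx \theta V$ and $\mathrm{var}(Z) \approx V$,
and $V$ never decreases as data accumulate, so $(V, Z)$ paths move
rightwards through a plane in which stopping rules can be drawn as
straight lines.

A pairwise rule (`pairwise_boundary()`) has an intercept $a$ and two
slopes: $T_i$ is declared better than $T_j$ when
$Z \ge a + b_{\text{outer}} V$ (worse when $Z \le -a - b_{\text{outer}}
V$), and the pair no different when $Z$ lies in the *open* interval
$(a - b_{\text{inner}} V,\; -a + b_{\text{inner}} V)$, which is nonempty
only once $V > a/b_{\text{inner}}$. Elimination comparisons are
inclusive, exactly as the rules are printed: $Z$ is a rational number,
so boundary equality can genuinely occur and must classify
deterministically. The one-sided variant (the classical triangular test
for an experimental-versus-control comparison) keeps only the upper
efficacy line and a rising lower "no better" line
$Z \le -a + b_{\text{inner}} V$; the two meet at
$V = 2a/(b_{\text{inner}} - b_{\text{outer}})$ (`boundary_geometry()`).

Three configurations ship as presets (`design_preset()`); their
constants are configuration, not logic — deriving them from error
requirements is out of scope.

| preset | arms | $a$ | $b_\text{outer}$ | $b_\text{inner}$ | per-arm increment | cap | interims |
|---|---|---|---|---|---|---|---|
| `four_arm_sepsis` | 4 | 10.90266 | 0.12380 | 0.37140 | 36 | 2772 | cap-bound |
| `two_arm_tri` | 2 | 10.93898 | 0.123134 | 0.369402 | 36 | 1800 | 20 (+5) |
| `four_arm_simple` | 4 | 4.9261 | 0.2470 | 0.7411 | 32 | 640 | 8 |

The four-arm rules are calibrated so that a truly tied arm is wrongly
declared sole winner with probability at most 0.025 and an arm inferior
by an odds ratio of 1.5 (2.25 for the smaller design) is eliminated with
probability at least 0.90. The per-arm increment of 36 comes from the
information increment $V = 4.40337$ per interim: for two equal arms,
$V \approx (n/2)\bar p(1-\bar p)$, giving $n = 35.58$ at success rates
of 0.40/0.50 (`implied_sample_increment()`), rounded up.

## The trial engine

`simulate_multiarm_trial()` advances the design interim by interim:
every remaining arm accrues its increment of binomial responses (split
multinomially with equal probabilities across centres when stratified),
all active pairs are classified on the same data, and **every arm found
worse than any other is eliminated simultaneously** — the elimination
rule quantifies over "any other" arm and states no sequencing, so arms
that are themselves eliminated at an interim can still eliminate others
at that interim. The trial stops with a sole winner when one arm
remains, with joint winners when every remaining pair is declared no
different, and otherwise continues until an interim analysis would push
the total past the cap (the check runs *before* accrual, so the cap is
never exceeded) or the interim limit is reached; both of these end the
trial `unresolved`, with the decision log retained so a caller can read
off any partial conclusions.

The two-arm engine records which boundary was crossed. Its lower
crossing means "the experimental arm is no better" — neither a winner
declaration nor an unresolved trial — so trial outcomes carry a fourth
kind, `no_better`, alongside `sole_winner`, `joint_winners` and
`unresolved`. Interim analyses continue past the 20 planned, up to 25,
while no boundary has been reached, covering realised information
increments that fall short of the anticipated 4.4419 per analysis.

The no-difference region has no memory: a pair inside it at one interim
simply continues if other comparisons are unresolved, and the region is
re-evaluated at the next interim. A pair with $V = 0$ (no pooled
successes or no pooled failures) classifies as `continue`: no
information, no decision. If, beyond the meeting point of the one-sided
boundaries, both stopping conditions held simultaneously, the efficacy
boundary takes precedence; this affects only pathological overshoot and
is fixed for determinism.

## Naive estimation and the comparison window

The unadjusted analysis takes $\hat\theta = Z^*/V^*$ with
$SE = 1/\sqrt{V^*}$ and interval $\hat\theta \pm 1.96\,SE$. The normal
quantile is fixed at 1.96 for fidelity to the worked examples; other
levels are available through the `z_crit` argument. After a multi-arm
trial two windows are available (`select_comparison_data()`): Option 1
uses all data on each arm; Option 2 restricts a pairwise comparison to
patients randomised while both arms were in contention, protecting it
from temporal drift. Option 2 counts are always dominated componentwise
by Option 1 counts.

## Reverse-simulation Rao-Blackwellisation (RB2)

The first-interim estimate $\hat\theta_1 = Z_1/V_1$ is unbiased because
no stopping rule has yet acted; its conditional expectation given the
terminal sufficient statistics keeps the unbiasedness and reduces
variance. The conditional distribution is sampled backwards
(`reverse_fill()`): for each arm and stratum independently, the
successes at interim $k$ given those at $k+1$ are hypergeometric — a
draw of $n_k$ from the $n_{k+1}$ responses of which $S_{k+1}$ are
successes. Arms eliminated earlier are anchored at their own final
analysis and back-filled from there.

Paths are then filtered (`consistency_mask()`) by replaying the decision
rule at every interim before the start: at the analysis where an arm was
actually eliminated, a replicate must reproduce every "better than"
conclusion the real data reached against that arm, and must not place
the arm on either elimination boundary against arms that did not defeat
it; at earlier analyses no pair may cross an elimination boundary; and
no replicate may imply a joint no-difference stop of the set of arms
that in fact continued. For the one-sided two-arm design this reduces to
the path staying strictly inside the continuation region before the
final analysis (the boundaries are inclusive stopping sets, so a
replicate *on* a boundary is deleted). The real trial's conclusions are
recomputed from the observed counts, so loaded histories need no stored
decision log. Under Option 2 each pair's reverse simulation starts at
the last analysis with both arms in contention; pairs sharing a start
share one replicate set, and Option 1 is the special case of a single
start at the final analysis.

Over the consistent replicates, $\tilde\theta$ is the mean of
$\hat\theta_1$ and

$$SE(\tilde\theta) = \sqrt{\overline{1/V_1} -
  \widehat{\mathrm{var}}(\hat\theta_1 \mid \text{data})}.$$

$V_1$ varies across replicates (it depends on the simulated counts), so
the first term uses the mean of $1/V_1$ over consistent replicates —
the natural Monte Carlo analogue, reducing to $1/V_1$ when $V_1$ is
constant. A negative radicand is reported as a missing SE with the
moment components exposed, never as a silent `NaN`. In the stratified
case the within-centre first-interim samples are small, and the
denominator of $\hat\theta_1$ (and the $1/V_1$ term) uses the
small-sample information $V' = V\,n/(n-1)$ (`adjusted_information()`):
$E(Z)$ is closer to $\theta V'$ than to $\theta V$ at these sizes, and
without the correction estimates are visibly biased and SEs sometimes
fail to exist. Consistency checking always uses the plain $V$, the
statistic the trial itself monitored.

Replicates are generated and filtered in chunks (default $10^5$) to
bound memory; a single seeded stream is consumed sequentially, chunk by
chunk, with draws ordered by arm, then stratum, then interim (backwards
from each anchor). Analyses with fewer than `min_complete` (default
1000) consistent replicates are flagged unreliable and excluded from
simulation aggregates. When the start *is* the first interim analysis,
conditioning is vacuous and the estimate is returned directly as
$Z_1/V_1$ with $SE = 1/\sqrt{V_1}$, exactly.

## The analytic two-arm method (RB1)

For the one-sided triangular test the conditional moments of $Z_1$ are
available analytically. Under the canonical group-sequential model the
score increments are independent normal with variance equal to the
information increment; the likelihood factor
$\exp(\theta z - \theta^2 V/2)$ cancels in the conditional ratio, so all
probabilities are evaluated at $\theta = 0$. With continuation limits
$(\ell_k, u_k)$ and the final continuation region pinched to
$(z_n - \delta z, z_n + \delta z)$, the survivor function
$S(t) = P(Z_1 > \ell_1 + t \mid K = n, Z_n)$ is a ratio of continuation
masses with the first region trimmed to $(\ell_1 + t, u_1)$, and

$$E(Z_1 - \ell_1 \mid \cdot) = \int_0^{u_1-\ell_1} S(t)\,dt, \qquad
  E\{(Z_1-\ell_1)^2 \mid \cdot\} = 2\int_0^{u_1-\ell_1} t\,S(t)\,dt.$$

`continuation_mass()` evaluates these by backward recursion of the
conditional crossing probability on a uniform grid per continuation
interval (default 400 points, trapezoidal convolution against the
normal increment density); one backward pass yields the whole survivor
curve. Defaults $\delta z = 0.01$ and a 100-interval $t$-grid
(`rb1_config()`) are validated by a grid-refinement test: doubling both
resolutions moves the estimate by under $10^{-3}$ on the worked
examples.

The information schedule matters. The package defaults to equal spacing
scaled to the realised terminal information, $V_i = i\,V^*/n$
(`v_schedule = "realized"`); this choice reproduces the published
analytic adjustments on all twelve two-arm worked runs to three
decimals, whereas the nominal schedule $V_i = i \times 4.4419$ (also
available) does so only when the realised terminal information happens
to sit near its anticipated value. The method does not extend to more
than two arms — the stopping region of the multi-arm rule is not a
product of per-pair intervals — which is precisely the gap the reverse
simulation fills.

## Operating characteristics and estimator evaluation

`operating_characteristics()` tallies sole-winner and elimination
proportions per arm, expected total sample size, the unresolved
proportion, and a named joint no-difference event. That event is
scenario-specific configuration: by default the set of arms sharing the
maximum success probability (when at least two do), and a run counts
only if its terminal joint-winner set *equals* the named set.
`evaluate_estimators()` simulates trials, applies one estimator to every
pairwise comparison, and reports bias, spread, mean reported SE and
coverage, dropping (and counting) reverse-simulation analyses that fall
below the reliability threshold.

## What the generator emulates, and what it does not

The simulation engine reproduces the study conditions of the designs it
ships: exact per-arm accrual between interims, immediate binary
responses, equal randomisation, and — in the stratified case — random
multinomial allocation across equally weighted centres. It does not
model staggered enrolment or response delay, unequal per-arm sample
sizes within an interim, centre-size imbalance, or drift in success
probabilities over time. Passing tests therefore demonstrate
correctness of the decision rules and estimators under the idealised
accrual model, not robustness to the operational irregularities of a
real trial (the statistics themselves remain usable under moderate
imbalance, but the operating characteristics were not evaluated there).

## Problem sizes and numerical checks

The test suite and the reproduction script run everything at desk
scale, chosen so each summary's Monte Carlo error is small against the
tolerance it is checked at: $10^4$ trials for design operating
characteristics (MC SE about 0.002 on a proportion of 0.025), $10^5$ to
$2\times10^5$ reverse simulations for single worked-example analyses,
and 150–200 trial replicates with $2\times10^4$–$5\times10^4$ reverse
simulations each for estimator sampling properties. Full-scale
reproduction ($10^6$ trials, $10^7$ reverse simulations) is exposed
through the same arguments. Distributional correctness is anchored by
enumeration and independent oracles rather than scale: the filtered
back-sampling law is compared with exhaustive path enumeration on a
two-patients-per-arm toy design (total variation below 0.01), the
recursion behind the analytic method against forward normal-increment
Monte Carlo, and the two Rao-Blackwell routes against each other on all
twelve two-arm worked runs (they agree within 0.02, the scale of their
model difference: exact hypergeometric versus normal increments).

## Known limitations

Confidence intervals from both Rao-Blackwell methods lean on two
approximations — the conditional variance estimate substitutes for its
expectation, and the pivot is treated as normal — and run conservative
(coverage near 0.97 at nominal 0.95). The unbiasedness claim is the
stronger result. Reverse simulation needs many replicates when the
observed path is atypical: completeness can drop below 2% for
comparisons whose start is deep into the trial, and analyses below the
reliability threshold should be rerun with more replicates rather than
trusted. Success probabilities near 0 or 1 concentrate the
hypergeometric draws and have not been evaluated here; and the
engine's exchangeability of arms means label-specific operating
characteristics are obtained by permuting the scenario, not the design.
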