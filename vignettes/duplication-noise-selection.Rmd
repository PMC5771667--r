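---
title: "Noise buffering by gene duplication: model, estimators, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise buffering by gene duplication: model, estimators, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsel)
```

This vignette documents the science inside `dupsel`: the fitness and
expression models and their assumptions, the parameters that matter and why
their defaults are what they are, the synthetic-data generators and what
they do and do not emulate, the numerical and estimator choices that were
genuinely open, and the package's known limitations.

## The cost–benefit fitness model

Fitness is the cellular growth rate `W` of *E. coli* growing on lactose,
decomposed into a metabolic benefit and an expression cost of the LacZ
enzyme:

$$W = W_0\,(1 + B - C), \qquad
  B = \frac{a\,y\,x}{k + x}, \qquad
  C = \frac{b\,y}{h - y}.$$

`x` is the lactose dose (mM), `y` the LacZ expression normalised to the
wild-type singleton maximum. The benefit is Michaelis–Menten in the dose and
linear in expression; the cost diverges as expression approaches the
resource ceiling `h`, and `W = 0` for `y > h`. Defaults are the
experimentally fitted constants (`fitness_params()`): `W0 = 1` /h,
`a = 0.17`, `k = 0.40` mM, `b = 0.036`, `h = 1.80`, `x0 = 0.13` mM, `n = 4`.
Units are fixed throughout: doses in mM, growth rates in 1/h, expression
dimensionless.

Imposing `dW/dy = 0` gives the optimal expression
`y_opt = h - \sqrt{b\,h\,(k+x)/(a\,x)}`. Two design decisions around the
closed form:

* **Clamping.** The printed form is negative at low doses (below
  `x ≈ 0.053` mM at the defaults), where any expression costs more than it
  earns; `optimal_expression()` clamps to `[0, h]` because fitness is
  monotone decreasing in `y` whenever the unclamped optimum is negative, so
  the biologically meaningful optimum is zero expression. In the clamped
  region the optimal curve is flat and `optimal_slope_at()` reports a zero
  slope with a warning.
* **Flooring.** For `y` just below `h` the cost term can push
  `1 + B - C` below zero. `fitness()` floors `W` at 0: growth rates cannot
  be negative, and the dilution simulator requires non-negative clone
  volumes. This is the package's own resolution of a case the model leaves
  open, consistent with the `y > h` convention.

For organisms other than *E. coli* the cost ceiling scales with haploid
genome size as `h = 0.36 G` (`scale_to_genome()`), and the effective
population size as `⟨N⟩ = 3·10⁹/G^1.44`
(`effective_population_size()`) — both empirical interspecific scalings
that tie organismal complexity to the cost of extra expression and to the
strength of drift.

## Stochastic expression and gene duplication

Expression is modelled at steady state per cell cycle. Each copy `i` of the
gene responds to a noise-distorted dose:

$$y = \sum_i y_{\max,i}\,
  \frac{(x\,z_i\,z_0)^n}{x_0^n + (x\,z_i\,z_0)^n},$$

with one extrinsic multiplier `z0` per cell (shared by all copies) and one
intrinsic multiplier `z_i` per copy, all log-normal with zero log-mean and
log-SDs `eta_ex` and `eta_in`. **All noise amplitudes are natural-log SDs**:
this convention reproduces the experimentally reported coefficient-of-
variation range 0.26–0.72 for `eta = 0.1–0.5` at the EC50 (base-10 does
not), which is also how the lactose fluctuation amplitude `delta_x` is
interpreted. Noise is redrawn independently per cell and per cell cycle with
no temporal autocorrelation.

Three structural consequences, each a tested invariant:

* With `eta_in = 0` the two copies of a dosage-sharing duplicate
  (`y_max = 0.5 + 0.5`) receive identical multipliers and the duplicate is
  *bit-identical* to the singleton (the implementation draws no random
  numbers for a zero-amplitude component, so the RNG streams coincide).
  Extrinsic noise cannot be buffered by duplication.
* With `eta_ex = 0` the duplicate's expression is the sum of two iid halved
  responses, so its variance is exactly half the singleton's.
* With both noise sources active the variance reduction sits between those
  extremes. Its value depends on the intrinsic/extrinsic ratio, which the
  underlying experimental setting leaves unspecified: at
  `eta_in = eta_ex` the reduction is ~25–30% near the EC50, while with
  extrinsic noise moderately dominant (`eta_in = 0.3, eta_ex = 0.4` — the
  more common situation in single-cell reports at moderate expression) it is
  ~20%, inside the commonly quoted 15–25% band. The property test uses the
  latter setting, chosen once on that empirical ground.

`hill_slope_at_x0()` quantifies the flattening of the *median*
dose–response curve of a duplicate under intrinsic noise by refitting a
Hill function (trust-region least squares via `minpack.lm`, free amplitude,
coefficient and midpoint, initialised at the deterministic values, on
log-spaced doses spanning `x0/30`–`30 x0`). The deterministic singleton
recovers `n_eff = 4` and midpoint slope `n/4 = 1`; the dosage-sharing
duplicate at `eta_in = 0.5` flattens to `n_eff ≈ 3`, slope ≈ 0.75, closer
to the optimal curve's 0.47. The fitting protocol is the package's own
choice; the underlying analysis reports only the fitted values.

`curve_deviation_test()` ranks the wild-type regulation among alternative
EC50 values sampled log-uniformly on 0.01–1 mM, using the Euclidean
distance to the optimal curve on 50 log-spaced doses in 0.001–10 mM
(both grids package choices; the dose grid spans the full induction range
with equal weight per decade). At defaults the wild type beats ~98% of
alternatives (p ≈ 0.02).

## Synthetic environments and promoter-mutant spectra

Two inputs of the analysis are distributions rather than constants, and the
package generates both synthetically.

**Lactose environments** (`environment_spec()`, `sample_lactose()`):
constant, or log-normally fluctuating with `ln(x/x_median) ~ N(0, delta_x)`.
The default `delta_x = 1` (natural log) matches the convention above. This
emulates between-passage environmental variation only — it does not model
temporal autocorrelation, gradual depletion within a passage, or spatial
structure.

**Promoter-mutant activities** (`promoter_mutant_spec()`,
`sample_promoter_activity()`): the distribution of maximal expression among
single-point cis-regulatory mutants, summarised by three constraints — a
peak at the wild-type activity, sample skewness ≈ −0.68, and ~10% of
mutants near half expression (mass in [0.4, 0.6]). The generating family is
a mixture of a skew-normal main peak (mode pinned at 1) and a narrow
Gaussian component at half activity, truncated to (0, 1.3]. Its free
parameters (main-peak scale and shape, tail weight) are solved by
multi-start Nelder–Mead on quadrature moments. Skewness is the binding
constraint (calibration errors out if it cannot be met within 0.05); the
half-expression mass is matched as closely as the bounded support allows,
since e.g. a symmetric target with the peak at 1 and support capped at 1.3
cannot simultaneously hold 10% of its mass at 0.5. The main-peak scale is
bounded (0.02–0.6) so the distribution stays genuinely peaked and the
truncation sampler stays efficient. This generator reproduces the *printed
summaries* of the mutant spectrum only — it does not re-fit the linear
model on the external mutant library behind them, and it deliberately
excludes epistasis and any effect of mutations on noise (mean effects
only).

## Information transfer

`mutual_information()` measures the fidelity of the lactose→LacZ channel as
the mutual information between `ln x` and `y`, in bits, from the 2-D
histogram of the sample. The estimator was the one genuinely open design
decision, and it was pinned by an oracle: for the additive Gaussian channel
`y = ln x + ε` with `SD(ln x) = 1`, `SD(ε) = 0.5`, the closed form is
`I = 0.5·log2(5) ≈ 1.161` bits, and the estimator must land within
±0.1 bits of it at `n = 1e5`.

* **Equal-frequency (quantile) bins**, not equal-width. The Hill response
  saturates, piling probability mass near 0 and 1; equal-width bins in `y`
  collapse distinguishable responses inside the piles and lose real
  information (measured: 1.03 bits on the Gaussian oracle at `n = 1e5` with
  16 equal-width bins — outside the oracle bound — and ~0.87 bits on the
  lacZ channel). Quantile bins keep resolution where the mass is.
* **48 bins per axis** (exposed as `bins`). At `n = 1e5` the oracle check
  gives 1.150 bits (within 0.011 of the closed form); at the analysis's
  working size `n = 1e4` the plug-in bias of order
  `(B-1)²/(2n ln 2)` is part of the estimator's documented behaviour —
  independence tests at `n = 1e4` sit near the ~0.16-bit bias floor, and
  the singleton/duplicate lacZ channel values (~1.25/1.55 bits) include it.
  MI is reported in bits (log2) even though the noise model uses natural
  logs.

`mi_significance()` compares two MI values through the equivalent-Gaussian
correlation `r = sqrt(1 - 2^(-2I))` and Fisher's r-to-z transformation,
`z = (atanh r_2 - atanh r_1)/sqrt(2/(n-3))`, two-sided normal p.

## Selection analysis

`selection_distribution()` is the workhorse: per trial it draws one dose,
gives the challenger and the reference genotype *independent* noise draws —
including independent extrinsic multipliers, because competing genotypes
are distinct cells; only the environment is shared — evaluates `W` for
each, and records `S = W_chal/W_ref - 1`. `⟨S⟩` is the mean of per-trial
ratios (the distribution mean), not the ratio of mean fitnesses; the latter
is kept as a diagnostic field. Skewness is Fisher–Pearson `g1`
(uncorrected), the conventional default. Trials with a dead reference are
excluded with a counted warning; for all standard genotypes
(`Σ y_max ≤ 2 < h` at sane noise) no exclusions occur.

Noise-level vocabulary used across curves: "moderate" is
`eta_in = eta_ex = 0.3`, "high" is `eta_in = eta_ex = 1`.

`neutral_region()` maps where a doubling duplication is effectively neutral
(`|⟨N⟩·⟨S⟩| < 1`) over expression level and genome size, with the benefit
switched off (`a = 0`) — the gene is expressed but earns nothing, so only
the cost matters. With no benefit, a fully induced response equals its
maximal expression regardless of multiplicative dose noise, and the
selection coefficient reduces to the deterministic cost ratio
`(1 - C(2y))/(1 - C(y)) - 1`; the function therefore computes it in closed
form. Cells whose singleton expression already exceeds the ceiling
(`y > h`) are inviable and flagged non-neutral rather than given a
selection coefficient.

## Population genetics

All closed forms are implemented as printed: competition
`r = r_0·2^{St}`, `f = 1/(1+1/r)`; punctual fixation `P = 2S`,
`t_fix = log2(⟨N⟩²)/S`, `t_half = t_fix/2`; neutral `P = 1/⟨N⟩`,
`t_fix = 2⟨N⟩`; recurrent supply `P = 1`, `t_fix = log2(⟨N⟩S/μ_b)/S`;
duplication regime via the effective coefficient `S' = S - μ_d` (not
fixable when `S ≤ μ_d`). Decisions where the printed account is silent or
approximate:

* The duplication regime uses the punctual closed forms evaluated at `S'`,
  which makes it reduce *exactly* to the punctual regime at `μ_d = 0`.
* `recurrent_mutant_dynamics()` implements the printed approximate
  large-supply form `r = μ_b·2^{St}/S`; the exact prefactor differs by the
  O(1) factor `√D/log2(D)` and the base of its `log(D)` is not pinned down,
  so the approximate form — which the regime's limiting behaviour is quoted
  in — is the implementation.
* `duplication_frequency_dynamics()` is a per-generation two-class
  recurrence: duplicate mass grows by `(1+S)`, fractions `μ_d` and `μ_c`
  convert between classes, then the population renormalises. Its neutral
  stationary point is *exactly* `μ_c/(μ_c+μ_d)`; for deleterious duplicates
  it agrees with `μ_c/(μ_c+μ_d-S)` to first order in the rates (a few
  percent at `S = -0.28`, `μ_d = 0.044`). With `μ_c = μ_d = 0` it is pure
  competition with per-generation growth `1+S`, i.e. `2^{S't}` with
  `S' = log2(1+S)` — the `1+S` vs `2^S` distinction is second-order at the
  `|S| ≲ 10⁻²` scales of interest but is stated here because the package
  tests it exactly. With `S > μ_d` the recurrence sweeps towards fixation,
  leaving only the deletion-regenerated singleton mass
  (`1 - f* ≈ μ_d(1+S)/S`).

The two-step path to an adaptive duplication (promoter mutation halving
expression, then duplication restoring it) is arithmetic on these pieces:
`mutant_supply()` for the expected number of halving mutants,
`concurrence_and_global_fixation()` for
`p_concur = n_mut·p_dup/2` and `P_fix = 2(S-μ_d)·p_concur`. The per-cell
duplication probability `p_dup` is an explicit argument (a formation rate
or a standing frequency, whichever the scenario calls for) because the two
published uses of the arithmetic employ different values.

## The serial-dilution evolution simulator

`run_evolution()` competes two genotypes in a culture of capacity
`N = 1e5` diluted 100-fold daily, i.e. `log2(100) ≈ 6.64` generations per
passage, one shared lactose dose per passage redrawn from the environment.
Design decisions:

* **Synchronous cell-cycle resolution.** Each 1-h step every cell draws its
  own expression and hence growth rate `W`, multiplies its volume by
  `2^W`, and splits into two daughters that redraw noise next step; the
  final fractional step (0.64 h) multiplies volume without a redraw. At the
  `S ~ 10⁻³` scales involved this synchronous branching agrees to first
  order with event-driven asynchronous division while remaining fully
  vectorisable.
* **Dilution sampling.** The next passage's `N/D` founders are drawn
  binomially with probability proportional to genotype volume shares:
  relative volume is the deterministic dominant factor, and the retained
  sampling noise produces the replicate-to-replicate variance that the
  replicate envelopes quantify. No mutations occur within a simulation.

`theory_comparison()` confronts the replicate-mean trajectory with the
analytic competition curve at an independently estimated `⟨S⟩`. It reports
residuals, and envelope containment both strictly (`within_envelope`) and
as a fraction of recorded generations (`envelope_coverage`). With `R`
replicates the ±2 SD band uses an `R-1`-df SD estimate, so the pointwise
miss probability is ~7% at `R = 3` but ~0.4% at `R = 6`; tests therefore
run 6 replicates and require coverage ≥ 0.95, which cleanly separates the
correct `⟨S⟩` from a tenfold-exaggerated negative control.

## Problem sizes and reproducibility

Monte-Carlo sizes used by the tests and the acceptance script are the
analysis's own working sizes: `n = 1e4` trials for the headline selection
distribution and channel informations, `1e5`–`2e5` draws for CVs, variance
ratios and the high-noise mean selection, 60–75 passages × 3–6 replicates
for simulator checks — all chosen so every statistic's Monte-Carlo SE is
well below the effect it measures, and the whole suite runs in well under a
minute. Every stochastic function takes an explicit integer seed and
restores the caller's RNG state; `run_experiment()` writes a manifest
(experiment id, overrides, seed, package version) sufficient to reproduce a
run byte-for-byte.

Statistical caveat stated once: the skewness of the selection distribution
is a heavy-tailed statistic whose sampling SD at `n = 1e4` is ~0.2, so
single-run values between roughly 1.9 and 2.9 are all consistent with the
model; the package reports whatever the seeded run produces rather than a
curated draw.

## Limitations

* Steady-state, monostable induction only: no transient expression
  dynamics, no bistability (which lactose, unlike synthetic inducers, does
  not elicit in this system).
* Expression cost is attached to LacZ expression; a LacY-based uptake cost
  would be more mechanistic but is outside scope.
* Promoter mutations shift mean expression only — no epistasis, no effect
  on noise amplitudes; intrinsic/extrinsic amplitudes are constants, not
  functions of expression level.
* The promoter-mutant generator reproduces three summary statistics of the
  mutant spectrum, not the spectrum itself; conclusions that depend on
  finer features of that distribution are outside what passing tests
  establish.
* The simulator has no within-run mutation, duplication or deletion events
  (those enter analytically), no spatial structure, and one dose per
  passage; real serial-dilution experiments violate all three to some
  degree.
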