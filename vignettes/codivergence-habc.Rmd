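---
title: "Testing simultaneous divergence across a barrier with hierarchical ABC"
author: "codiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing simultaneous divergence across a barrier with hierarchical ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codiverge)
```

## The question and the model

Comparative phylogeography repeatedly finds several co-distributed
species whose populations are split by the same biogeographic barrier.
Shared spatial structure suggests shared history — a single vicariant
event splitting every species at once — but congruent *space* does not
imply congruent *time*: the same barrier may have fractured different
species' ranges in different epochs, and even a truly simultaneous
split produces discordant gene-divergence times because each species'
coalescent history adds its own noise.

`codiverge` implements a hierarchical Approximate Bayesian Computation
(HABC) test that separates these explanations. Each species
contributes a *taxon pair*: two population samples of one aligned
locus, one sample on each side of the barrier. Above the pairs sits a
hyperparameter pair:

* $\Psi$ — the number of distinct divergence pulses shared by the $Y$
  taxon pairs, with prior discrete-uniform on $\{1, \dots, \Psi_{\max}\}$
  and $\Psi_{\max} = Y$;
* $\tau_1, \dots, \tau_\Psi$ — the pulse times, i.i.d. uniform on
  $(0, \tau_{\max})$.

Pairs are mapped to pulses by a uniformly random surjection, so a draw
with $\Psi$ pulses realises exactly $\Psi$ distinct divergence times
and $\Psi$ is literally "the number of divergence times present among
the pairs". (An alternative `assignment = "uniform"` scheme assigns
pairs to pulses independently; it is retained as an option, but it
decouples the drawn $\Psi$ from the realised number of times — a
$\Psi = 5$ draw frequently realises only 2 or 3 — which in validation
runs left the $\Psi$ posterior nearly flat even when $\Omega$ was well
resolved, so the surjective scheme is the default.) Each pair's
demographic nuisance parameters are drawn from sub-priors: a per-site
$\theta = 4N\mu$ shared by both descendant populations
($\theta \sim U(\theta_{\min}, \theta_{\max})$), an ancestral
$\theta_A$ fixed at a configurable ratio of $\theta$ (default 0.5),
and scaled migration rates $m_1, m_2 \sim U(0, 2\bar m)$ whose mean
$\bar m$ is barrier-level prior information (typically an
isolation-with-migration posterior-mean summary for that barrier).
Conditional on its parameters, a pair evolves under a two-population
isolation-with-migration structured coalescent with finite-sites HKY
mutation.

The posterior of interest is summarised by $\Psi$ and by the
dispersion index
$$\Omega = \operatorname{Var}(\tau) / \operatorname{E}(\tau)$$
across the per-pair divergence times. $\Omega = 0$ under strictly
simultaneous divergence and grows with temporal discordance; because a
hypothesis about *times* is better measured on the time scale than by
the integer $\Psi$, $\Omega$ is the primary evidence measure, with
$\Psi$ reported alongside.

The three stages of the test mirror the classic msBayes-style
workflow:

1. **Observed statistics.** Each pair is reduced to eight summary
   statistics — $\pi_1, \pi_2$ (within-population nucleotide
   diversity), $\pi_b$ (mean between-population pairwise diversity),
   $\pi_{net} = \pi_b - (\pi_1{+}\pi_2)/2$, Watterson's
   $\theta_{W,1}, \theta_{W,2}$, and Tajima's $D_1, D_2$ — and the
   across-pair means and variances of each statistic are appended as
   hyper-summaries.
2. **Reference table.** `run_simulations()` draws `n_sims`
   hyperparameter sets and simulates every pair under each, recording
   the condensed hyperparameters ($\Psi$, realised $\Psi$,
   $E(\tau)$, $\operatorname{Var}(\tau)$, $\Omega$) next to the same
   statistic vector.
3. **Rejection.** Statistics are standardised by their simulation
   standard deviations; the `n_accept` rows closest to the observed
   vector in Euclidean distance are retained and summarised
   (optionally after local-linear regression adjustment of the
   continuous hyperparameters and a weighted multinomial-logit fit
   for $\Psi$).

## Time and rate scaling

Every time in the package is expressed in coalescent units anchored by
a reference theta, $\theta_{ref} = \theta_{\max}/2$:

* two lineages in a population with $\theta = \theta_{ref}$ coalesce
  at rate 1 per unit (a population with a different $\theta$ coalesces
  at rate $\theta_{ref}/\theta$ per lineage pair);
* each lineage mutates at $(\theta_{ref}/2) \times
  \text{rate\_multiplier}$ per site per unit;
* $\tau$ and the migration rates $m_1, m_2$ (per-lineage jump rates,
  backward in time) are in the same unit.

Two closed-form consequences pin the convention and are enforced by
the test suite: a panmictic sample of two has
$E[\text{TMRCA}] = \theta/\theta_{ref}$ units and $E[\pi] = \theta$;
and without migration
$E[\pi_{net}] = \text{rate\_multiplier} \times \theta_{ref} \times \tau$,
so the fitted slope of $\pi_{net}$ on $\tau$ recovers
$\theta_{ref}$ exactly up to the small finite-sites multiple-hit
deficit. Because a single locus per pair carries the signal, loci with
different absolute rates are put on one time axis through the
dimensionless `rate_multiplier` (20 for mtDNA, 1 for cpDNA/ITS — the
conventional 20-fold difference between mitochondrial and
chloroplast/ribosomal spacer rates in plants-plus-vertebrates panels).

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `tau_max` | 3 | upper bound of the pulse-time prior, coalescent units |
| `theta_max` | 0.15816 | upper bound of the per-pair $\theta$ prior, per site (an mtDNA-scale value); also sets $\theta_{ref}$ |
| `theta_min` | 1e-4 | lower bound of the $\theta$ prior |
| `theta_anc_ratio` | 0.5 | $\theta_A / \theta$ |
| `mig_mean` | 0 | barrier-level mean scaled migration rate; $m \sim U(0, 2\bar m)$ |
| `kappa` | 4 | HKY transition/transversion parameter |
| `n_sims` | 1e6 | reference-table rows (study scale); desk-scale analyses use 2e4–5e4 |
| `n_accept` | 2000 | retained draws (study scale); desk scale 200–500 |

A uniform distribution is used for the migration prior because a mean
alone does not fix a distribution; $U(0, 2\bar m)$ is the
least-structured choice matching the mean, and the choice is echoed in
every output header. For $\Omega$ the population variance
(divide by $Y$) is the default, switchable to the sample variance;
`Var(tau)/E(tau)` names a moment ratio without fixing the denominator
convention, so the package fixes one and documents it.

## The synthetic-study generator

`study_truth()` / `generate_study()` draw complete studies from the
same IM coalescent at *fixed* (not prior-drawn) parameters, so every
pipeline stage can be validated against known truth. The presets
mirror the shapes of real barrier sets: 10, 5, 3 and 2 taxon pairs
with per-side sample sizes echoing published single-locus panels
(105/17 down to 10/3 sequences), 600 bp loci, mixed mtDNA
(multiplier 20, truth $\theta = 0.002$) and cpDNA/ITS (multiplier 1,
truth $\theta = 0.008$) — i.e. per-site diversities around 4% and
0.8% and cross-barrier mtDNA divergences of a few to fifteen percent.
The 10-pair preset carries three divergence pulses
($\tau \in \{0.5, 1.5, 2.5\}$); the others are single-pulse.

Desk-scale analyses of these synthetic studies use
$\theta_{\max} = 0.01$ (hence $\theta_{ref} = 0.005$, the unit the
preset truths are expressed in). This choice is deliberate: with the
20-fold mtDNA multiplier, an mtDNA-scale $\theta_{\max}$ of 0.15816
would put most prior mass in a regime where a 600 bp locus is
mutationally saturated and carries little information about $\tau$;
the synthetic truths are calibrated to realistic diversities, and the
prior is calibrated to bracket them. The study-scale prior
($\theta_{\max} = 0.15816$, $\tau_{\max} = 3$, $10^6$ simulations,
2000 accepted) remains the package default and runs end to end; its
original posteriors can only be reproduced with the original
alignments.

What the generator does *not* emulate: base-composition bias, rate
heterogeneity among sites, indel/missing-data patterns of real
chromatograms, recombination, and post-divergence bottlenecks or
growth. Passing recovery tests therefore demonstrate that the
machinery is calibrated and powerful under the model's own
assumptions, not that any particular real dataset satisfies them.

## Numerical and degenerate-input choices

* **Missing data.** Sites with N or a gap are excluded pairwise (per
  compared sequence pair), not listwise, preserving information in
  ragged field data. Simulated data contain no missing sites, and the
  fused C++ statistics path is tested for exact equality with the R
  definitions on materialised alignments.
* **Tajima's D.** Undefined for $n < 3$ or $S = 0$ (NA sentinel). For
  $n = 3$ the 1989 variance constants are identically zero, so D only
  exists for $n \ge 4$; the implementation returns the sentinel there
  too. Inside ABC statistic vectors a defined-but-degenerate D
  ($S = 0$ at $n \ge 3$) is encoded as 0 so observed and simulated
  vectors stay numerically comparable.
* **Between-population diversity.** $\pi_b$ averages over all
  $n_1 n_2$ cross pairs with equal weight (standard Nei definition);
  feeding one sample in as both populations therefore includes the
  zero-distance self-pairings, giving $\pi_{net} = -\pi_1/n$ rather
  than 0 — an exact finite-sample property the tests assert.
* **TN93 distances.** Base frequencies are pooled over the union of
  the compared sequence sets (configurable); a non-positive logarithm
  argument (saturation) is an error naming the offending sequence
  pair, and the within/between distance summary (`Dx`, `Dy`, `Dxy`,
  `Da`) shares one pooled frequency estimate.
* **Rejection.** Zero-variance statistic columns are dropped with a
  warning; distance ties are broken by row index, making the accepted
  set deterministic. Statistics that are undefined for a pair's
  sample sizes (a side with one sequence) are NA in both observed and
  simulated vectors and drop out of the distance.
* **Adjusted reporting.** Plain rejection must tolerate large
  per-statistic deviations when the statistic vector is long (dozens
  of standardised dimensions at a 1% acceptance rate), which blurs the
  hyperparameter posteriors even though the statistics individually
  carry strong signal. The recommended reporting
  (`test_codivergence(..., adjust = TRUE)`) therefore applies the
  standard local-linear adjustment to the continuous hyperparameters
  and a weighted multinomial-logit fit for $\Psi$ — the estimator
  conventionally quoted for $\Psi$ in this literature. The categorical
  fit uses the across-pair hyper-summaries as predictors by default:
  a hyperparameter describes the across-pair configuration, its
  signal lives in the across-pair moments, and 16 predictors on a few
  hundred accepted draws keeps the fit well-conditioned
  (`psi_predictors = "all"` is available). Unadjusted weighted counts
  remain the verifiable baseline and the default of
  `summarize_posterior()`.
* **KDE mode.** $\Omega$'s mode uses a Gaussian kernel with Silverman
  bandwidth, maximised on the density grid and clamped to the range
  of the accepted draws (all-equal draws short-circuit to that value).
* **Class occupancy.** Under the default surjective assignment every
  drawn pulse is realised (`psi_realized == psi`); under the optional
  independent-uniform assignment the realised number of distinct times
  is recorded separately per draw, and both are reported. The
  surjection is sampled exactly (sequential occupancy-conditional
  probabilities from inclusion–exclusion counts), not by rejection.
* **RNG.** All randomness, including the C++ simulator's, flows from
  R's RNG, so a single `set.seed()` makes every stage bit-reproducible.
  Execution is serial; reproducibility comes from the single stream
  rather than counter-based sub-streams.
* **Event cap.** Each genealogy simulation is capped at $10^7$ events
  and fails loudly if a parameter draw is pathological.

## Problem sizes used in the shipped checks

The validation suite uses sizes chosen to make Monte-Carlo error
small relative to the effects checked while keeping a desk-scale run
practical: 100-case oracle sweeps for the statistics; 20,000
replicates for the closed-form coalescent checks; 16,000 simulations
for the time-scaling regression; and, for hyperparameter recovery, 20
replicate studies per scenario analysed with 50,000-row reference
tables and 500 accepted draws (5-pair simultaneous truth and 8-pair
two-pulse truth). The bundled acceptance script analyses all four
preset barrier shapes at the same table size.

## Known limitations

* Single locus per pair: co-divergence inference rests on ruling out
  differences in coalescent times from one gene genealogy per
  species; multi-locus extensions are out of scope.
* No recombination, growth or bottleneck sub-models in the IM
  simulator.
* The summary-statistic vector is a documented default (the eight
  per-pair statistics plus across-pair means and variances), not an
  optimised choice; the layout is versioned in output headers so
  alternative vectors can be compared.
* $\Psi$ is weakly identified when pulses are close relative to the
  coalescent noise floor — the reason $\Omega$ is the primary
  evidence measure.
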