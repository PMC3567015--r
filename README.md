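# codiverge

Hierarchical Approximate Bayesian Computation (HABC) tests of
simultaneous versus non-simultaneous divergence for co-distributed
taxon pairs separated by a shared biogeographic barrier.

## The problem

When several unrelated species all show a genetic break across the
same geographic barrier, did one vicariant event split them all at
once, or did the barrier fracture different species at different
times? Congruent spatial structure does not settle the question:
coalescent noise makes gene divergence times scatter even under a
single shared event. `codiverge` is for comparative phylogeographers
who have, per species, one aligned locus sampled on both sides of a
barrier, and who want a model-based answer.

## The method

Each species is a *taxon pair* (two population samples of one locus).
A hyperprior places Ψ divergence pulses at times
τ₁…τ_Ψ ~ U(0, τ_max), Ψ ~ U{1…Y}, maps the pairs onto the pulses by a
uniformly random surjection (every pulse is realised), and
draws per-pair nuisance parameters (θ ~ U(θ_min, θ_max), ancestral
θ_A = θ/2, migration m₁, m₂ ~ U(0, 2·m̄) from barrier-level prior
information). Every pair is then simulated under a two-population
isolation-with-migration structured coalescent with finite-sites HKY
mutation, reduced to summary statistics (π within/between, net
divergence π_net, Watterson's θ_W, Tajima's D, plus across-pair means
and variances), and an acceptance/rejection step keeps the
simulations closest to the observed statistics. The posterior is
summarised by the mode and mean of Ψ and of the dispersion index

    Ω = Var(τ) / E(τ)

across pairs: Ω = 0 under strictly simultaneous divergence, larger
with temporal discordance. Tamura–Nei corrected distances
(Dx, Dy, Dxy, Da) are reported alongside the raw statistics for each
pair. See the methods vignette
(`vignettes/codivergence-habc.Rmd`) for the model, the time/rate
scaling convention, and every numerical choice.

## Worked example

Generate a synthetic two-pair study with known truth (one shared
divergence pulse at τ = 0.5 coalescent units), then test it:

```r
library(codiverge)

truth <- preset_scenarios("depression-like", seed = 1)
truth
#> <study_truth> barrier depression-like: Y = 2, psi_true = 1, tau = {0.5}, omega_true = 0

study <- generate_study(truth)$study
prior <- preset_prior("depression-like", n_sims = 20000, n_accept = 200)
fit <- test_codivergence(study, prior, seed = 42)
fit$posterior
#> <posterior_summary>
#>   Psi mode  = 1
#>   Psi mean  = 1.255
#>   Omega mode = 0
#>   Omega mean = 0.03161  (95% quantiles 0-0.3025)
#>   E(tau) mean = 0.4393
#>   accepted draws = 200
```

The truth had a single pulse (Ψ = 1, Ω = 0): the posterior mode of Ψ
is 1, the Ω posterior is concentrated at 0 (mode 0, 95% interval
including 0), and the posterior mean divergence time E(τ) ≈ 0.44 sits
near the true 0.5. Per-pair observed statistics and
corrected distances:

```r
round(pair_summary_vector(study[[1]]), 4)
#>      pi_1      pi_2      pi_b    pi_net theta_w_1 theta_w_2    tajd_1    tajd_2
#>    0.0384    0.0356    0.0768    0.0398    0.0337    0.0387    0.5999   -0.5190
round(distance_summary(study[[1]]), 4)
#>     Dx     Dy    Dxy     Da
#> 0.0401 0.0371 0.0817 0.0431
```

Real data enter through a manifest TSV (columns `pair_id`,
`barrier_id`, `fasta_path`, `sequence_id`, `population`,
`locus_type`, optional `rate_multiplier` — 20 for mtDNA, 1 for
cpDNA/ITS by default) with `read_study()`, or from the command line:

```sh
Rscript inst/cli/codiverge.R gen   --preset depression-like --seed 1 --out study/
Rscript inst/cli/codiverge.R stats --manifest study/manifest.tsv --out stats.tsv
Rscript inst/cli/codiverge.R run   --manifest study/manifest.tsv --seed 42 \
        --config prior.cfg --out run/
Rscript inst/cli/codiverge.R summarize --accepted run/accepted.tsv --out post.json
```

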