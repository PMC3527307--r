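# rhomap

Fine-scale recombination maps from population haplotype data.

`rhomap` estimates the population-scaled recombination map ρ(x) (in units
of 4·N<sub>e</sub>·r per bp) along a chromosome from a sample of phased
haplotypes.  It is aimed at population geneticists working with
high-recombination, high-diversity organisms (the motivating setting is
*Drosophila*-scale data: θ ≈ 0.01/bp, background ρ ≈ 10/kb), where both a
quadra-allelic mutation model and accurate likelihoods at large ρ matter.

## The method

The map is a step function inferred in a Bayesian setting:

* **Exact two-locus likelihoods.**  For every pair of segregating sites,
  the likelihood of the two-site haplotype configuration is computed
  *exactly* under the coalescent with recombination, jointly with the event
  that each site mutated exactly once: the two-locus ancestral recursion
  (full haplotypes, plus half-lineages created by recombination) is solved
  as a sequence of small sparse linear systems.  Under the
  one-mutation-per-site assumption the nucleotide identities factor out —
  P(data) = θ² Q[x,y] Q[x',y'] g(counts; ρ) with Q the 4×4 mutation
  transition matrix — so one lookup table of g values serves every mutation
  pattern, and every missing-data sub-configuration is evaluated by exact
  marginalization from the same table.
* **Padé summation beyond the grid.**  Tables hold g on a ρ grid
  (0 to 10 by 0.1, 11 to 100 by 1, following the likelihood's expected
  curvature); for larger ρ the likelihood is evaluated from 11 exactly
  computed coefficients of its 1/ρ expansion via diagonal Padé approximants
  with a defect (spurious-pole) heuristic.
* **rjMCMC over piecewise-constant maps.**  The pairwise composite
  likelihood (pairs conditioned on being observed dimorphic) is combined
  with a change-point prior — block penalty on the number of change
  points, uniform positions at SNP midpoints, exponential/gamma/log-normal
  heights — and sampled with reversible-jump birth/death/move/height moves.
* Plus: estimation of Q and θ from outgroup-polarized sites, per-site
  ancestral-allele priors, a conservative hotspot prefilter (≥10× the arm
  mean, ≥500 bp), Morlet/Haar wavelet machinery for comparing maps with
  genomic features, and a coalescent-with-recombination simulator used for
  all validation.

See `vignettes/recombination-maps.Rmd` for the model, priors, numerical
choices and validation scale.

## A worked example

```r
library(rhomap)

# mutation model: uniform transitions, effective rate 0.008/bp
Q <- matrix(1/3, 4, 4); diag(Q) <- 0
model <- calibrate_theta(Q, 0.008)

# exact two-locus lookup table for samples of up to 6 haplotypes (~40 s)
tab <- build_table(6, model$theta)

# simulate 6 haplotypes over 10 kb with a 2 kb, 10x hotspot in the middle
truth <- make_hotspot_map(10000, 0.01, width_bp = 2000, strength = 10)
hap <- simulate_haplotypes(6, 10000, truth, model, seed = 1)
hap
#> <hap_matrix> 6 haplotypes x 164 sites over 10,000 bp; 0.0% missing

# posterior over maps (block penalty 50, height prior at the background rate)
fit <- sample_posterior(hap, tab, model,
                        prior = prior_spec(50, n_segregating(hap),
                                           height_mean = 0.01),
                        iters = 100000, burn_in = 20000, seed = 7)
glance(fit)
#> # A tibble: 1 x 8
#>   n_snps  iters mean_rate mean_k accept_birth accept_death accept_position accept_height
#>    <int>  <dbl>     <dbl>  <dbl>        <dbl>        <dbl>           <dbl>         <dbl>
#> 1    164 100000    0.0181      1    0.0000800    0.0000400         0.00868         0.200

tidy(fit)     # posterior mean map with quantiles, one row per interval
#> # A tibble: 165 x 6
#>    left right   rate   q025    q50   q975
#>   <dbl> <dbl>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1     0    68 0.0292 0.0220 0.0288 0.0380
#> 2    68    81 0.0292 0.0220 0.0288 0.0380
#> 3    81   270 0.0292 0.0220 0.0288 0.0380
#> # ...

map_mean_rate(fit$map)                 # landscape average (truth: 0.028)
#> [1] 0.01812
cumulative_rho(fit$map, 4000, 6000)    # estimated hotspot area (truth: 200)
#> [1] 53.5
```

The fitted mean rate is in the right regime, but at this deliberately tiny
sample size (n = 6) the posterior smears much of the concentrated hotspot
mass into the flanks — the vignette's validation section quantifies how
this small-sample bias recedes with more haplotypes.
`autoplot(fit, truth = truth)` draws the posterior map against the truth.

The hotspot prefilter operates on any map; on the true map of this example
(arm-wide mean 0.028/bp, so the 10x hotspot sits at 3.6x the arm mean):

```r
scan_hotspots(truth, ratio_threshold = 3)
#> # A tibble: 1 x 6
#>   start   end width_bp mean_rate rate_per_kb ratio
#>   <dbl> <dbl>    <dbl>     <dbl>       <dbl> <dbl>
#> 1  4000  6000     2000       0.1         100  3.57
```

Wavelet comparison of maps and genomic feature tracks:

```r
tr <- bin_map(fit$map, bin_width = 250)        # log cumulative rho per 250 bp
cw <- cwt_morlet(tr)                           # Morlet transform
mask <- ar1_significance(tr, cw)               # AR(1) red-noise significance
dw <- haar_dwt(tr)                             # orthonormal Haar details
```

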