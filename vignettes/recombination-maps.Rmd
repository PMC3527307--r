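---
title: "Estimating fine-scale recombination maps with rhomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fine-scale recombination maps with rhomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

rhomap estimates the fine-scale population-scaled recombination map
$\rho(x)$ (in units of $4 N_e r$ per bp) from a sample of $n$ phased
haplotypes.  The map is modelled as a step function; inference combines a
*pairwise composite likelihood* — the product over pairs of segregating
sites of exact two-locus sampling probabilities evaluated at the cumulative
map rate between the sites — with a change-point prior, sampled by
reversible-jump MCMC.

## Two-locus likelihoods under one mutation per site

The per-pair likelihood is the ordered sampling probability of the
two-site haplotype configuration jointly with the event that each site
experienced exactly one mutation below its marginal most recent common
ancestor.  For the low per-site mutation rates of typical data
($\theta \approx 0.01$/bp) this event carries almost all of the mass of a
segregating site, and it buys two crucial simplifications:

* the one-locus problem has a closed form (`one_locus_q1()`), and
* the nucleotide identities factor out of the two-locus problem:
  the probability of observing ancestral/derived nucleotides
  $(x \to y, x' \to y')$ is $\theta^2 Q_{xy} Q_{x'y'} \, g(\mathbf{c}; \rho)$,
  where $Q$ is the 4x4 mutation transition matrix and $g$ depends only on
  the haplotype *counts* $\mathbf{c}$.  One table of $g$ values therefore
  serves every mutation pattern, and site-specific $Q$ matrices cost
  nothing extra.

The $g$ values solve a two-locus ancestral recursion of Golding type.
States count full haplotypes $c_{ij}$ (alleles $i,j \in \{0,1\}$, 0 =
ancestral), locus-A-only half-lineages $a_i$ and locus-B-only half-lineages
$b_j$ (created backwards in time by recombination).  Events are pairwise
coalescence (rate 1 per pair; only merges that agree at shared loci have
positive probability), recombination of full haplotypes (rate $\rho/2$
each), and mutation (rate $\theta/2$ per carried locus).  The
exactly-one-mutation budget restricts the mutation transition to the single
event that removes the last derived copy at a locus, and mutation events
are counted only while at least two lineages carry the locus — events above
a marginal MRCA are invisible, which is exactly the convention that
reproduces the closed-form one-locus solution (all-derived samples have
probability zero).

The system decomposes by the number of lineages carrying each locus
$(n_A, n_B)$ and the mutation budget $(k_A, k_B) \in \{0,1\}^2$.  Within a
block only recombination and half-lineage coalescence couple states, so
blocks are solved in dependency order as modest sparse linear systems —
this is the reduction that makes exact solution practical, and it yields
every sub-configuration of every size "for free" in the same solve.

## Missing data

A haplotype typed at one site of a pair but missing at the other is
evaluated by *exact marginalization*: the observed configuration's
likelihood is the binomially weighted sum of the complete-configuration
values over all assignments of the unobserved alleles, all of which live in
the same solved system.  We deliberately do **not** use the half-lineage
states of the recursion for observed missing data: a missing allele's
lineage still carries mutational exposure in the data-generating model, so
the half-lineage value differs from the exact marginal at order $\theta$
(about 0.7% at $\theta = 0.02$ in our checks).  Marginalization is the
exact likelihood of what was observed.

## The rho grid and Pade summation

Tables are precomputed on a grid (default $0(0.1)10$, then $11(1)100$; the
fine low-$\rho$ spacing follows the expected likelihood curvature —
`fisher_information()` shows the information concentrated at small $\rho$).
Between grid points the log-likelihood is interpolated with a monotone
cubic (Fritsch–Carlson) — smooth for the MCMC, no overshoot.  Beyond the
grid maximum the likelihood is evaluated by *Pade summation* of its
asymptotic expansion about $\rho = \infty$: 11 coefficients in $1/\rho$ are
computed exactly from the same block structure (the leading term is the
independent-loci product of one-locus marginals), and the diagonal [5/5]
rational approximant is evaluated with a defect heuristic — a pole of the
approximant within $\varepsilon = 0.01$ (in $1/\rho$ units) of the
evaluation point triggers a step down to the next diagonal order.  The raw
truncated series diverges at moderate $\rho$; the Pade value stays within
0.1% of the exact solve at the grid maximum.

## Conditioning of the composite likelihood

Pair likelihoods are conditioned on both sites being observed dimorphic
(given the pair's missingness pattern).  The unconditional normalizer
$\sum_{\mathbf c} N(\mathbf c)\, g(\mathbf c;\rho)$ itself decreases with
$\rho$ — correlated marginal trees at low $\rho$ make it likelier that both
sites mutate — so composite estimation without the conditioning is pulled
systematically toward small $\rho$ (we measured flat-map composite MLEs at
roughly $0.4\times$ truth without it, and centred on truth with it).  This
is the same conditioning used by classical pairwise-likelihood recombination
estimators.  `config_log_likelihood()` itself returns the unconditional
sampling probability; the conditioning is applied by
`composite_log_likelihood()`/`sample_posterior()` (argument `condition`;
an alternative `"margins"` mode additionally conditions on the observed
marginal allele counts — in our experiments the two give near-identical
maps).

# The prior and the block penalty

The map prior has three parts: a prior on the number of change points $k$,
uniform positions on the midpoints between adjacent SNPs (data constrain
only inter-SNP cumulative rates, so this loses nothing), and iid heights
from an exponential (default), gamma, or log-normal distribution.  The
exponential height mean should be set to the expected background rate of
the organism — a human-scale prior on high-recombination data produces
badly shrunken maps.

The *block penalty* $b$ controls smoothness.  `prior_spec()` offers two
readings:

* `changepoint_prior = "penalty"` (default): prior mass
  $\propto e^{-bk}$, i.e. each change point costs $b$ units of composite
  log-likelihood.  This is the reading under which the estimated map's
  smoothness actually responds to $b$ on the scale composite likelihoods
  operate at, and it is the one used by the penalized-composite-likelihood
  change-point samplers this method descends from.
* `changepoint_prior = "poisson"`: $k \sim$ Poisson with mean $s/b$ for
  $s$ SNPs.  Taken literally this changes the per-change-point cost only
  logarithmically in $b$; in our experiments maps sampled under it at
  desk scale are overfitted (dozens of change points, spiky rates)
  regardless of $b$, which is why it is not the default.

Birth/death moves follow the standard change-point construction: a birth
draws $u$ (from a U-shaped Beta(0.3, 0.3), whose density enters the
acceptance ratio; the heavy tails propose occasional hotspot-scale height
ratios), splits the containing segment's height $h$ into $h_1, h_2$ with
$h_1^{w_1} h_2^{w_2} = h$ and $h_1/h_2 = u/(1-u)$, and carries the
dimension-matching Jacobian $(h_1+h_2)^2/h$.  Height updates are log-scale
random walks with a heavy-tailed mixture kernel.  With the likelihood
switched off the sampler reproduces its prior exactly (change-point count
distribution and height distribution) — this is part of the test suite and
validates every acceptance ratio.

Whole chromosomes are processed in overlapping SNP blocks
(`blocked_inference()`, default 4,400 SNPs with 200 trimmed from each
internal edge), and per-interval summaries are posterior means with
2.5/50/97.5% quantiles.  Reported map means can trim edge regions
(`map_mean_rate(trim_bp = 2500)`) where the change-point model has little
data.

# The simulator

`simulate_haplotypes()` is a Hudson-style backwards-in-time
coalescent-with-recombination: piecewise-constant recombination maps,
piecewise demography with within-epoch exponential growth (bottleneck and
growth helpers provided), and finite-sites quadra-allelic mutation — every
mutation event draws its target base from the $Q$ row of the current base,
so recurrent and "ineffective" mutations occur and the inference model's
one-mutation assumption is deliberately *not* enforced.  Its output matches
Watterson's segregating-site expectation, pairwise diversity, and the
expected decay of linkage disequilibrium with $\rho$ (test suite).

What the simulations do not emulate: natural selection (sweeps), gene
conversion, inversion polymorphism, variable coverage/quality and phasing
error.  Passing benchmarks therefore demonstrate correctness of the
machinery under the neutral model, not robustness to everything real data
contain.

# Validation scale and the published control rows

The reference analysis this package re-implements reports, for neutral
25 kb simulations with background $\rho = 0.01$/bp and a central 2 kb
hotspot of relative strength 1, 10 or 50: median estimated mean rates of
9.3/kb (no hotspot) and median hotspot areas (total $\rho$ over the central
2 kb) of 18.2, 183.5 and 1100.  `run_benchmark()` reproduces that design.

Exact-table construction cost grows steeply with sample size (roughly
$n^5$), so the package's routine validation runs at $n = 10$ haplotypes on
20 kb regions, 12 replicates, a 30-SNP pair span and $10^5$ MCMC
iterations — sizes chosen so the entire validation executes on a laptop in
minutes.  (Hotspot areas over the central 2 kb are directly comparable to
the published 25 kb design; mean-rate rows are compared only for the flat
landscape, where the region length does not change the target.)  At that sample size the
composite-likelihood information per pair is weak: background rates are
recovered (flat-landscape medians within ~10% of the published row), but
concentrated hotspot mass is systematically smeared into the flanks — a
truth-initialized sampler *leaves* the true map, so this is small-sample
estimator bias, not a sampler failure, and larger samples sharpen the
per-pair curves and progressively recover the published hotspot areas.
The acceptance checks record exactly which of the published numbers are and
are not met at the validation scale.

# Other components

* **Mutation model estimation** (`polarize_sites()`, `estimate_Q()`,
  `calibrate_theta()`): outgroup parsimony polarization (a site is used
  only if the non-missing outgroup alleles show exactly one nucleotide and
  it matches a sample allele; tri/quadra-allelic sites are discarded),
  empirical per-base mutation frequencies normalized by the largest row sum
  so one diagonal entry of $Q$ is exactly zero, and $\theta$ calibrated so
  the stationary-weighted rate of allele-changing mutations matches an
  infinite-sites estimate: $\theta = \theta_w / \sum_a \pi_a (1-Q_{aa})$.
  The stationary distribution (rather than genomic base composition) keeps
  the calibration self-consistent with the model's own equilibrium.
* **Ancestral priors** (`ancestral_priors()`): without outgroup data the
  prior over the ancestral base is the stationary distribution of $Q$; with
  an outgroup allele $o$ and a TMRCA distribution $w(t)$ it is
  $\propto \pi_x \sum_t w(t) M(t)_{x,o}$ with
  $M(t) = \exp\{(\theta/2)(Q - I)\,2t\}$ (equal branch lengths to the two
  sides of the ancestor).  The observed sample alleles enter through the
  likelihood's polarization sum rather than the prior, so the mutation
  model is not double-counted.
* **Hotspot prefilter** (`scan_hotspots()`): maximal runs of map intervals
  above 10x the arm-wide (length-weighted) mean, at least 500 bp wide —
  narrower peaks are the characteristic width of rjMCMC artifacts.
  Sub-threshold gaps do not merge runs (conservative).
* **Wavelet comparison** (`cwt_morlet()`, `ar1_significance()`,
  `wavelet_coherence()`, `haar_dwt()`, `detail_correlation()`,
  `wavelet_linear_model()`): maps are binned to 250 bp tracks of
  log cumulative $\rho$ (floor: half the smallest non-zero bin).  The
  continuous transform uses the Morlet wavelet with $\omega_0 = 6$ and the
  $e^2$ cone-of-influence convention; significance uses the fitted-AR(1)
  red-noise background with the $\chi^2_2$ law; coherence uses
  scale-proportional Gaussian time smoothing plus 0.6-octave scale
  smoothing, with Monte-Carlo critical values from AR(1) surrogate pairs
  (per-scale mean of per-replicate 95% quantiles outside the cone).  The
  discrete transform truncates to the largest power of two (chromosome-arm
  tracks lose a negligible tail) and is orthonormal Haar, so it conserves
  energy and inverts exactly; per-scale association uses Kendall's tau
  with its normal-approximation critical value, and per-scale linear
  models are ordinary least squares on detail coefficients.

# Numerical choices and degenerate inputs

* Configurations impossible without recombination have likelihood exactly
  zero at $\rho = 0$; for log-scale interpolation these are floored at
  $10^{-10}$ times the row's smallest positive value.
* The AR(1) coefficient is estimated by lag-1 autocorrelation (the
  Yule–Walker order-1 solution).
* Ties in the hotspot scan cannot occur (intervals are half-open and
  abutting); `l1_distance()` evaluates on the common breakpoint refinement.
* Samplers, the simulator and the benchmark derive all randomness from R's
  RNG; block analyses use per-block streams derived from (seed, block).
* `hap_matrix()` rejects sites with no observed allele; sites with more
  than two observed alleles are excluded from pair likelihoods with a
  warning (the one-mutation model has nothing to say about them).

# Known limitations

* Table construction above $n \approx 14$ is expensive in pure R/Matrix;
  the reference implementation of this class of methods uses heavily
  optimized C++ for the same computation.
* The composite likelihood treats overlapping pairs as independent; its
  apparent information grows with the pair span, which is why the
  change-point penalty is essential and why posterior quantiles are
  composite-posterior quantiles, not calibrated frequentist intervals.
* At small sample sizes the estimator smears concentrated hotspot mass
  (see the validation section); hotspot *detection* (the prefilter) is
  affected less than hotspot *area* estimation.
* Selection, gene conversion and inversions are out of scope for the
  simulator and unmodelled in the likelihood.
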