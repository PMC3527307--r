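Package: rhomap
Title: Fine-Scale Recombination Map Estimation from Population Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates fine-scale population-scaled recombination maps (rho per bp)
    from phased haplotype alignments. Two-locus sampling probabilities are computed
    exactly under a one-mutation-per-site, quadra-allelic mutation model by solving
    the two-locus ancestral recursion jointly for all sample configurations, tabulated
    on a recombination-rate grid and extended to large rho by Pade summation of the
    asymptotic expansion. Piecewise-constant maps are fitted by reversible-jump MCMC
    under the pairwise composite likelihood with a Poisson change-point prior and a
    user-set block penalty. Includes estimation of the 4x4 mutation transition matrix
    from outgroup-polarized sites, ancestral-allele priors, a conservative hotspot
    prefilter, wavelet machinery (Morlet continuous transform with AR(1) red-noise
    significance and coherence; orthonormal Haar discrete transform with per-scale
    correlation and linear models) for comparing maps with genomic features, and a
    coalescent-with-recombination simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
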