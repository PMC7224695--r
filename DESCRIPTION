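Package: ndmmtools
Title: Annotation and Phylogenetic Comparative Analysis of Nematode-Derived
    Modular Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of nematode-derived modular
    metabolites (NDMMs), the ascaroside-based small-molecule pheromones of
    nematodes. Provides molecular-formula arithmetic and monoisotopic ion
    m/z computation, combinatorial assembly of modular ascaroside structures
    (simple, dimeric, and ureido-headed classes) with prediction of their
    diagnostic MS/MS fragment ions, a structure-based nomenclature grammar,
    and a targeted tandem-MS screen that matches spectra by precursor and
    diagnostic fragment m/z within ppm tolerances and classifies detections
    as quantifiable or trace. Downstream, replicate peak-area tables become
    within-class percentage profiles, closed compositional profiles, and
    presence/absence matrices, which feed phylogenetic comparative analyses:
    two-state Mk likelihoods with equal-rates/all-rates-differ model
    selection, stochastic character mapping with ancestral-state summaries,
    the Fritz-Purvis D statistic with permutation and Brownian-threshold
    nulls, Bray-Curtis dissimilarity, Mantel tests, and non-metric
    multidimensional scaling. Seed-deterministic simulators generate
    clade-structured ultrametric trees, binary traits, compositional
    profiles, and MGF spectra for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
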