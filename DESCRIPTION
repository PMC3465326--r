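Package: finitesites
Title: Finite-Sites Population Genetics with Among-Site Rate Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Polymorphism summaries and tests of neutral equilibrium for
    single-locus sequence data that violate the infinite-sites and
    uniform-rate assumptions, as is typical of the mitochondrial control
    region. Provides classical summaries (haplotype and nucleotide
    diversity, segregating sites, the minimum number of mutations,
    Watterson's estimator), gamma-rate finite-sites corrected estimators of
    the neutral parameter based on pairwise differences, segregating sites
    and the minimum number of mutations, Tajima's D with its beta
    approximation, Fu's Fs, and a corrected D-type statistic. A built-in
    neutral coalescent simulator (constant size or exponential growth;
    infinite-sites or HKY85/GTR mutation with discrete-gamma rates and
    invariant sites) generates empirical null distributions and synthetic
    data sets. Sliding-window statistics and per-site parsimony change
    counts support locus comparison and mutational hotspot detection.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
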