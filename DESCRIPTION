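Package: wujoint
Title: Similarity-Based Weighted U Tests for Joint SNV-Set and Gene
    Expression Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-region association testing that jointly models rare and
    common single-nucleotide variants (SNVs) and gene expression against
    quantitative or binary phenotypes with a similarity-based weighted
    U statistic. Per-sample burden scores up-weight rare variants by
    1/sqrt(p(1-p)), Gaussian kernels translate burden and expression
    distances into pairwise similarities, and a rank-based phenotype
    kernel makes the statistic distribution-free. Three test modes are
    provided (genotype-only, expression-only, and joint), with p-values
    from a chi-square/gamma-mixture approximation to the exact
    permutation null, calibrated with closed-form permutation moments
    and a Davies-type characteristic-function inversion. Includes a
    genome-screen driver with covariate and principal-component
    adjustment and Benjamini-Hochberg false discovery rate control, a
    region builder applying gene +/- flank SNV assignment and
    monomorphic-site filters, readers for VCF/GFF3/BED/TSV inputs, a
    synthetic-data generator mirroring the assumed generative model,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
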