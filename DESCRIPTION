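Package: ecoassembly
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring the ecological processes that assemble
    microbial communities along environmental gradients from an ASV table,
    a rooted phylogeny and sample metadata. Implements scaling with ranked
    subsampling (SRS) normalization, taxonomic and phylogenetic alpha
    diversity (Shannon, Gini-Simpson, Faith's PD, ses.PD, NTI), pairwise
    beta diversity (Bray-Curtis, Jaccard, weighted/unweighted UniFrac),
    the Baselga turnover/nestedness partition of the Jaccard index,
    SIMPER, beta-MNTD/beta-NTI and Raup-Crick (Bray-Curtis) null models
    with the standard classification into variable selection, homogeneous
    selection, dispersal limitation, homogenizing dispersal and drift,
    PCoA, one- and two-way PERMANOVA with permutation of residuals,
    PERMDISP, and a synthetic-data generator that emulates a sequential
    gradient-transfer incubation design with controllable phylogenetic
    signal, selection strength, dispersal limitation and drift.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    phyloseq,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
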