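Package: chipgrade
Title: Subsampling-Robustness Quality Grading and Certification of
    ChIP-seq Enrichment Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for ChIP-seq and related enrichment profiles
    based on the robustness of binned read-count intensities to random
    read subsampling. Reads are counted in a fixed 500 nt genomic grid,
    random subsets (90, 70 and 50 percent of total mapped reads) are
    drawn, and the per-bin dispersion of the observed counts around their
    proportional expectation (dRCI) is summarised as the fraction of
    populated bins within 2.5, 5 and 10 percent dispersion. Scores are
    discretised into three-letter A-D grades against quartile boundaries
    of a reference score collection. The package also extrapolates the
    optimal sequencing depth from the A-to-B grade transition over outer
    read subsamples, computes a local irreproducibility-discovery-rate
    statistic over robust windows of two biological replicates, bundles
    both replicates into an antibody certification report, and ships a
    synthetic mapped-read simulator for sharp-peak and broad-domain
    enrichment landscapes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
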