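Package: breakscape
Title: Site-Anchored Quantification of Chromatin Signal Around Induced
    DNA Double-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed quantification of ChIP-seq and DRIP-seq coverage
    around annotated double-strand break (DSB) sites, as used to study
    protein recruitment and RNA:DNA-hybrid remodeling in restriction
    enzyme-based DSB induction systems (AsiSI/DIvA). Provides cut versus
    uncut enrichment statistics (Mann-Whitney U), transcription-level
    stratification of break sites, binned heatmap matrices, averaged
    site-centered profiles, metagene profiles with scaled gene bodies,
    and qPCR-derived assay quantifications (resection ssDNA percent,
    repair kinetics, delta-delta-Ct translocation frequency, DRIP
    percent input). A synthetic-data module simulates genomes, break
    annotations, coverage tracks and qPCR cycle thresholds with known
    ground truth so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
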