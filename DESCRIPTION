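Package: orthobin
Title: Percentile-Rank Binning and Cross-Species Comparison of Expression Data
Version: 0.1.0
Authors@R:
    person("Orthobin", "Developers", email = "orthobin@example.org",
           role = c("aut", "cre"))
Description: Compares bulk transcriptomes across species on a rank scale.
    Expression matrices (TSV or GEO series-matrix text) are quantile
    normalized between arrays, replicate arrays are averaged, duplicate
    probes are collapsed with a bin-consistency filter, and every gene is
    assigned a percentile rank and one of four expression bins (very low,
    low, moderate, high). Orthologs are matched across two species by gene
    symbol; genes in the high bin of one species and the very low bin of the
    other are called species-specific, subject to a curated (NM_) RefSeq
    accession filter. Additional tools compute high-bin concordance between
    datasets of the same species, tabulate bin profiles of gene sets, and
    generate fully synthetic two-species datasets with planted ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
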