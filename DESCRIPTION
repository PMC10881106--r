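Package: evoindex
Title: Expression-Weighted Evolutionary Indices for Brain Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes expression-weighted evolutionary indices for tissue and
    single-cell transcriptomes: the evolutionary rate index (ERI), a
    TPM-weighted mean of per-gene dN/dS along nested ancestral lineages, and
    the transcriptome age index (TAI), an expression-weighted mean of
    phylostratigraphic gene ages. Includes sample quality control by mapping
    statistics, TPM normalization from counts, aggregation of samples to brain
    regions, developmental windows and cell types, Dollo-style gene-age
    assignment from ortholog presence/absence on a dated species tree,
    cortical versus non-cortical group comparisons with Welch or Student
    t-tests, Pearson correlation diagnostics between dN/dS and expression,
    developmental trajectory peak detection, and a synthetic study generator
    with planted effects for Monte Carlo calibration of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
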