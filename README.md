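# evoindex

Expression-weighted evolutionary indices for brain transcriptomes.

Different brain structures have evolved at different speeds, and the genes a
structure expresses carry the record: a region whose transcriptome is
dominated by fast-evolving or recently emerged genes has, in a concrete
sense, a faster-evolving transcriptome than one dominated by ancient,
conserved housekeeping genes. `evoindex` quantifies this with two
expression-weighted statistics computed per brain region, ancestral lineage,
developmental window or cell type, and provides the QC, normalization,
comparison and calibration machinery around them. It is aimed at molecular
evolution and neuro-genomics groups who have a per-gene table of selection
estimates (dN/dS along nested ancestral lineages) and gene ages on one side,
and bulk or single-cell expression matrices with sample annotations on the
other.

## The two indices

For a set of genes *i = 1…n* with expression *Eᵢ* in a group of samples
(a brain region, a region × developmental-window cell, a cell type):

- **Evolutionary rate index (ERI)**, per ancestral lineage *L*:

  ERI(L) = Σᵢ (dN/dS)ᵢ,L · Eᵢ / Σᵢ Eᵢ

  the expression-weighted mean of the genes' non-synonymous/synonymous
  substitution rate ratios on that lineage. High ERI means the group's
  transcriptome is dominated by rapidly evolving genes.

- **Transcriptome age index (TAI)**:

  TAI = Σᵢ Aᵢ · Eᵢ / Σᵢ Eᵢ

  where *Aᵢ* is the gene's evolutionary age (time before present at which
  the gene originated, assigned by Dollo parsimony on a dated species tree).
  Low TAI means the transcriptome is enriched for evolutionarily young
  genes.

Both weights use untransformed expression (TPM scale) and no expression
cutoff; genes with a missing dN/dS in a lineage are excluded pairwise for
that lineage only.

Around the indices the package implements: sample QC on mapping statistics
(strictly more than 10 million uniquely mapped reads and a unique fraction
strictly above 80%, both configurable), counts→TPM conversion, aggregation
of samples to regions/windows/cell types, Welch or Student t-tests of
cortical vs non-cortical per-region indices, Pearson diagnostics between
dN/dS and expression, developmental trajectory peak detection, Dollo
gene-age assignment from ortholog presence/absence, and a synthetic study
generator with planted effects that lets you calibrate the entire analysis
by Monte Carlo before trusting it on real data.

## Worked example

Simulate a 45-area study with a planted non-cortical excess
(`coupling_delta = 0.5`), run QC, aggregate to regions, and compute and
compare the indices:

```r
library(evoindex)

cfg      <- sim_config(n_genes = 1000, seed = 42)
gene_evo <- simulate_gene_evo(cfg)
study    <- simulate_expression_study(gene_evo, cfg)

meta <- qc_filter_samples(study$meta)          # mapping-stat QC
expr <- study$expr[, meta$sample_id]
region_means <- aggregate_expression(expr, meta, group_by = "region")

eri <- compute_eri_table(gene_evo, region_means)
head(eri, 3)
#>   group    lineage index_kind     value n_genes_used
#> 1   ACB H. sapiens        ERI 0.5323359          979
#> 2    AG H. sapiens        ERI 0.3216723          979
#> 3   AIC H. sapiens        ERI 0.3197473          979

cmp <- compare_region_classes(eri, cfg$regions)
cmp[1:3, c("lineage", "mean_noncortical", "mean_cortical", "t_statistic", "p_value")]
#>      lineage mean_noncortical mean_cortical t_statistic  p_value
#> 1 H. sapiens            0.529         0.319        60.8 1.85e-24
#> 2   Hominini            0.477         0.295       101.0 1.42e-31
#> 3  Homininae            0.441         0.305       175.0 2.21e-55

tai <- compute_tai_table(gene_evo, region_means)
head(tai, 2)
#>   group lineage index_kind    value n_genes_used
#> 1   ACB    <NA>        TAI 23.65754         1000
#> 2    AG    <NA>        TAI 23.02652         1000
```

Each ERI row is one region × lineage: e.g. the accumbens nucleus (ACB, a
non-cortical area) has ERI 0.53 on the terminal human lineage, computed
from the 979 genes with a dN/dS value there, against ~0.32 for cortical
areas — the planted class effect. `compare_region_classes` then tests, per
lineage, the per-region ERIs of non-cortical vs cortical areas (Welch
t-test by default); here every lineage shows the planted non-cortical
excess at vanishing p-values. TAI values are expression-weighted mean gene
ages in million years; lower = younger transcriptome.

The same analyses run from the shell via the thin wrapper
`inst/scripts/evoindex.R` over a YAML config (`simulate`, `qc`, `tpm`,
`ages`, `eri`, `tai`, `compare`, `correlate`, `trajectory`, `calibrate`,
`all`), writing TSV/JSON outputs plus a checksummed run manifest.

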