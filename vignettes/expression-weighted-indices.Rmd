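---
title: "Expression-weighted evolutionary indices: models, assumptions and design"
author: "evoindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted evolutionary indices: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoindex)
```

## The statistics

`evoindex` computes two scalar summaries of the evolutionary character of a
transcriptome. For genes $i = 1 \dots n$ with expression $E_i \ge 0$ in a
group of samples:

$$\mathrm{ERI}_L = \frac{\sum_i (dN/dS)_{i,L}\, E_i}{\sum_i E_i},
\qquad
\mathrm{TAI} = \frac{\sum_i A_i\, E_i}{\sum_i E_i},$$

where $(dN/dS)_{i,L}$ is gene $i$'s ratio of non-synonymous to synonymous
substitution rates on ancestral lineage $L$ (eight nested primate lineages
from the terminal human branch back to Haplorrhini by default), and $A_i$
is the gene's evolutionary age, the time before present at which it
originated. Both are weighted means, so each index always lies within the
range of the per-gene values that enter it, and is invariant to rescaling
all weights by a common factor — which is why per-sample library-size
normalization (TPM) does not distort it.

Interpretation is straightforwardly compositional: a group whose expression
mass sits on fast-evolving genes has a high ERI; a group whose mass sits on
recently emerged genes has a low TAI. Neither index is a test statistic;
inference happens downstream by comparing per-region index values between
region classes.

Three contract decisions shape the implementation:

* **No expression cutoff.** Every gene with positive weight contributes.
  Lowly expressed genes are naturally down-weighted by $E_i$ itself, and a
  cutoff would make the index discontinuous in the data.
* **Pairwise missingness.** A gene missing its dN/dS in lineage $L$ is
  dropped from $\mathrm{ERI}_L$ only; it still contributes to other
  lineages and to TAI. This maximizes the genes used per lineage and
  matches the per-lineage definition of the formula. `n_genes_used` is
  reported per table cell so the effective support is always visible.
* **Undefined is an error.** If, after pairwise removal, no gene carries
  positive weight, the index is undefined and the package raises a typed
  error (`evoindex_undefined_index`) naming the group and lineage rather
  than silently emitting `NaN`.

## From samples to groups

The indices are defined per group (region, region × developmental window,
cell type). Two reduction orders are possible and they do not coincide in
general:

1. **aggregate-then-index** (default): average the member samples'
   expression per gene, then compute one index from the mean profile;
2. **per-sample-then-average**: compute one index per sample, then average
   within the group (optionally with a seeded percentile bootstrap CI).

The first path keeps the result a genuine weighted mean of per-gene values
(the group profile is itself an expression vector), which is why it is the
default for one-value-per-area reporting. The two paths agree exactly when
every sample in a group has the same total weight, and differ otherwise;
`compare_index_modes()` computes both and reports the discrepancy instead
of hiding the choice. For single-cell input the same machinery applies with
cell types as groups over depth-normalized per-cell profiles (pseudobulk
means); the package makes no claim about which summary a given published
figure used — both are exposed.

Group reduction is the arithmetic mean of TPM by default (median behind a
flag). The mean preserves linearity, so the group index remains
interpretable as an expression-weighted mean over the pooled samples.

## Sample QC and normalization

Samples are gated on mapping statistics: strictly more than
`min_unique_reads` uniquely mapped reads (default $10^7$) *and* a uniquely
mapped fraction strictly above `min_unique_fraction` (default 0.8). The
inequalities are strict — a sample sitting exactly on a threshold is
removed — and the filter refuses to run if any sample lacks mapping stats,
because a silent pass is the one failure mode QC must not have. Every
removed sample is logged with the specific criterion it failed. The filter
is idempotent.

TPM conversion follows the standard two-step normalization: per sample,
counts are divided by gene length (in bases) to per-base rates, then rates
are scaled to sum to $10^6$. All-zero libraries are left at zero and
flagged rather than producing `0/0`.

## Gene ages: Dollo assignment on a dated tree

Gene ages come from ortholog presence/absence on an ultrametric, dated
species tree. Under the Dollo assumption (a gene family originates once and
can only be lost), the origin of a gene is the most recent common ancestor
of the focal species and all carriers, i.e. the deepest node on the
focal-to-root path that subtends any carrier; $A_i$ is that node's age.
Consequences worth stating explicitly:

* ages take values only in the discrete set of focal-path node ages;
* adding a carrier can only deepen (never lower) an assignment;
* under loss-only evolution the rule can only *under*-date: a gene whose
  deepest carriers all lost the ortholog is assigned a younger node. The
  test suite quantifies this one-sided bias on simulated data.
* genes found only in the focal species are assigned the focal leaf, age 0.
  They are the youngest stratum; any positive constant would be arbitrary
  and would leak into TAI.

The default tree is an eight-taxon pectinate primate tree with round
TimeTree-style node ages (6.7 to 64 Mya). Node ages are read off the tree
by depth, after checking ultrametricity to a relative tolerance of $10^{-6}$
(the worst leaf-depth deviation is reported on failure); leaf ages are then
clamped to exactly 0 so that float dust in branch lengths cannot create a
spurious youngest stratum. TAI comparisons only require a monotone age
encoding, so any consistent alternative (e.g. phylostratum ranks) preserves
orderings; the package standardizes on time before present, where *older =
larger*, so that "low TAI = young transcriptome".

## Inference

**Class comparison.** Per lineage, the per-region ERI values of
non-cortical regions are tested against cortical regions with a two-sample
t-test. Welch's unequal-variance form is the default — the two classes are
anatomically heterogeneous collections with no reason to share a variance —
with the pooled Student form behind a flag. Tests are two-sided by default;
the directional alternative (non-cortical greater) is available but
deliberately not the default, since a conservative default should not
presuppose the effect it is testing. When both classes are constant the
closed form applies ($t = 0$, $p = 1$ on equality). Raw per-lineage
p-values are reported; a Benjamini–Hochberg column is emitted alongside so
users who want multiplicity control across the eight lineages have it
without it being silently imposed.

**Correlation diagnostic.** Because ERI weights dN/dS by expression, a
strong correlation between the two would make the index partly an
expression artifact. `dnds_expression_correlation()` reports the Pearson
correlation per group × lineage (untransformed expression by default,
`log1p` behind a flag), with pairwise missing exclusion; degenerate inputs
(fewer than 3 complete genes, zero variance) yield a flagged row, not an
error.

**Developmental peaks.** For region × window trajectories, the peak is the
argmax over windows for ERI and the argmin for TAI (the "youngest
transcriptome" reading). Exact ties break toward the earliest window, a
deterministic rule that also pins down the degenerate all-equal case. The
window order is the configured developmental scheme; the default preset is
eight windows spanning 12 post-conception weeks to 64 postnatal years, with
w5–w8 carrying the conventional spans (late fetal, late infancy/early
childhood, childhood, adolescence+). Peak detection is invariant to adding
a constant to all values and makes no smoothness assumption — with very few
samples per cell it will happily report a noise peak, which is exactly what
the Monte Carlo calibration below is for.

## The synthetic study generator

The generator produces every input the pipeline consumes, with known
ground truth, so each downstream stage can be validated end to end. What it
emulates, and how:

* **dN/dS tables**: per lineage, gamma-distributed values (default shape 2,
  scale 0.125; mean 0.25, a typical genome-wide purifying-selection level)
  multiplied by a per-gene gamma rate factor with mean 1 (default shape 2).
  The shared factor induces the cross-lineage correlation real ortholog
  tables show — a gene under weak constraint is fast on most lineages. A
  configurable fraction of cells (default 2%) is set missing.
* **Gene ages**: drawn uniformly from the focal-path node ages of the
  species tree, optionally rank-correlated with the rate factor
  (`age_rate_cor`, default 0 so that ERI and TAI tests stay orthogonal).
* **Expression**: log-normal per gene and sample around a per-gene baseline
  (log-mean 2, log-sd 1.0, noise sd 0.5). The planted class effect is a
  log-linear tilt: non-cortical samples shift gene $i$'s log-expression by
  `coupling_delta` · $z_i$, where $z_i$ is the standard score of the gene's
  mean dN/dS across lineages. Tilting by the *mean* rather than a single
  reference lineage is a deliberate design choice: the shared rate factor
  then propagates the planted excess to every lineage's ERI, the pattern
  the class comparison is meant to detect; a single reference lineage
  remains available via `reference_lineage`. The same mechanism, scaled by
  a tent profile peaking at the configured window (`window_coupling`,
  default 0.5), plants the developmental peak.
* **Mapping statistics**: total reads negative binomial (mean 3.5·10⁷,
  size 15), unique fraction beta(60, 6). Non-planted samples are
  rejection-sampled to pass the QC thresholds with a small safety margin,
  so the `n_qc_fail` planted failures — alternating read-count and
  fraction violations, each recorded with its criterion — are *exactly*
  the failures QC must find. Exact bookkeeping beats realism here because
  the QC tests need exact expected counts.
* **Presence/absence**: each gene originates uniformly on the focal path
  and evolves by pure loss (per-branch probability `loss_rate`, default
  0.1), with the focal path immune so every gene is observable.

Defaults were fixed once to make the default study a plausible miniature of
a 45-area primate brain design: 20 non-cortical + 25 cortical areas, 13
samples per area (585 samples), 2000 genes. The coupling defaults
(`coupling_delta = 0.5`, `window_coupling = 0.5`) were chosen so that the
planted effects are unambiguous at these sizes — the generator's own
contract is that the planted ERI excess is positive in expectation for
every lineage, and the expected per-lineage excess is computed analytically
and stored in the returned truth object. An early draft used stronger
couplings and heavier-tailed expression; the exponential tilt then
concentrated weight on a handful of fast genes, the effective number of
genes behind each index collapsed, and single lineages could flip sign —
violating that contract. The final defaults keep the effective support
broad (index values ≈ 0.3 against a mean dN/dS of 0.25).

What the generator does **not** emulate: gene–gene expression correlation
structure, compositional noise of real RNA-seq (counts are bypassed
entirely unless the TPM path is exercised), region-specific expression
programs beyond the planted couplings, batch effects, and any realistic
relationship between a gene's age and its expression breadth. Passing the
Monte Carlo checks therefore shows the *pipeline* is correct and
calibrated under a clean generative model — it does not validate the
biological conclusions one would draw from real data.

## Monte Carlo calibration

`run_null_calibration()` repeats the full
simulate → aggregate → ERI → t-test chain over replicate studies and
reports per-lineage rejection rates with exact binomial CIs. With
`coupling_delta = 0` this measures the empirical type-I error of the whole
pipeline (it should sit near the nominal $\alpha$); with a positive
coupling it measures power. Replicate $r$ uses seed `config$seed + r`, so
the whole calibration is reproducible from one integer.

Problem sizes for the package's own calibration runs were chosen as the
smallest designs that still exercise every stage: 300 genes, 12 regions
(6 + 6), 2 samples per region for the null (2000 replicates); a larger
20 + 25-region design with `coupling_delta = 0.5` for power (200
replicates); and the full default presets for the single end-to-end
pattern checks. These sizes are statements about sufficiency — the null
level and power stabilize well below them — not about any particular
machine.

## Numerical and degenerate-input policy

* Weighted means are computed in double precision with no compensated
  summation; the oracle-equivalence tests bound the discrepancy against a
  naive loop at $10^{-12}$ relative, and the convexity bound holds up to
  float rounding ($\sim 10^{-15}$ relative).
* TPM validity is checked as column sums within relative $10^{-6}$ of
  $10^6$; all-zero columns are exempt and flagged.
* TSV writers emit 15 significant digits, UTF-8, LF endings; write/read
  round trips are stable to ~$10^{-15}$ relative.
* Determinism: one master seed per study object; sub-generators use fixed
  offsets (+1 gene table, +2 expression, +3 presence/absence), calibration
  replicates add the replicate number. Identical seeds give bit-identical
  objects, and the pipeline runner produces byte-identical output files on
  rerun (manifests record checksums, not timestamps).
* Degenerate inputs are typed errors with named offenders: negative
  expression, duplicate identifiers, non-ultrametric trees (worst deviation
  reported), genes absent from the focal species, classes with fewer than
  two regions, unknown window labels.

## Known limitations

* The Dollo age assignment is a deliberate simplification of full
  phylostratigraphy: no homology-search error model, no gain-twice or
  horizontal-transfer scenarios, and a discrete age support bounded by the
  tree's root age.
* ERI inherits every bias of the upstream dN/dS estimates; the package
  treats them as given and offers only the correlation diagnostic, not a
  correction. No phylogenetic non-independence correction across lineages
  is attempted — the eight lineages are nested and their ERIs are
  correlated by construction.
* The t-test treats regions as exchangeable units; spatially adjacent brain
  areas are not independent, and no spatial correction is provided.
* The per-sample index mode reports bootstrap CIs over samples, which
  ignore uncertainty in the per-gene evolutionary values themselves.
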