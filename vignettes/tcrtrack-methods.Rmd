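---
title: "Methods: quantifying tumor-reactive T-cell repertoires with tcrtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-reactive T-cell repertoires with tcrtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtrack)
```

# The problem

A tumor-reactive CD8 T cell can be identified functionally in blood — it
proliferates when stimulated with dendritic cells loaded with autologous
tumor lysate — but whether such cells actually reach the tumor must be read
out from sequence. Because each T cell carries an essentially unique T-cell
receptor (TCR), the CDR3 amino-acid sequence of the receptor's beta (or
alpha) chain acts as a barcode: if a CDR3 observed in the blood-derived
tumor-reactive compartment reappears among tumor-infiltrating lymphocytes
(TILs), that TIL clonotype is, with high confidence, tumor-reactive.

`tcrtrack` implements this tracking analysis end to end on bulk TCR
clonotype tables: abundance filtering, repertoire descriptive statistics,
CDR3 specificity clustering, exact and cluster-extended blood-to-tumor
matching, pathogen annotation under HLA restriction, the accompanying
wet-lab assay formulas, and a binned-control signature score for single-cell
expression data. A synthetic cohort generator with planted ground truth
makes every stage testable without patient material.

# Data model and filtering

A **clonotype** is the unit of analysis: the combination of V gene, J gene
and CDR3 amino-acid sequence on one chain, with a read/UMI count. Tables are
ingested from AIRR Rearrangement TSV or MiXCR-export TSV
(`readClonotypes()`); gene calls are truncated at the first `*` to gene
level, because allele-level assignments from short bulk reads are not
reliable and all downstream statistics are at gene resolution. CDR3s with
stop codons or non-standard residues are dropped with a logged count.
Counts are taken as given — UMI correction belongs to the upstream
assembler, and re-collapsing here would double-correct.

`filterClonotypes()` first aggregates duplicate (chain, V, J, CDR3) keys by
summing counts, then removes clonotypes with aggregated count below
`minCount = 10`. Aggregation-before-threshold matters: two records of the
same clonotype with counts 6 and 5 represent 11 observations and survive.
The threshold of 10 reads/UMIs is the conventional guard against
cross-talk and PCR artifacts in bulk TCR libraries.

# Diversity statistics

On the filtered table, with clonotype proportions $p_i$:

* **Shannon diversity** $H = -\sum_i p_i \ln p_i$ (`shannonDiversity()`),
  reported in nats. The base is configurable; natural log is the default in
  repertoire analysis, and the filtered table is used throughout so that
  every statistic describes the same clonotype set.
* **Top-N occupancy** (`topNOccupancy()`): the percentage of repertoire
  space held by the N = 10 most expanded clonotypes. Ties at the N-th rank
  are broken by lexicographic CDR3 order so the statistic is deterministic;
  fewer than N clonotypes saturates at 100%.
* **V–J usage** (`vjUsage()`): relative frequency of each V–J
  rearrangement, counting each unique clonotype once by default (the
  convention of per-clonotype Circos displays); count-weighted mode is
  available. Rendering is left to dedicated plotting packages — the
  long-format matrix is the output.
* **Shared-CDR3 overlap** (`pairwiseSharedCDR3()`): a symmetric matrix of
  unique CDR3 strings shared between samples, the "public vs private"
  readout.

# Specificity clustering (GLIPH2-style)

TCRs with near-identical CDR3s, or CDR3s sharing an unusually enriched
interior motif, tend to recognize the same epitope. `buildClusters()`
groups CDR3s with two edge types over the pooled, labeled input sets:

* **Global edges** (`globalPairs()`): equal full length and Hamming
  distance ≤ 1 over the *interior* — the CDR3 minus its first `nHead = 3`
  and last `nTail = 2` framework-proximal residues.
* **Local edges** (`enrichedMotifs()`): both interiors contain a motif
  (k-mer, k ∈ {2,3,4}) that is enriched in the analysis set relative to a
  reference repertoire: at least `minOcc = 3` occurrences (counted once per
  unique CDR3), fold enrichment ≥ `minFold = 10` (with pseudocount 1 in the
  reference numerator when the reference count is zero), and one-sided
  Fisher exact p ≤ `maxP = 0.001`, computed in closed hypergeometric form.

Clusters are the connected components, numbered deterministically by each
component's lexicographically first member, so results are invariant to
input order. Published analyses of this kind rarely report the parameter
values they ran with, so these defaults follow the published GLIPH2
conventions and every one is exposed as an argument; only parameter
*sensitivity* is testable, not numeric concordance with any specific
published cluster count. The reference repertoire is
user-supplied; the pipeline's default fallback is the pooled
non-reactive TIL background of the other patients, since no bundled naive
reference can be redistributed. With no reference, only global edges are
used. Both edge types are retained and reported per edge, since the
published analysis does not state which type drove its "similar but not
identical" sequences.

# Blood-to-tumor tracking

`exactMatchFraction()` computes the headline statistic: the number of
unique TIL clonotypes whose CDR3 exactly matches any blood tumor-reactive
CDR3, divided by the total number of unique TIL clonotypes (the
≥10-count-filtered table — the only table the rest of the analysis uses, so
every statistic describes the same clonotype set). Matching is CDR3-only, following the "fully matched
sequence" convention — a CDR3 observed with two V genes in the tumor counts
as two matched clonotypes. Counting *clonotypes* in the numerator keeps
numerator and denominator in the same units; a `countSequences` flag
switches to counting distinct CDR3 strings, and `requireVJ` adds V/J
identity for stricter matching.

`clusterExtendedFraction()` additionally counts TIL CDR3s that share a
specificity cluster with a reactive CDR3 without matching exactly
(`expandReactiveSet()`), so the extended fraction is ≥ the exact fraction
by construction. Extension defaults to the beta chain: the alpha chain's
shorter, less constrained CDR3 makes similarity grouping much less
specific, so TRA tracking uses exact matching unless extension is requested
explicitly.

`pathogenFraction()` annotates TIL clonotypes against a VDJdb-format
epitope table: a clonotype is pathogen-specific when its CDR3 completely
matches a record whose antigen species is on the pathogen list (host
"HomoSapiens" records are excluded) *and* whose restricting HLA allele
matches the patient's typing — two-field exact, or group-level prefix when
the record is low-resolution, because public databases mix resolutions.

Patients with no detectable blood-reactive repertoire are reported as
missing, not zero: "no measurable circulating response" and "low
tumor-reactive TIL" are different findings. `cohortReport()` groups
per-patient fractions by lymph-node status (ND excluded from grouping,
retained per patient) and histology, reporting group medians and a
rank-based two-group p-value as a labeled descriptive convenience, without
multiplicity correction, mirroring per-figure testing practice.

# Assay formulas

* Relative proliferation: `max(0, f_loaded − f_unloaded)` of CFSE-low
  CD25+ frequencies; the responder call is strictly `f_loaded >
  f_unloaded`, so equality is a non-response.
* Percent cytotoxicity: $100 - \frac{\%T/\%R}{\%T_{ctrl}/\%R_{ctrl}}
  \times 100$. Left unclamped by default: negative values record target
  outgrowth, which a clamp would silently erase (a `clamp` flag exists).
* Relative green intensity: coculture TII minus both monoculture TIIs,
  elementwise over timepoints.
* Poisson sampling adequacy: the probability of missing a clone at
  frequency $f$ when sequencing $n$ cells is $e^{-nf}$; at $n = 5\times
  10^5$, $f = 10^{-4}$ this is $1.93\times 10^{-22}$ — sampling 15% of a
  T-cell line retains repertoire diversity.
* Antigen expression: a gene counts as expressed at value ≥ 5 (inclusive),
  on the scale the table is provided in (normalized read counts); shared
  antigens are the intersection of per-group unions ("expressed by at least
  one line in each subtype") or of all samples.

# Binned-control signature score

`moduleScore()` scores each cell for a gene signature against
expression-matched controls: genes are ranked by mean expression (ties by
gene name) and cut into `nBins = 24` equal-size bins (remainder to the
lowest bins); each signature gene contributes `nCtrl = 100` genes sampled
from its bin, excluding signature genes, with replacement when the bin's
pool is smaller; the pooled control set is deduplicated and the score is
the cell's mean signature expression minus its mean control expression.
Controls are pooled rather than paired per signature gene, following the
established module-score convention. The subtraction cancels cell-wide
shifts (library size after `logNormalize()`), and bin-matching cancels the
expression-level dependence of dropout. Scoring is bit-reproducible given a
seed, and the caller's RNG state is never touched.

The signature gene list is an input: the neoantigen-specificity signature
used in published reanalyses is imported from its original source by the
user, and no specific list (nor the seed such analyses used) is printed
anywhere, so numeric concordance with published score distributions is not
attainable — the procedure, not the numbers, is what is reproduced here.
`topClusterFrequency()` then identifies the cluster with the highest mean
score (ties broken by label order and flagged) and reports each patient's
percentage of cells in it. `purifyCD8()` applies the standard cleanup:
cells with CD4 > 0.5 and CD8 = 0 are removed, as are cells with more than
5,000 detected genes.

# The synthetic cohort: what it emulates, and what it does not

`simulatePairedCohort()` generates the study design the analysis assumes:
15 patients (5 lymph-node positive, 10 negative), each with a blood
tumor-reactive repertoire of 47 clonotypes (the typical per-patient unique
CDR3β yield of a tumor-reactive line) and a TIL repertoire of 1000
clonotypes. A fraction θ of TIL clonotypes copies reactive CDR3s — θ = 0.04
in node-negative and 0.01 in node-positive patients, matching the direction
and rough scale of the observed few-percent tumor-reactive TIL medians and
their reduction under nodal metastasis (0.04 rather than 0.05 so the
planted set never exceeds the 47-clonotype reactive repertoire). Five
near-miss CDR3s per patient differ from a reactive CDR3 by exactly one
interior residue (recoverable only by cluster extension), and 1% of TIL
CDR3s are copied from pathogen epitope records compatible with the
patient's simulated HLA typing.

CDR3s are built as `C` + uniform-residue interior + `F` with lengths 8–20
peaked at 14–15; an optional positional-bias mode plants motifs for
enrichment testing. Clone counts are drawn i.i.d. from a discrete power law
$P(k) \propto k^{-s}$ with $s = 2$, truncated below at the filter threshold
so that filtering is tested separately via an explicit low-count injection
mode (`lowCountFraction`); smaller exponents give heavier tails and higher
top-clone occupancy. All randomness flows from one root seed through
`splitSeed()`, so any sub-simulation can be regenerated independently.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: VDJ recombination biology (no insertion/deletion
machinery, no convergent recombination, no germline-encoded motif
structure), sequencing error, cross-sample contamination, shared public
clonotypes between patients, or the correlation between clone size and
tumor reactivity. Recovery of θ here demonstrates correctness of the
counting pipeline, not robustness to those real-world effects.

`simulateExpression()` produces negative-binomial counts (lognormal gene
means, dispersion size 2) with signature genes' means multiplied by
$e^\delta$ in a designated cell subset — enough structure to validate
binned-control scoring, but with none of the gene–gene correlation of real
single-cell data.

# Numerical and design choices

* Fisher p-values use the closed hypergeometric tail, cross-checked in the
  test suite against `fisher.test`.
* Connected components are delegated to `igraph`; the test suite verifies
  them against a brute-force transitive-closure oracle.
* Degenerate inputs are errors, not silent values: empty repertoires have
  undefined diversity and undefined match fractions; empty HLA typings are
  rejected; zero-total cells are excluded from normalization with a
  warning.
* Problem sizes in the test suite and acceptance script — cohorts of 15
  patients with 1000-clonotype TIL repertoires, 20-seed recovery runs,
  100-instance clustering oracles, 100-seed spike-detection runs on
  2000 × 500 matrices — were chosen as the smallest sizes at which the
  targeted properties (±0.02 recovery of θ, ≥ 99% spike detection,
  ≥ 95% group-ordering) are comfortably identifiable.
* The package exposes its functionality as an R API plus `runPipeline()` /
  `validateConfig()` over a YAML config, rather than a shell entry point:
  its users work inside R, where the objects (repertoires, cluster sets,
  reports) are the interface.

# Known limitations

Only bulk, single-chain clonotype tables are handled — no paired-chain
single-cell linking, no nucleotide-level CDR3s, no read-level assembly.
Cluster extension inherits GLIPH2's central caveat: similarity predicts
shared specificity statistically, not per sequence. HLA matching ignores
loci beyond class-I A/B/C. The grouped statistics are descriptive; the
package deliberately stops short of clinical inference.
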