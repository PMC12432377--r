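# tcrtrack

Tracking tumor-reactive T-cell receptor repertoires from blood to tumor.

## The problem

Blood CD8 T cells that proliferate against autologous tumor lysate are
functionally tumor-reactive, but that assay says nothing about whether those
cells infiltrate the tumor. Their T-cell receptors do: the CDR3 amino-acid
sequence of each clonotype (V gene + J gene + CDR3) is a sequence barcode,
and a tumor-infiltrating lymphocyte (TIL) clonotype whose CDR3 matches a
blood-derived tumor-reactive CDR3 marks a tumor-reactive cell inside the
tumor. `tcrtrack` implements this tracking analysis for bulk TCR clonotype
tables, for immunologists quantifying antitumor repertoires across paired
blood/tumor samples.

The core statistics, per patient and chain:

- **Exact tumor-reactive TIL fraction** — unique TIL clonotypes whose CDR3
  exactly matches a blood tumor-reactive CDR3, over all unique TIL
  clonotypes (both sets filtered to clonotype count ≥ 10).
- **Cluster-extended fraction** — additionally counts TIL CDR3s that share a
  GLIPH2-style specificity cluster with a reactive CDR3: clusters are
  connected components over *global* edges (equal length, Hamming ≤ 1 on the
  CDR3 interior, i.e. trimming 3 head and 2 tail residues) and *local* edges
  (a shared interior k-mer, k ∈ {2,3,4}, enriched vs a reference repertoire:
  ≥ 3 occurrences, fold ≥ 10, one-sided Fisher p ≤ 10⁻³).
- **Pathogen-specific fraction** — TIL CDR3s completely matching a
  VDJdb-format record of pathogen category whose restricting HLA allele
  matches the patient's class-I typing (two-field exact, or group-level
  prefix for low-resolution records).

Around these sit repertoire descriptives (Shannon index H = −Σ pᵢ ln pᵢ,
top-10 clonal occupancy, V–J usage, pairwise shared-CDR3 overlap), the
accompanying assay formulas (relative proliferation with negatives clamped
to zero and a strict responder rule; % cytotoxicity =
100 − ((%target/%ref)/(%target_ctrl/%ref_ctrl) × 100); Poisson sampling
adequacy e^(−nf); inclusive ≥ 5 antigen-expression cutoff), a binned-control
gene-signature score for single-cell matrices, and a synthetic paired-cohort
generator with planted ground truth. See the methods vignette
(`vignettes/tcrtrack-methods.Rmd`) for the full model description.

## Worked example

Simulate a paired cohort under the default study design (15 patients, 5
lymph-node positive; true shared-clonotype fraction θ = 0.04 node-negative
vs 0.01 node-positive), then track one patient's repertoire:

```r
library(tcrtrack)

ch <- simulatePairedCohort(cohortConfig(seed = 42))
f  <- filterClonotypes(ch$til$P06)          # count >= 10 filter
diversitySummary(f)
#>   sample_id n_unique_clonotypes n_unique_cdr3 shannon_H top_n_occupancy_pct
#> 1   P06_til                1000          1000   5.16387            38.86589

rC <- unique(clonotypes(ch$reactive$P06)$cdr3_aa)
tC <- unique(clonotypes(ch$til$P06)$cdr3_aa)
cs <- buildClusters(list(reactive = rC, til = tC))
cs
#> MotifClusterSet: 1007 nodes, 5 edges (5 global, 0 local), 1002 clusters
#>   0 enriched motifs retained

rep <- clusterExtendedFraction(ch$reactive$P06, ch$til$P06, cs)
rep <- mergeReports(rep, pathogenFraction(ch$til$P06, ch$epitopeDb, ch$hla$P06))
rep
#> SpecificityReport: patient P06, TRB
#>   TIL clonotypes: 1000; exact 40 (0.040), extended 45 (0.045), pathogen 0.010
```

The exact fraction 0.040 recovers the planted θ = 0.04 for this
node-negative patient; the five extra extended matches are the planted
near-miss CDR3s (one interior mismatch from a reactive CDR3), and the
pathogen fraction recovers the 1% HLA-compatible epitope-database spike.
Cohort-wide, the grouped report reproduces the designed ordering — fewer
tumor-reactive TIL under lymph-node metastasis:

```r
reports <- lapply(names(ch$til), function(pid)
  exactMatchFraction(ch$reactive[[pid]], ch$til[[pid]]))
cohortReport(reports, ch$metadata)$by_lymph_node
#>   group median_fraction  n
#> 1    no            0.04 10
#> 2   yes            0.01  5
```

Real data enter through `readClonotypes()` (AIRR or MiXCR-export TSV),
`readVDJdb()`, `readHLA()`, `readMetadata()`, and the whole analysis runs
from one YAML config via `runPipeline()` (see `?runPipeline`).

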