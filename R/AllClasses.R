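#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.validChain <- function(chain) chain %in% c("TRA", "TRB")

#' RepertoireTable: a clonotype repertoire for one sample
#'
#' The central container of the package: a deduplicated-or-raw table of
#' clonotypes (chain, V gene, J gene, CDR3 amino-acid sequence, abundance
#' count) for a single sample, together with sample annotation and derived
#' per-clonotype proportions.
#'
#' A clonotype is the unit used throughout: the combination of V gene, J gene
#' and CDR3 amino-acid sequence on one chain, carrying a read/UMI count.
#' Proportions are recomputed whenever the clonotype set changes and sum to 1
#' over the included clonotypes.
#'
#' @slot sampleID character(1) sample identifier.
#' @slot patientID character(1) patient identifier.
#' @slot compartment character(1); one of "blood_reactive", "til", "other".
#' @slot clonotypes a \link[S4Vectors]{DataFrame} with columns
#'   \code{chain}, \code{v_gene}, \code{j_gene}, \code{cdr3_aa},
#'   \code{count}, \code{proportion}.
#'
#' @seealso [RepertoireTable()] constructor, [filterClonotypes()],
#'   [shannonDiversity()], [clonotypes()]
#' @export
setClass("RepertoireTable",
  slots = c(
    sampleID    = "character",
    patientID   = "character",
    compartment = "character",
    clonotypes  = "DataFrame"
  )
)

setValidity("RepertoireTable", function(object) {
  cl <- object@clonotypes
  need <- c("chain", "v_gene", "j_gene", "cdr3_aa", "count", "proportion")
  if (!all(need %in% colnames(cl)))
    return(paste("clonotypes must have columns:", paste(need, collapse = ", ")))
  if (!object@compartment %in% c("blood_reactive", "til", "other"))
    return("compartment must be blood_reactive, til or other")
  n <- nrow(cl)
  if (n > 0L) {
    if (!all(.validChain(cl$chain)))
      return("chain must be TRA or TRB")
    if (any(cl$count < 0)) return("counts must be non-negative")
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cl$cdr3_aa) | nchar(cl$cdr3_aa) < 5L
    if (any(bad))
      return("cdr3_aa must be standard amino acids only, length >= 5")
    vok <- (cl$chain == "TRA" & startsWith(cl$v_gene, "TRAV")) |
           (cl$chain == "TRB" & startsWith(cl$v_gene, "TRBV"))
    jok <- (cl$chain == "TRA" & startsWith(cl$j_gene, "TRAJ")) |
           (cl$chain == "TRB" & startsWith(cl$j_gene, "TRBJ"))
    if (!all(vok)) return("v_gene prefix inconsistent with chain")
    if (!all(jok)) return("j_gene prefix inconsistent with chain")
    if (sum(cl$count) > 0 && abs(sum(cl$proportion) - 1) > 1e-9)
      return("proportions must sum to 1")
  }
  TRUE
})

#' MotifClusterSet: CDR3 similarity clusters
#'
#' Result of GLIPH2-style specificity grouping: unique CDR3 sequences (nodes)
#' joined by local edges (sharing an enriched interior motif) and/or global
#' edges (same length, at most one interior mismatch), partitioned into
#' connected components.
#'
#' @slot nodes a \link[S4Vectors]{DataFrame}: \code{cdr3_aa}, \code{cluster},
#'   and one logical origin column per input sample label
#'   (e.g. \code{from_reactive}).
#' @slot edges a \link[S4Vectors]{DataFrame}: \code{from}, \code{to} (CDR3
#'   strings), \code{type} ("global" or "local"), \code{motif} (NA for
#'   global edges).
#' @slot motifs a \link[S4Vectors]{DataFrame} of retained enriched motifs with
#'   their counts, fold enrichment and Fisher p-values.
#' @slot params list of clustering parameters used.
#'
#' @seealso [buildClusters()], [expandReactiveSet()], [clusterMembership()]
#' @export
setClass("MotifClusterSet",
  slots = c(
    nodes  = "DataFrame",
    edges  = "DataFrame",
    motifs = "DataFrame",
    params = "list"
  )
)

setValidity("MotifClusterSet", function(object) {
  nd <- object@nodes
  if (!all(c("cdr3_aa", "cluster") %in% colnames(nd)))
    return("nodes must have cdr3_aa and cluster columns")
  if (anyDuplicated(nd$cdr3_aa)) return("node CDR3s must be unique")
  ed <- object@edges
  if (nrow(ed) > 0) {
    if (!all(c(ed$from, ed$to) %in% nd$cdr3_aa))
      return("edge endpoints must be nodes")
    same <- nd$cluster[match(ed$from, nd$cdr3_aa)] ==
            nd$cluster[match(ed$to, nd$cdr3_aa)]
    if (!all(same)) return("edge endpoints must share a cluster")
  }
  TRUE
})

#' SpecificityReport: per-patient clonotype tracking summary
#'
#' Fractions of TIL clonotypes matching blood tumor-reactive CDR3s (exact and
#' cluster-extended) and pathogen-specific database entries under patient HLA
#' restriction. Fields not yet computed are NA; [exactMatchFraction()],
#' [clusterExtendedFraction()] and [pathogenFraction()] each fill their part.
#'
#' @slot patientID character(1).
#' @slot chain character(1), "TRA" or "TRB".
#' @slot nTIL integer(1): unique TIL clonotypes (the denominator).
#' @slot nExact integer(1): TIL clonotypes exactly matching a reactive CDR3.
#' @slot nExtended integer(1): exact plus cluster-similar matches.
#' @slot exactFraction,extendedFraction,pathogenFraction numeric(1) in [0,1]
#'   (NA when not computed).
#' @slot matches \link[S4Vectors]{DataFrame}: \code{cdr3_aa},
#'   \code{match_type} in \{"exact", "cluster", "pathogen"\}.
#'
#' @seealso [exactMatchFraction()], [cohortReport()]
#' @export
setClass("SpecificityReport",
  slots = c(
    patientID        = "character",
    chain            = "character",
    nTIL             = "integer",
    nExact           = "integer",
    nExtended        = "integer",
    exactFraction    = "numeric",
    extendedFraction = "numeric",
    pathogenFraction = "numeric",
    matches          = "DataFrame"
  )
)

setValidity("SpecificityReport", function(object) {
  fr <- c(object@exactFraction, object@extendedFraction, object@pathogenFraction)
  fr <- fr[!is.na(fr)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    return("fractions must lie in [0, 1]")
  if (!is.na(object@exactFraction) && !is.na(object@extendedFraction) &&
      object@extendedFraction < object@exactFraction - 1e-12)
    return("extendedFraction must be >= exactFraction")
  TRUE
})

#' ModuleScoreResult: per-cell binned-control signature scores
#'
#' @slot scores named numeric, one score per cell.
#' @slot params list: n_bins, n_ctrl, seed.
#' @slot signatureUsed character: signature genes present in the matrix and
#'   actually scored.
#' @slot signatureMissing character: requested signature genes absent from
#'   the matrix (reported, never silently dropped).
#'
#' @seealso [moduleScore()], [topClusterFrequency()]
#' @export
setClass("ModuleScoreResult",
  slots = c(
    scores           = "numeric",
    params           = "list",
    signatureUsed    = "character",
    signatureMissing = "character"
  )
)

# ---- constructors ----------------------------------------------------------

#' Construct a RepertoireTable
#'
#' @param clonotypes data.frame or DataFrame with columns chain, v_gene,
#'   j_gene, cdr3_aa, count. Proportions are (re)computed from counts.
#' @param sampleID,patientID sample and patient identifiers.
#' @param compartment "blood_reactive", "til" or "other".
#' @return A [RepertoireTable-class] object.
#' @examples
#' rt <- RepertoireTable(data.frame(
#'   chain = "TRB", v_gene = "TRBV27", j_gene = "TRBJ2-5",
#'   cdr3_aa = "CASSLGQETQYF", count = 12L), sampleID = "s1")
#' nClonotypes(rt)
#' @export
RepertoireTable <- function(clonotypes, sampleID = "sample",
                            patientID = sampleID,
                            compartment = c("other", "blood_reactive", "til")) {
  compartment <- match.arg(compartment)
  cl <- DataFrame(as.data.frame(clonotypes))
  if (nrow(cl) == 0L) {
    cl <- DataFrame(chain = character(), v_gene = character(),
                    j_gene = character(), cdr3_aa = character(),
                    count = integer(), proportion = numeric())
  } else {
    cl$count <- as.integer(cl$count)
    tot <- sum(cl$count)
    cl$proportion <- if (tot > 0) cl$count / tot else rep(0, nrow(cl))
    cl <- cl[, c("chain", "v_gene", "j_gene", "cdr3_aa", "count", "proportion")]
  }
  new("RepertoireTable", sampleID = as.character(sampleID),
      patientID = as.character(patientID), compartment = compartment,
      clonotypes = cl)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn RepertoireTable clonotype table as a DataFrame.
#' @param x a RepertoireTable.
#' @export
clonotypes <- function(x) {
  stopifnot(is(x, "RepertoireTable"))
  x@clonotypes
}

#' @describeIn RepertoireTable number of clonotype rows.
#' @export
nClonotypes <- function(x) nrow(clonotypes(x))

#' @describeIn RepertoireTable sample identifier.
#' @export
sampleID <- function(x) x@sampleID

#' @describeIn RepertoireTable patient identifier.
#' @export
patientID <- function(x) x@patientID

#' @describeIn RepertoireTable compartment label.
#' @export
compartment <- function(x) x@compartment

#' Cluster membership of a MotifClusterSet
#'
#' @param x a [MotifClusterSet-class].
#' @return Named integer vector: cluster id per node CDR3.
#' @export
clusterMembership <- function(x) {
  stopifnot(is(x, "MotifClusterSet"))
  stats::setNames(x@nodes$cluster, x@nodes$cdr3_aa)
}

#' Per-cell scores from a ModuleScoreResult
#'
#' @param x a [ModuleScoreResult-class].
#' @return Named numeric vector of per-cell scores.
#' @export
cellScores <- function(x) {
  stopifnot(is(x, "ModuleScoreResult"))
  x@scores
}

#' Coerce a SpecificityReport to a one-row data.frame
#'
#' @param x a [SpecificityReport-class].
#' @return data.frame with one row per report.
#' @export
reportAsDataFrame <- function(x) {
  stopifnot(is(x, "SpecificityReport"))
  data.frame(
    patient_id        = x@patientID,
    chain             = x@chain,
    n_til_clonotypes  = x@nTIL,
    n_exact_matches   = x@nExact,
    n_extended_matches = x@nExtended,
    exact_fraction    = x@exactFraction,
    extended_fraction = x@extendedFraction,
    pathogen_fraction = x@pathogenFraction,
    stringsAsFactors  = FALSE
  )
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "RepertoireTable", function(object) {
  cl <- object@clonotypes
  cat(sprintf("RepertoireTable: %s (patient %s, %s)\n",
              object@sampleID, object@patientID, object@compartment))
  cat(sprintf("  %d clonotypes, %d unique CDR3, total count %d\n",
              nrow(cl), length(unique(cl$cdr3_aa)), sum(cl$count)))
  if (nrow(cl) > 0) {
    top <- utils::head(cl[order(-cl$count), ], 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s %s/%s %s count=%d\n", top$chain[i], top$v_gene[i],
                  top$j_gene[i], top$cdr3_aa[i], top$count[i]))
  }
})

setMethod("show", "MotifClusterSet", function(object) {
  k <- length(unique(object@nodes$cluster))
  cat(sprintf("MotifClusterSet: %d nodes, %d edges (%d global, %d local), %d clusters\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$type == "global"),
              sum(object@edges$type == "local"), k))
  cat(sprintf("  %d enriched motifs retained\n", nrow(object@motifs)))
})

setMethod("show", "SpecificityReport", function(object) {
  cat(sprintf("SpecificityReport: patient %s, %s\n", object@patientID, object@chain))
  cat(sprintf("  TIL clonotypes: %d; exact %d (%.3f), extended %d (%.3f), pathogen %.3f\n",
              object@nTIL, object@nExact, object@exactFraction,
              object@nExtended, object@extendedFraction, object@pathogenFraction))
})

setMethod("show", "ModuleScoreResult", function(object) {
  cat(sprintf("ModuleScoreResult: %d cells, %d signature genes used (%d missing)\n",
              length(object@scores), length(object@signatureUsed),
              length(object@signatureMissing)))
  cat(sprintf("  n_bins=%d n_ctrl=%d seed=%s; score range [%.3f, %.3f]\n",
              object@params$n_bins, object@params$n_ctrl,
              as.character(object@params$seed),
              min(object@scores), max(object@scores)))
})
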