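# run expr with a private, seeded RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Log-normalize a count matrix
#'
#' Per cell: \code{ln(1 + count / cell_total * scaleTotal)}. Cells with a
#' zero total are flagged with a warning and excluded from the result.
#'
#' @param counts non-negative gene x cell matrix (dense or sparse) with
#'   dimnames.
#' @param scaleTotal library-size scale factor (default 1e4).
#' @return matrix of the same kind, zero-total cells removed.
#' @export
logNormalize <- function(counts, scaleTotal = 1e4) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- Matrix::colSums(counts)
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " zero-total cell(s) excluded")
    counts <- counts[, !bad, drop = FALSE]
    tot <- tot[!bad]
  }
  log1p(sweep_cols(counts, scaleTotal / tot))
}

# multiply each column j by f[j], preserving sparsity and dimnames
sweep_cols <- function(m, f) {
  if (methods::is(m, "Matrix")) {
    out <- m %*% Matrix::Diagonal(x = f)
    dimnames(out) <- dimnames(m)
    out
  } else {
    sweep(m, 2, f, `*`)
  }
}

#' Binned-control gene-signature score per cell
#'
#' Implements the module-score convention used for per-cell signature
#' activity: all genes are ranked by mean expression across cells (ties
#' broken by gene name) and cut into \code{nBins} equal-size expression bins
#' (remainder genes assigned to the lowest bins). For every signature gene,
#' \code{nCtrl} control genes are sampled from its bin, excluding signature
#' genes (with replacement when the bin's non-signature pool is smaller);
#' the sampled controls are pooled into one unique control set. A cell's
#' score is its mean expression over the signature genes minus its mean over
#' the pooled controls, so a shared shift across all genes cancels.
#' Deterministic given \code{seed}; the caller's RNG state is untouched.
#'
#' Signature genes absent from the matrix are reported in the result, never
#' silently dropped; scoring proceeds on the present subset.
#'
#' @param m log-normalized gene x cell matrix with dimnames
#'   (see [logNormalize()]).
#' @param signature character vector of signature gene names (>= 1 present
#'   in the matrix, else an error).
#' @param nBins number of expression bins (default 24).
#' @param nCtrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return A [ModuleScoreResult-class].
#' @export
moduleScore <- function(m, signature, nBins = 24L, nCtrl = 100L, seed = 1L) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  if (anyDuplicated(rownames(m))) stop("gene names must be unique")
  sigUse <- intersect(signature, rownames(m))
  sigMiss <- setdiff(signature, rownames(m))
  if (!length(sigUse)) stop("no signature gene present in the matrix")

  avg <- Matrix::rowMeans(m)
  ord <- order(avg, names(avg))          # rank, ties by gene name
  genes <- names(avg)[ord]
  nG <- length(genes)
  base <- nG %/% nBins
  extra <- nG %% nBins                   # remainder genes to the lowest bins
  sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
  bin <- rep(seq_len(nBins), times = sizes)
  names(bin) <- genes

  ctrl <- .withSeed(seed, {
    picked <- character()
    for (g in sort(sigUse)) {
      pool <- setdiff(genes[bin == bin[[g]]], signature)
      if (!length(pool)) next
      picked <- c(picked,
                  sample(pool, nCtrl, replace = length(pool) < nCtrl))
    }
    unique(picked)
  })
  if (!length(ctrl)) stop("control pool empty: signature covers entire bins")

  sigMean <- Matrix::colMeans(m[sigUse, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  new("ModuleScoreResult",
      scores = stats::setNames(as.numeric(sigMean - ctrlMean), colnames(m)),
      params = list(n_bins = as.integer(nBins), n_ctrl = as.integer(nCtrl),
                    seed = seed, n_ctrl_genes = length(ctrl)),
      signatureUsed = sigUse, signatureMissing = sigMiss)
}

#' Per-patient frequency of the top-scoring cluster
#'
#' Identifies the cell cluster with the highest mean signature score and
#' returns, per patient, the percentage of that patient's cells falling in
#' it. A tie in cluster means is broken deterministically by cluster label
#' sort order and flagged.
#'
#' @param scores a [ModuleScoreResult-class] or a named numeric vector of
#'   per-cell scores.
#' @param clusters per-cell cluster labels (same cells as \code{scores}).
#' @param patients per-cell patient labels.
#' @return list: \code{top_cluster}, \code{tie} (logical),
#'   \code{cluster_means}, and \code{per_patient} data.frame
#'   (patient_id, n_cells, n_in_top, pct_in_top).
#' @export
topClusterFrequency <- function(scores, clusters, patients) {
  s <- if (is(scores, "ModuleScoreResult")) cellScores(scores) else scores
  stopifnot(length(s) == length(clusters), length(s) == length(patients))
  if (anyNA(clusters)) stop("cluster labels must cover all scored cells")
  cm <- sort(tapply(s, as.character(clusters), mean), decreasing = TRUE)
  tie <- sum(abs(cm - cm[1]) < 1e-12) > 1
  topLab <- sort(names(cm)[abs(cm - cm[1]) < 1e-12])[1]
  if (tie) warning("tie in cluster mean scores; taking first label in sort order")
  tab <- data.frame(patient_id = as.character(patients),
                    top = as.character(clusters) == topLab)
  agg <- stats::aggregate(top ~ patient_id, tab,
                          function(v) c(n = length(v), k = sum(v)))
  per <- data.frame(patient_id = agg$patient_id,
                    n_cells = agg$top[, "n"],
                    n_in_top = agg$top[, "k"])
  per$pct_in_top <- 100 * per$n_in_top / per$n_cells
  list(top_cluster = topLab, tie = tie, cluster_means = cm,
       per_patient = per)
}

#' Purify a CD8 T-cell expression matrix
#'
#' Removes contaminating cells: those with CD4 marker expression above
#' \code{cd4Max} and exactly zero CD8 expression, and (quality control)
#' cells with more than \code{maxGenes} detected (nonzero) genes.
#'
#' @param m gene x cell matrix.
#' @param cd8Expr,cd4Expr per-cell marker values (imputation upstream).
#' @param cd4Max CD4 threshold (default 0.5).
#' @param maxGenes detected-gene ceiling (default 5000); NULL disables.
#' @return the matrix with excluded cells removed.
#' @export
purifyCD8 <- function(m, cd8Expr, cd4Expr, cd4Max = 0.5, maxGenes = 5000L) {
  stopifnot(length(cd8Expr) == ncol(m), length(cd4Expr) == ncol(m))
  drop <- cd4Expr > cd4Max & cd8Expr == 0
  if (!is.null(maxGenes))
    drop <- drop | Matrix::colSums(m > 0) > maxGenes
  m[, !drop, drop = FALSE]
}
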