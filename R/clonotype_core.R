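#' Aggregate and filter a clonotype table by abundance
#'
#' Rows are first aggregated by the clonotype key (chain, V gene, J gene,
#' CDR3) with counts summed, then clonotypes whose aggregated count falls
#' below \code{minCount} are removed and proportions recomputed over the
#' survivors. The default threshold of 10 reads/UMIs removes low-confidence
#' clonotypes from bulk TCR libraries.
#'
#' @param x a [RepertoireTable-class] (raw, from [readClonotypes()]).
#' @param minCount integer >= 1; clonotypes with aggregated count below this
#'   are dropped.
#' @return A filtered [RepertoireTable-class] with unique clonotype keys.
#' @examples
#' rt <- RepertoireTable(data.frame(
#'   chain = "TRB", v_gene = "TRBV27", j_gene = "TRBJ2-5",
#'   cdr3_aa = c("CASSLGQETQYF", "CASSLGQETQYF"), count = c(6L, 5L)))
#' nClonotypes(filterClonotypes(rt))   # aggregated to count 11, retained
#' @export
filterClonotypes <- function(x, minCount = 10L) {
  stopifnot(is(x, "RepertoireTable"))
  if (minCount < 1L) stop("minCount must be >= 1")
  cl <- as.data.frame(clonotypes(x))
  if (nrow(cl) > 0L) {
    key <- paste(cl$chain, cl$v_gene, cl$j_gene, cl$cdr3_aa, sep = "\r")
    agg <- rowsum(cl$count, key)
    first <- cl[!duplicated(key), , drop = FALSE]
    first$count <- as.integer(agg[match(paste(first$chain, first$v_gene,
                                              first$j_gene, first$cdr3_aa,
                                              sep = "\r"),
                                        rownames(agg)), 1])
    cl <- first[first$count >= minCount, , drop = FALSE]
    cl <- cl[order(cl$chain, cl$cdr3_aa, cl$v_gene, cl$j_gene), , drop = FALSE]
    rownames(cl) <- NULL
  }
  RepertoireTable(cl, sampleID = sampleID(x), patientID = patientID(x),
                  compartment = compartment(x))
}

#' Shannon diversity of a repertoire
#'
#' H = -sum(p_i log p_i) over clonotype proportions, in nats by default
#' (\code{base} switches the logarithm). Bounded by log(richness).
#'
#' @param x a non-empty [RepertoireTable-class].
#' @param base base of the logarithm (default \code{exp(1)}: nats).
#' @return numeric(1), the Shannon index.
#' @examples
#' rt <- RepertoireTable(data.frame(
#'   chain = "TRB", v_gene = "TRBV27", j_gene = "TRBJ2-5",
#'   cdr3_aa = c("CASSAAAAF", "CASSCCCCF", "CASSDDDDF"),
#'   count = c(10L, 5L, 5L)))
#' shannonDiversity(rt)   # 1.0397
#' @export
shannonDiversity <- function(x, base = exp(1)) {
  p <- clonotypes(x)$proportion
  if (length(p) == 0L) stop("diversity undefined for an empty repertoire")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Repertoire space occupied by the top n clonotypes
#'
#' Sum of the proportions of the n most abundant clonotypes, as a percent.
#' Ties at the n-th rank are broken by lexicographic CDR3 order so the
#' statistic is deterministic; a repertoire with fewer than n clonotypes
#' returns 100.
#'
#' @param x a non-empty [RepertoireTable-class].
#' @param n integer >= 1; number of top clonotypes (default 10).
#' @return numeric(1) percent in [0, 100].
#' @export
topNOccupancy <- function(x, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  cl <- clonotypes(x)
  if (nrow(cl) == 0L) stop("occupancy undefined for an empty repertoire")
  if (nrow(cl) <= n) return(100)
  ord <- order(-cl$count, cl$cdr3_aa)
  100 * sum(cl$proportion[ord[seq_len(n)]])
}

#' V-J gene rearrangement usage
#'
#' Relative frequency of each V-J pair. By default each unique clonotype
#' counts once (the convention of per-clonotype Circos plots);
#' \code{weightByCount = TRUE} weights pairs by clonotype abundance instead.
#'
#' @param x a non-empty, filtered [RepertoireTable-class].
#' @param weightByCount weight rearrangements by read/UMI count.
#' @return list with \code{usage} (V x J matrix of relative frequency,
#'   summing to 1), \code{v_marginal}, \code{j_marginal}, \code{n_v},
#'   \code{n_vj}.
#' @export
vjUsage <- function(x, weightByCount = FALSE) {
  cl <- clonotypes(x)
  if (nrow(cl) == 0L) stop("usage undefined for an empty repertoire")
  w <- if (weightByCount) cl$count else rep(1, nrow(cl))
  tab <- stats::xtabs(w ~ v_gene + j_gene,
                      data = data.frame(v_gene = cl$v_gene,
                                        j_gene = cl$j_gene, w = w))
  usage <- as.matrix(tab) / sum(tab)
  list(usage = usage,
       v_marginal = rowSums(usage),
       j_marginal = colSums(usage),
       n_v = sum(rowSums(usage) > 0),
       n_vj = sum(usage > 0))
}

#' Per-sample diversity summary
#'
#' @param x a filtered [RepertoireTable-class].
#' @param topN top-clonotype count for the occupancy statistic.
#' @return one-row data.frame: sample_id, n_unique_clonotypes, n_unique_cdr3,
#'   shannon_H (nats), top_n_occupancy_pct.
#' @export
diversitySummary <- function(x, topN = 10L) {
  cl <- clonotypes(x)
  data.frame(
    sample_id = sampleID(x),
    n_unique_clonotypes = nrow(cl),
    n_unique_cdr3 = length(unique(cl$cdr3_aa)),
    shannon_H = if (nrow(cl)) shannonDiversity(x) else NA_real_,
    top_n_occupancy_pct = if (nrow(cl)) topNOccupancy(x, topN) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Pairwise shared-CDR3 overlap across samples
#'
#' Entry (i, j) counts unique CDR3 amino-acid strings present in both
#' samples; the diagonal holds each sample's own unique-CDR3 count.
#'
#' @param tables list of [RepertoireTable-class] objects, all the same chain.
#' @param chain "TRA" or "TRB"; clonotypes of other chains are ignored and a
#'   table with none on this chain contributes an empty set.
#' @return symmetric integer matrix, dimnames = sample IDs.
#' @export
pairwiseSharedCDR3 <- function(tables, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (length(tables) < 2L) stop("need at least two repertoires")
  sets <- lapply(tables, function(t) {
    cl <- clonotypes(t)
    unique(cl$cdr3_aa[cl$chain == chain])
  })
  ids <- vapply(tables, sampleID, character(1))
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n)
    m[i, j] <- m[j, i] <- if (i == j) length(sets[[i]]) else
      length(intersect(sets[[i]], sets[[j]]))
  m
}
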