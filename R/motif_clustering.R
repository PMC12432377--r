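#' Interior of a CDR3 sequence
#'
#' GLIPH-style trimming: the first \code{nHead} and last \code{nTail}
#' residues of a CDR3 are framework-proximal (the conserved C... F framing
#' plus its neighbours) and carry little specificity information, so motif
#' search and global similarity operate on the remaining interior. A CDR3 of
#' exactly \code{nHead + nTail} residues yields an empty interior (excluded
#' from motif search downstream); a shorter one yields NA.
#'
#' @param cdr3 character vector of CDR3 amino-acid strings.
#' @param nHead,nTail residues trimmed from each end (defaults 3 and 2).
#' @return character vector of interiors (possibly "", NA when too short).
#' @examples
#' cdr3Interior("CASSKGASGNEQFF")   # "SKGASGNEQ"
#' @export
cdr3Interior <- function(cdr3, nHead = 3L, nTail = 2L) {
  len <- nchar(cdr3)
  out <- rep(NA_character_, length(cdr3))
  ok <- len >= nHead + nTail
  out[ok] <- substr(cdr3[ok], nHead + 1L, len[ok] - nTail)
  out
}

.kmerSet <- function(interior, k) {
  n <- nchar(interior) - k + 1L
  if (is.na(n) || n < 1L) return(character())
  unique(substring(interior, seq_len(n), seq_len(n) + k - 1L))
}

# kmers-per-CDR3 presence counts: each unique CDR3 contributes each motif
# at most once
.motifCounts <- function(interiors, kSet) {
  interiors <- interiors[!is.na(interiors) & nzchar(interiors)]
  km <- unlist(lapply(interiors, function(s)
    unlist(lapply(kSet, .kmerSet, interior = s), use.names = FALSE)),
    use.names = FALSE)
  if (!length(km)) return(integer())
  table(km)
}

#' Enriched interior motifs in a sample vs a reference repertoire
#'
#' Counts, once per unique CDR3, every interior k-mer (k in \code{kSet}) in
#' the sample and in the reference, and retains motifs that (i) occur in at
#' least \code{minOcc} sample CDR3s, (ii) are fold-enriched at least
#' \code{minFold} over the reference rate (pseudocount 1 in the reference
#' numerator when the reference count is 0), and (iii) reach a one-sided
#' Fisher exact p <= \code{maxP} on the 2x2 table of CDR3s
#' containing/not-containing the motif in sample vs reference.
#'
#' @param sampleCdr3s,referenceCdr3s character vectors of CDR3s (deduplicated
#'   internally).
#' @param kSet motif lengths (default 2:4).
#' @param minFold minimum fold enrichment (default 10).
#' @param maxP maximum one-sided Fisher p (default 1e-3).
#' @param minOcc minimum sample occurrences (default 3).
#' @param nHead,nTail interior trim (see [cdr3Interior()]).
#' @return data.frame, one row per retained motif: motif, k, sample_count,
#'   ref_count, fold, p_value; sorted by p then motif.
#' @export
enrichedMotifs <- function(sampleCdr3s, referenceCdr3s, kSet = 2:4,
                           minFold = 10, maxP = 1e-3, minOcc = 3L,
                           nHead = 3L, nTail = 2L) {
  empty <- data.frame(motif = character(), k = integer(),
                      sample_count = integer(), ref_count = integer(),
                      fold = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  sampleCdr3s <- unique(sampleCdr3s)
  referenceCdr3s <- unique(referenceCdr3s)
  if (!length(referenceCdr3s)) stop("reference repertoire must be non-empty")
  if (!length(sampleCdr3s)) return(empty)
  si <- cdr3Interior(sampleCdr3s, nHead, nTail)
  ri <- cdr3Interior(referenceCdr3s, nHead, nTail)
  ns <- sum(!is.na(si) & nzchar(si))
  nr <- sum(!is.na(ri) & nzchar(ri))
  sc <- .motifCounts(si, kSet)
  if (!length(sc) || nr == 0L) return(empty)
  rc <- .motifCounts(ri, kSet)
  motifs <- names(sc)
  a <- as.integer(sc)
  c0 <- as.integer(rc[motifs]); c0[is.na(c0)] <- 0L
  keep <- a >= minOcc
  motifs <- motifs[keep]; a <- a[keep]; c0 <- c0[keep]
  if (!length(motifs)) return(empty)
  fold <- (a / ns) / (ifelse(c0 == 0L, 1L, c0) / nr)
  # one-sided Fisher exact (enrichment) in closed hypergeometric form
  p <- stats::phyper(a - 1L, a + c0, (ns - a) + (nr - c0), ns,
                     lower.tail = FALSE)
  keep <- fold >= minFold & p <= maxP
  out <- data.frame(motif = motifs[keep], k = nchar(motifs[keep]),
                    sample_count = a[keep], ref_count = c0[keep],
                    fold = fold[keep], p_value = p[keep],
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$motif), , drop = FALSE]
}

#' Global similarity pairs among CDR3s
#'
#' Two distinct CDR3s form a global pair when they have equal full length
#' and their interiors differ by Hamming distance at most 1. CDR3s too short
#' to have an interior are excluded.
#'
#' @param cdr3s character vector (deduplicated internally).
#' @param nHead,nTail interior trim (see [cdr3Interior()]).
#' @return data.frame with columns \code{from}, \code{to}
#'   (\code{from < to} lexicographically), possibly zero rows.
#' @export
globalPairs <- function(cdr3s, nHead = 3L, nTail = 2L) {
  cdr3s <- sort(unique(cdr3s))
  ints <- cdr3Interior(cdr3s, nHead, nTail)
  keep <- !is.na(ints)
  cdr3s <- cdr3s[keep]; ints <- ints[keep]
  res <- list()
  for (len in unique(nchar(cdr3s))) {
    idx <- which(nchar(cdr3s) == len)
    if (length(idx) < 2L) next
    L <- len - nHead - nTail
    if (L == 0L) {            # empty interiors: distance 0
      pr <- t(utils::combn(idx, 2L))
      res[[length(res) + 1L]] <- data.frame(from = cdr3s[pr[, 1]],
                                            to = cdr3s[pr[, 2]])
      next
    }
    chars <- matrix(unlist(lapply(ints[idx], utf8ToInt), use.names = FALSE),
                    nrow = length(idx), ncol = L, byrow = TRUE)
    eq <- matrix(0L, length(idx), length(idx))
    for (k in seq_len(L)) eq <- eq + outer(chars[, k], chars[, k], "==")
    hit <- which(L - eq <= 1L & upper.tri(eq), arr.ind = TRUE)
    if (nrow(hit))
      res[[length(res) + 1L]] <- data.frame(from = cdr3s[idx[hit[, 1]]],
                                            to = cdr3s[idx[hit[, 2]]])
  }
  if (!length(res))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  swap <- out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build CDR3 specificity clusters
#'
#' GLIPH2-style grouping: nodes are the unique CDR3s pooled over labeled
#' input sets; edges are \emph{global} (same length, at most one interior
#' mismatch, [globalPairs()]) and \emph{local} (two CDR3s whose interiors
#' share a retained enriched motif, [enrichedMotifs()] against
#' \code{reference}); clusters are the connected components. With
#' \code{reference = NULL} no motif enrichment is possible and only global
#' edges are used.
#'
#' @param samples named list, label -> character vector of CDR3s
#'   (e.g. \code{list(reactive = ..., til = ...)}). Labels become logical
#'   origin columns \code{from_<label>} on the nodes.
#' @param reference character vector of reference CDR3s for motif
#'   enrichment, or NULL to skip local edges.
#' @param kSet,minFold,maxP,minOcc motif-enrichment parameters
#'   (see [enrichedMotifs()]).
#' @param nHead,nTail interior trim.
#' @param edgeTypes which edge types to use (subset of "global", "local").
#' @return A [MotifClusterSet-class]. Cluster ids are deterministic:
#'   components are numbered by their lexicographically first member.
#' @seealso [expandReactiveSet()], [clusterSummary()]
#' @export
buildClusters <- function(samples, reference = NULL, kSet = 2:4,
                          minFold = 10, maxP = 1e-3, minOcc = 3L,
                          nHead = 3L, nTail = 2L,
                          edgeTypes = c("global", "local")) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            !is.null(names(samples)), all(nzchar(names(samples))))
  edgeTypes <- match.arg(edgeTypes, several.ok = TRUE)
  nodes <- sort(unique(unlist(samples, use.names = FALSE)))
  if (!length(nodes)) stop("no CDR3s supplied")

  edges <- data.frame(from = character(), to = character(),
                      type = character(), motif = character(),
                      stringsAsFactors = FALSE)
  if ("global" %in% edgeTypes) {
    gp <- globalPairs(nodes, nHead, nTail)
    if (nrow(gp))
      edges <- rbind(edges, data.frame(gp, type = "global",
                                       motif = NA_character_))
  }
  motifTab <- data.frame(motif = character(), k = integer(),
                         sample_count = integer(), ref_count = integer(),
                         fold = numeric(), p_value = numeric(),
                         stringsAsFactors = FALSE)
  if ("local" %in% edgeTypes && !is.null(reference) && length(reference)) {
    motifTab <- enrichedMotifs(nodes, reference, kSet, minFold, maxP,
                               minOcc, nHead, nTail)
    ints <- cdr3Interior(nodes, nHead, nTail)
    for (m in motifTab$motif) {
      hit <- nodes[!is.na(ints) & grepl(m, ints, fixed = TRUE)]
      if (length(hit) >= 2L) {
        pr <- t(utils::combn(hit, 2L))
        edges <- rbind(edges, data.frame(from = pr[, 1], to = pr[, 2],
                                         type = "local", motif = m))
      }
    }
  }

  memb <- seq_along(nodes)            # singleton default
  names(memb) <- nodes
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = nodes)
    memb <- igraph::components(g)$membership[nodes]
  }
  # renumber components deterministically by first (lexicographic) member
  first <- tapply(nodes, memb, function(v) v[1])
  newid <- stats::setNames(rank(first, ties.method = "first"), names(first))
  cluster <- as.integer(newid[as.character(memb)])

  nd <- S4Vectors::DataFrame(cdr3_aa = nodes, cluster = cluster)
  for (lab in names(samples))
    nd[[paste0("from_", lab)]] <- nodes %in% samples[[lab]]

  new("MotifClusterSet",
      nodes = nd,
      edges = S4Vectors::DataFrame(edges),
      motifs = S4Vectors::DataFrame(motifTab),
      params = list(kSet = kSet, minFold = minFold, maxP = maxP,
                    minOcc = minOcc, nHead = nHead, nTail = nTail,
                    edgeTypes = edgeTypes))
}

#' Per-cluster summary of a MotifClusterSet
#'
#' @param x a [MotifClusterSet-class].
#' @return data.frame: cluster, size, one \code{contains_<label>} column per
#'   origin label, and \code{multi_origin} (TRUE when more than one label is
#'   represented).
#' @export
clusterSummary <- function(x) {
  stopifnot(is(x, "MotifClusterSet"))
  nd <- as.data.frame(x@nodes)
  labs <- grep("^from_", colnames(nd), value = TRUE)
  out <- data.frame(cluster = sort(unique(nd$cluster)))
  out$size <- as.integer(table(nd$cluster)[as.character(out$cluster)])
  for (lab in labs)
    out[[sub("^from_", "contains_", lab)]] <-
      as.logical(tapply(nd[[lab]], nd$cluster, any)[as.character(out$cluster)])
  cc <- grep("^contains_", colnames(out), value = TRUE)
  out$multi_origin <- rowSums(as.matrix(out[, cc, drop = FALSE])) > 1
  out
}

#' Extend a tumor-reactive CDR3 set through specificity clusters
#'
#' Returns the TIL CDR3s that share a cluster with at least one blood
#' tumor-reactive CDR3 but are not themselves exact matches (exact matches
#' are reported separately by [exactMatchFraction()]; their union with this
#' expansion is always a superset of the exact set).
#'
#' @param reactiveCdr3s,tilCdr3s character vectors.
#' @param clusterSet a [MotifClusterSet-class] built over the union of both
#'   inputs (an uncovered CDR3 is a parameter error).
#' @return sorted character vector of similar-but-not-identical TIL CDR3s.
#' @export
expandReactiveSet <- function(reactiveCdr3s, tilCdr3s, clusterSet) {
  reactiveCdr3s <- unique(reactiveCdr3s)
  tilCdr3s <- unique(tilCdr3s)
  memb <- clusterMembership(clusterSet)
  missing <- setdiff(c(reactiveCdr3s, tilCdr3s), names(memb))
  if (length(missing))
    stop("cluster set does not cover input CDR3s: ",
         paste(utils::head(missing, 3), collapse = ", "))
  reactClusters <- unique(memb[reactiveCdr3s])
  hit <- tilCdr3s[memb[tilCdr3s] %in% reactClusters]
  sort(setdiff(hit, reactiveCdr3s))
}
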