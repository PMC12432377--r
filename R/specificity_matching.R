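.chainCdr3 <- function(x, chain) {
  cl <- clonotypes(x)
  cl[cl$chain == chain, , drop = FALSE]
}

#' Fraction of TIL clonotypes exactly matching blood tumor-reactive CDR3s
#'
#' The numerator counts unique TIL \emph{clonotypes} whose CDR3 amino-acid
#' sequence is identical to any blood tumor-reactive CDR3 (CDR3-only
#' matching: two TIL clonotypes with the same CDR3 but different V genes
#' both count); the denominator is the total number of unique TIL
#' clonotypes. Set \code{requireVJ = TRUE} to additionally require identical
#' V and J genes, or \code{countSequences = TRUE} to count unique matched
#' CDR3 strings instead of clonotypes.
#'
#' @param reactive,til filtered [RepertoireTable-class] objects
#'   (blood tumor-reactive and tumor-infiltrating).
#' @param chain "TRB" or "TRA".
#' @param requireVJ also require V/J gene identity (default FALSE).
#' @param countSequences numerator counts unique CDR3 strings rather than
#'   clonotypes (default FALSE).
#' @return A partial [SpecificityReport-class] (extended == exact,
#'   pathogen NA).
#' @export
exactMatchFraction <- function(reactive, til, chain = c("TRB", "TRA"),
                               requireVJ = FALSE, countSequences = FALSE) {
  chain <- match.arg(chain)
  tcl <- .chainCdr3(til, chain)
  rcl <- .chainCdr3(reactive, chain)
  if (nrow(tcl) == 0L)
    stop("undefined fraction: TIL table has no ", chain, " clonotypes")
  if (requireVJ) {
    key <- function(d) paste(d$v_gene, d$j_gene, d$cdr3_aa)
    hit <- key(tcl) %in% key(rcl)
  } else {
    hit <- tcl$cdr3_aa %in% rcl$cdr3_aa
  }
  nTIL <- nrow(tcl)
  nExact <- if (countSequences) length(unique(tcl$cdr3_aa[hit])) else sum(hit)
  matches <- S4Vectors::DataFrame(
    cdr3_aa = sort(unique(tcl$cdr3_aa[hit])),
    match_type = rep("exact", length(unique(tcl$cdr3_aa[hit]))))
  new("SpecificityReport",
      patientID = patientID(til), chain = chain,
      nTIL = as.integer(nTIL), nExact = as.integer(nExact),
      nExtended = as.integer(nExact),
      exactFraction = nExact / nTIL, extendedFraction = nExact / nTIL,
      pathogenFraction = NA_real_, matches = matches)
}

#' Cluster-extended tumor-reactive fraction
#'
#' Starting from [exactMatchFraction()], additionally counts TIL clonotypes
#' whose CDR3 is similar (shares a specificity cluster with a reactive CDR3,
#' [expandReactiveSet()]) though not identical. The denominator is
#' unchanged, so the extended fraction is always >= the exact fraction.
#'
#' @param reactive,til filtered [RepertoireTable-class] objects.
#' @param clusterSet a [MotifClusterSet-class] covering the union of both
#'   CDR3 sets on \code{chain}.
#' @param chain "TRB" or "TRA".
#' @inheritParams exactMatchFraction
#' @return A [SpecificityReport-class] with exact and extended fields set.
#' @export
clusterExtendedFraction <- function(reactive, til, clusterSet,
                                    chain = c("TRB", "TRA"),
                                    requireVJ = FALSE,
                                    countSequences = FALSE) {
  chain <- match.arg(chain)
  rep0 <- exactMatchFraction(reactive, til, chain, requireVJ, countSequences)
  tcl <- .chainCdr3(til, chain)
  rcl <- .chainCdr3(reactive, chain)
  similar <- expandReactiveSet(unique(rcl$cdr3_aa), unique(tcl$cdr3_aa),
                               clusterSet)
  extra <- tcl$cdr3_aa %in% similar & !(tcl$cdr3_aa %in% rcl$cdr3_aa)
  nExtra <- if (countSequences) length(unique(tcl$cdr3_aa[extra])) else
    sum(extra)
  nExtended <- rep0@nExact + nExtra
  matches <- rbind(rep0@matches,
                   S4Vectors::DataFrame(cdr3_aa = sort(similar),
                                        match_type = rep("cluster",
                                                         length(similar))))
  methods::initialize(rep0,
      nExtended = as.integer(nExtended),
      extendedFraction = nExtended / rep0@nTIL,
      matches = matches)
}

.hlaMatches <- function(recordAllele, patientAlleles) {
  if (is.na(recordAllele)) return(FALSE)
  if (isGroupLevelHLA(recordAllele))
    any(startsWith(patientAlleles, paste0(recordAllele, ":")) |
        patientAlleles == recordAllele)
  else recordAllele %in% patientAlleles
}

#' Fraction of TIL clonotypes matching pathogen-specific database entries
#'
#' A TIL clonotype counts as pathogen-specific when its CDR3 amino-acid
#' sequence completely matches an epitope-database record of pathogen
#' category whose restricting HLA allele matches one of the patient's
#' class-I alleles: two-field exact match, or group-level prefix match when
#' the record is low-resolution (e.g. record "HLA-A*02" matches patient
#' "HLA-A*02:01").
#'
#' @param til filtered [RepertoireTable-class].
#' @param epitopeDb data.frame from [readVDJdb()].
#' @param hla character vector of the patient's normalized class-I alleles
#'   (one element of [readHLA()]'s result).
#' @param chain "TRB" or "TRA".
#' @return A partial [SpecificityReport-class] with \code{pathogenFraction}
#'   set (exact/extended NA).
#' @export
pathogenFraction <- function(til, epitopeDb, hla, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (length(hla) == 0L || all(is.na(hla)))
    stop("empty HLA typing")
  hla <- normalizeHLA(hla)
  tcl <- .chainCdr3(til, chain)
  if (nrow(tcl) == 0L)
    stop("undefined fraction: TIL table has no ", chain, " clonotypes")
  db <- epitopeDb[epitopeDb$antigen_category == "pathogen" &
                  epitopeDb$chain == chain, , drop = FALSE]
  okAllele <- vapply(db$mhc_allele, .hlaMatches, logical(1),
                     patientAlleles = hla)
  dbCdr3 <- unique(db$cdr3_aa[okAllele])
  hit <- tcl$cdr3_aa %in% dbCdr3
  matches <- S4Vectors::DataFrame(
    cdr3_aa = sort(unique(tcl$cdr3_aa[hit])),
    match_type = rep("pathogen", length(unique(tcl$cdr3_aa[hit]))))
  new("SpecificityReport",
      patientID = patientID(til), chain = chain,
      nTIL = nrow(tcl), nExact = NA_integer_, nExtended = NA_integer_,
      exactFraction = NA_real_, extendedFraction = NA_real_,
      pathogenFraction = sum(hit) / nrow(tcl), matches = matches)
}

#' Merge partial specificity reports for one patient/chain
#'
#' @param exactReport report from [exactMatchFraction()] or
#'   [clusterExtendedFraction()].
#' @param pathogenReport report from [pathogenFraction()] (optional).
#' @return A combined [SpecificityReport-class].
#' @export
mergeReports <- function(exactReport, pathogenReport = NULL) {
  if (is.null(pathogenReport)) return(exactReport)
  stopifnot(exactReport@patientID == pathogenReport@patientID,
            exactReport@chain == pathogenReport@chain)
  methods::initialize(exactReport,
      pathogenFraction = pathogenReport@pathogenFraction,
      matches = rbind(exactReport@matches, pathogenReport@matches))
}

#' Cohort-level grouped summary of specificity reports
#'
#' Collects per-patient reports into a table and summarises the
#' tumor-reactive TIL fraction by lymph-node metastasis status and by
#' histology. Patients with lymph-node status "ND" are retained in the
#' per-patient table but excluded from the yes/no grouping. A rank-based
#' two-group test (Wilcoxon/Mann-Whitney) p-value on the yes/no split is
#' emitted as a descriptive convenience, uncorrected.
#'
#' @param reports list of [SpecificityReport-class] objects.
#' @param metadata data.frame from [readMetadata()]; every reported patient
#'   must be present (integrity error otherwise).
#' @param statistic which fraction to summarise: "exact", "extended" or
#'   "pathogen".
#' @return list with \code{per_patient} (data.frame), \code{by_lymph_node}
#'   (group medians and n), \code{by_histology}, and \code{p_lymph_node}.
#' @export
cohortReport <- function(reports, metadata,
                         statistic = c("exact", "extended", "pathogen")) {
  statistic <- match.arg(statistic)
  pp <- do.call(rbind, lapply(reports, reportAsDataFrame))
  missing <- setdiff(pp$patient_id, metadata$patient_id)
  if (length(missing))
    stop("integrity error: patient(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  idx <- match(pp$patient_id, metadata$patient_id)
  pp$histology <- metadata$histology[idx]
  pp$lymph_node_metastasis <- metadata$lymph_node_metastasis[idx]
  val <- switch(statistic, exact = pp$exact_fraction,
                extended = pp$extended_fraction,
                pathogen = pp$pathogen_fraction)
  pp$value <- val
  grp <- function(g) {
    keep <- !is.na(pp$value) & !is.na(g) & g != "ND"
    agg <- stats::aggregate(pp$value[keep], list(group = g[keep]),
                            stats::median)
    names(agg)[2] <- "median_fraction"
    agg$n <- as.integer(table(g[keep])[agg$group])
    agg
  }
  byLN <- grp(pp$lymph_node_metastasis)
  byHist <- grp(pp$histology)
  pLN <- NA_real_
  keep <- pp$lymph_node_metastasis %in% c("yes", "no") & !is.na(pp$value)
  if (length(unique(pp$lymph_node_metastasis[keep])) == 2L)
    pLN <- suppressWarnings(stats::wilcox.test(
      value ~ lymph_node_metastasis, data = pp[keep, ])$p.value)
  list(per_patient = pp, by_lymph_node = byLN, by_histology = byHist,
       p_lymph_node = pLN)
}
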