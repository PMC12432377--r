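#' Relative proliferation of CD8 T cells after lysate stimulation
#'
#' The frequency of CFSE-low CD25+ CD8 T cells after coculture with
#' unloaded dendritic cells is subtracted from the frequency after coculture
#' with lysate-loaded dendritic cells; negative values are scaled to zero.
#'
#' @param fLoaded,fUnloaded percents in [0, 100] (vectorized).
#' @return percent(s) in [0, 100].
#' @examples
#' relativeProliferation(5, 2)   # 3
#' relativeProliferation(1, 2)   # 0
#' @export
relativeProliferation <- function(fLoaded, fUnloaded) {
  .checkPct(fLoaded); .checkPct(fUnloaded)
  pmax(0, fLoaded - fUnloaded)
}

.checkPct <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x > 100))
    stop("percentages must lie in [0, 100]")
  invisible(x)
}

#' Responder call from a proliferation measurement
#'
#' A patient is called a responder (detectable circulating tumor-reactive
#' CD8 response) when proliferation with antigen-loaded dendritic cells is
#' strictly higher than the baseline with unloaded cells.
#'
#' @inheritParams relativeProliferation
#' @return logical (vectorized); equality is \code{FALSE}.
#' @export
callResponder <- function(fLoaded, fUnloaded) {
  .checkPct(fLoaded); .checkPct(fUnloaded)
  fLoaded > fUnloaded
}

#' Responder rate as a percent
#'
#' Convenience utility for responder counts: 100 * k / n.
#'
#' @param nResponders,nTotal counts.
#' @return percent (vectorized).
#' @examples
#' responderRate(16, 23)   # 69.57
#' @export
responderRate <- function(nResponders, nTotal) {
  stopifnot(all(nTotal > 0), all(nResponders >= 0),
            all(nResponders <= nTotal))
  100 * nResponders / nTotal
}

#' Percent cytotoxicity from a flow-based killing assay
#'
#' \deqn{100 - \frac{\%target/\%reference}{\%target_{ctrl}/\%reference_{ctrl}}
#'   \times 100}
#' where the control ratio comes from target cells cultured without T cells.
#' The result is scale-invariant in the four percentages. Negative values
#' (target outgrowth relative to control) are meaningful and returned as-is
#' unless \code{clamp = TRUE}.
#'
#' @param pctTarget,pctReference percents from the test coculture.
#' @param pctTargetControl,pctReferenceControl percents from the
#'   no-effector control.
#' @param clamp clamp negatives to 0 (default FALSE).
#' @return percent cytotoxicity (vectorized).
#' @examples
#' cytotoxicityPct(10, 20, 20, 20)   # 50
#' @export
cytotoxicityPct <- function(pctTarget, pctReference,
                            pctTargetControl, pctReferenceControl,
                            clamp = FALSE) {
  if (any(pctReference <= 0) || any(pctReferenceControl <= 0))
    stop("reference percentages must be positive")
  if (any(pctTargetControl <= 0))
    stop("control target percentage must be positive")
  out <- 100 - (pctTarget / pctReference) /
    (pctTargetControl / pctReferenceControl) * 100
  if (clamp) out <- pmax(0, out)
  out
}

#' Relative green intensity in an imaging killing assay
#'
#' Per timepoint: total integrated intensity (TII) of the coculture minus
#' the TII of the T-cell-only and tumor-cell-only monocultures.
#'
#' @param tiiCoculture,tiiTcellOnly,tiiTumorOnly non-negative intensities;
#'   equal-length vectors give an elementwise time series.
#' @return numeric, same length as the inputs.
#' @export
relativeGreenIntensity <- function(tiiCoculture, tiiTcellOnly, tiiTumorOnly) {
  if (any(tiiCoculture < 0) || any(tiiTcellOnly < 0) || any(tiiTumorOnly < 0))
    stop("intensities must be non-negative")
  tiiCoculture - tiiTcellOnly - tiiTumorOnly
}

#' Probability of missing a clone under Poisson sampling
#'
#' With n cells sequenced and a clone at frequency f, the expected number of
#' sampled cells from the clone is lambda = n * f and the probability that
#' the clone is absent from the library is exp(-lambda). Used to argue that
#' sequencing 5e5 cells retains clones at frequency 1e-4 essentially surely.
#'
#' @param nCells positive integer: cells sequenced.
#' @param cloneFrequency clone frequency in [0, 1).
#' @return probability of not sampling the clone.
#' @examples
#' poissonMissProbability(5e5, 1e-4)   # 1.928e-22
#' @export
poissonMissProbability <- function(nCells, cloneFrequency) {
  stopifnot(all(nCells > 0), all(cloneFrequency >= 0),
            all(cloneFrequency < 1))
  exp(-nCells * cloneFrequency)
}

#' Antigens expressed per sample under a fixed cutoff
#'
#' An antigen (gene) is called expressed in a sample when its value is
#' greater than or equal to \code{cutoff} (inclusive), on the scale the
#' table is given in (normalized read counts; no re-normalization).
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param cutoff inclusive expression threshold (default 5).
#' @return named list: sample -> character vector of expressed genes.
#' @export
expressedAntigens <- function(expr, cutoff = 5) {
  stopifnot(is.matrix(expr) || methods::is(expr, "Matrix"),
            !is.null(rownames(expr)), !is.null(colnames(expr)))
  lapply(stats::setNames(colnames(expr), colnames(expr)),
         function(s) rownames(expr)[expr[, s] >= cutoff])
}

#' Antigens shared across sample groups
#'
#' Under \code{mode = "any_per_group"} an antigen is shared when it is
#' expressed by at least one sample in every group (intersection of
#' per-group unions); under \code{mode = "all_samples"} it must be expressed
#' by every sample.
#'
#' @param antigenSets named list from [expressedAntigens()].
#' @param groups named list: group -> character vector of sample names
#'   (ignored under "all_samples"). Unknown samples are an integrity error.
#' @param mode "any_per_group" or "all_samples".
#' @return character vector of shared antigens.
#' @export
sharedAntigens <- function(antigenSets, groups = NULL,
                           mode = c("any_per_group", "all_samples")) {
  mode <- match.arg(mode)
  if (mode == "all_samples")
    return(sort(Reduce(intersect, antigenSets)))
  stopifnot(!is.null(groups))
  unknown <- setdiff(unlist(groups), names(antigenSets))
  if (length(unknown))
    stop("integrity error: unknown sample(s) in groups: ",
         paste(unknown, collapse = ", "))
  perGroup <- lapply(groups, function(ss)
    sort(unique(unlist(antigenSets[ss], use.names = FALSE))))
  sort(Reduce(intersect, perGroup))
}
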