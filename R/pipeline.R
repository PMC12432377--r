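#' Validate a pipeline run configuration
#'
#' Checks a configuration (a list, or a path to a YAML file with the same
#' structure) without executing anything, returning every problem found.
#'
#' Expected structure: \code{samples}: list of per-patient entries with
#' \code{patient_id}, \code{reactive} and \code{til} file paths;
#' \code{vdjdb}, \code{hla}, \code{metadata}: file paths; \code{out_dir};
#' \code{seed}; optional parameter blocks \code{filter} (\code{min_count}),
#' \code{cluster} (\code{enabled}, \code{kmin}, \code{kmax}, \code{max_p},
#' \code{min_fold}, \code{min_occ}), \code{diversity} (\code{top_n}),
#' \code{chain}.
#'
#' @param cfg list or YAML path.
#' @return list with \code{errors} and \code{warnings} character vectors;
#'   an empty \code{errors} vector means the config is runnable.
#' @export
validateConfig <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  errs <- character(); warns <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.list(cfg$samples) && length(cfg$samples) > 0,
       "samples: at least one per-patient entry required")
  for (s in cfg$samples) {
    pid <- if (is.null(s$patient_id)) "<missing patient_id>" else s$patient_id
    need(!is.null(s$patient_id), "samples: entry without patient_id")
    for (f in c("reactive", "til")) {
      if (is.null(s[[f]]))
        errs <- c(errs, sprintf("patient %s: missing %s file entry", pid, f))
      else if (!file.exists(s[[f]]))
        errs <- c(errs, sprintf("patient %s: %s file not found: %s",
                                pid, f, s[[f]]))
    }
  }
  for (f in c("vdjdb", "hla", "metadata"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errs <- c(errs, sprintf("%s file not found: %s", f, cfg[[f]]))
  mc <- cfg$filter$min_count
  if (!is.null(mc) && mc < 1) errs <- c(errs, "filter$min_count must be >= 1")
  tn <- cfg$diversity$top_n
  if (!is.null(tn) && tn < 1) errs <- c(errs, "diversity$top_n must be >= 1")
  mp <- cfg$cluster$max_p
  if (!is.null(mp) && (mp <= 0 || mp > 1))
    errs <- c(errs, "cluster$max_p must lie in (0, 1]")
  if (!is.null(cfg$chain) && !cfg$chain %in% c("TRA", "TRB"))
    errs <- c(errs, "chain must be TRA or TRB")
  if (is.null(cfg$out_dir)) errs <- c(errs, "out_dir required")
  if (is.null(cfg$seed)) warns <- c(warns, "no seed given; defaulting to 1")
  list(errors = errs, warnings = warns)
}

.cfgDefault <- function(x, default) if (is.null(x)) default else x

#' Run the end-to-end tumor-reactive repertoire pipeline
#'
#' filter -> diversity -> (optional) specificity clustering -> blood-to-tumor
#' matching -> pathogen annotation -> grouped cohort report. Outputs are
#' written to \code{out_dir}: \code{diversity.tsv} (per sample),
#' \code{clusters.tsv} (when clustering is enabled), \code{report.tsv} (one
#' row per patient), \code{group_summary.tsv}, and \code{manifest.json}
#' (parameters plus input checksums). Identical config and inputs give
#' byte-identical TSV outputs.
#'
#' When clustering is enabled, the motif-enrichment reference for each
#' patient defaults to the pooled TIL CDR3s of all \emph{other} patients
#' that match no reactive CDR3 — the cohort's non-reactive background.
#'
#' @param cfg list or YAML path (see [validateConfig()]).
#' @return the output directory, invisibly; a failed stage aborts with the
#'   stage named and \code{INCOMPLETE} marker left in the directory.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  diag <- validateConfig(cfg)
  if (length(diag$errors))
    stop("invalid config:\n  ", paste(diag$errors, collapse = "\n  "))
  for (w in diag$warnings) message(w)

  chain <- .cfgDefault(cfg$chain, "TRB")
  minCount <- .cfgDefault(cfg$filter$min_count, 10L)
  topN <- .cfgDefault(cfg$diversity$top_n, 10L)
  doCluster <- isTRUE(.cfgDefault(cfg$cluster$enabled, TRUE))
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outDir, "INCOMPLETE")
  file.create(marker)
  stage <- "setup"
  on.exit(if (file.exists(marker))
    message("pipeline aborted at stage: ", stage))

  stage <- "read"
  meta <- if (!is.null(cfg$metadata)) readMetadata(cfg$metadata) else NULL
  db <- if (!is.null(cfg$vdjdb)) readVDJdb(cfg$vdjdb) else NULL
  hla <- if (!is.null(cfg$hla)) readHLA(cfg$hla) else NULL
  pats <- lapply(cfg$samples, function(s) {
    list(id = s$patient_id,
         reactive = readClonotypes(s$reactive,
                                   sampleID = paste0(s$patient_id, "_reactive"),
                                   patientID = s$patient_id,
                                   compartment = "blood_reactive"),
         til = readClonotypes(s$til, sampleID = paste0(s$patient_id, "_til"),
                              patientID = s$patient_id, compartment = "til"))
  })

  stage <- "filter"
  pats <- lapply(pats, function(p) {
    p$reactive <- filterClonotypes(p$reactive, minCount)
    p$til <- filterClonotypes(p$til, minCount)
    p
  })

  stage <- "diversity"
  dv <- do.call(rbind, lapply(pats, function(p)
    rbind(diversitySummary(p$reactive, topN), diversitySummary(p$til, topN))))
  write.table(dv, file.path(outDir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stage <- "match"
  tilAll <- lapply(pats, function(p) unique(.chainCdr3(p$til, chain)$cdr3_aa))
  names(tilAll) <- vapply(pats, `[[`, character(1), "id")
  reactAll <- lapply(pats, function(p)
    unique(.chainCdr3(p$reactive, chain)$cdr3_aa))
  names(reactAll) <- names(tilAll)

  clusterRows <- list()
  reports <- lapply(pats, function(p) {
    rep0 <- if (doCluster) {
      # cohort non-reactive background: other patients' TIL CDR3s that match
      # no reactive CDR3 anywhere
      ref <- setdiff(unlist(tilAll[names(tilAll) != p$id], use.names = FALSE),
                     unlist(reactAll, use.names = FALSE))
      cs <- buildClusters(list(reactive = reactAll[[p$id]],
                               til = tilAll[[p$id]]),
                          reference = ref,
                          kSet = .cfgDefault(cfg$cluster$kmin, 2L):
                                 .cfgDefault(cfg$cluster$kmax, 4L),
                          minFold = .cfgDefault(cfg$cluster$min_fold, 10),
                          maxP = .cfgDefault(cfg$cluster$max_p, 1e-3),
                          minOcc = .cfgDefault(cfg$cluster$min_occ, 3L))
      nd <- as.data.frame(cs@nodes)
      nd$patient_id <- p$id
      clusterRows[[p$id]] <<- nd
      clusterExtendedFraction(p$reactive, p$til, cs, chain)
    } else exactMatchFraction(p$reactive, p$til, chain)
    if (!is.null(db) && !is.null(hla) && p$id %in% names(hla))
      rep0 <- mergeReports(rep0, pathogenFraction(p$til, db, hla[[p$id]],
                                                  chain))
    rep0
  })
  if (doCluster && length(clusterRows))
    write.table(do.call(rbind, clusterRows),
                file.path(outDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  stage <- "report"
  ppAll <- do.call(rbind, lapply(reports, reportAsDataFrame))
  write.table(ppAll, file.path(outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(meta)) {
    cr <- cohortReport(reports, meta,
                       statistic = if (doCluster) "extended" else "exact")
    gs <- cr$by_lymph_node
    gs$p_value <- cr$p_lymph_node
    write.table(gs, file.path(outDir, "group_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  stage <- "manifest"
  inputs <- c(vapply(cfg$samples, `[[`, character(1), "reactive"),
              vapply(cfg$samples, `[[`, character(1), "til"),
              unlist(cfg[c("vdjdb", "hla", "metadata")], use.names = FALSE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tcrtrack")),
    parameters = list(chain = chain, min_count = minCount, top_n = topN,
                      cluster = doCluster,
                      seed = .cfgDefault(cfg$seed, 1L)),
    inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  invisible(outDir)
}
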