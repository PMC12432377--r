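# ---- catalogs --------------------------------------------------------------

#' Default V/J gene catalogs for simulation
#'
#' Common human TRB/TRA gene segments used by the simulator; real analyses
#' take gene names from the input files, so the catalog only needs to be
#' plausible and internally consistent with the chain.
#'
#' @param chain "TRB" or "TRA".
#' @return character vector of gene names.
#' @export
defaultVGenes <- function(chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (chain == "TRB")
    paste0("TRBV", c("2", "4-1", "5-1", "6-1", "6-5", "7-2", "7-9", "9",
                     "10-3", "11-2", "12-3", "13", "14", "15", "18", "19",
                     "20-1", "24-1", "25-1", "27", "28", "29-1", "30"))
  else
    paste0("TRAV", c("1-2", "2", "3", "8-2", "8-4", "9-2", "12-1", "13-1",
                     "17", "19", "21", "22", "26-1", "29/DV5", "35", "38-1"))
}

#' @rdname defaultVGenes
#' @export
defaultJGenes <- function(chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (chain == "TRB")
    paste0("TRBJ", c("1-1", "1-2", "1-3", "1-4", "1-5", "1-6",
                     "2-1", "2-2", "2-3", "2-4", "2-5", "2-6", "2-7"))
  else
    paste0("TRAJ", c("4", "6", "9", "12", "20", "23", "27", "30", "33",
                     "37", "42", "45", "49", "53"))
}

#' Default CDR3 length distribution
#'
#' Discrete distribution over lengths 8-20, peaked at 14-15 residues, the
#' typical human CDR3beta length profile.
#'
#' @return named numeric vector of probabilities (names = lengths).
#' @export
defaultCdr3LengthDist <- function() {
  len <- 8:20
  w <- stats::dnorm(len, mean = 14.5, sd = 2)
  stats::setNames(w / sum(w), len)
}

#' Derive reproducible child seeds from a root seed
#'
#' All simulator randomness flows from one root seed: child seeds for
#' sub-simulations are drawn as a deterministic stream so any part can be
#' regenerated independently. Seeds stay below 2^31.
#'
#' @param seed root integer seed.
#' @param n number of child seeds.
#' @return integer vector of n seeds.
#' @export
splitSeed <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.randomCdr3 <- function(n, lengthDist) {
  lens <- as.integer(sample(names(lengthDist), n, replace = TRUE,
                            prob = lengthDist))
  vapply(lens, function(L)
    paste0("C", paste(sample(AA_STANDARD, L - 2L, replace = TRUE),
                      collapse = ""), "F"), character(1))
}

.uniqueCdr3 <- function(n, lengthDist, avoid = character()) {
  out <- character()
  while (length(out) < n) {
    cand <- setdiff(unique(.randomCdr3(2L * (n - length(out)), lengthDist)),
                    c(avoid, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# i.i.d. clone sizes from a discrete power law P(k) ~ k^-s, k >= kmin.
# Smaller exponents give heavier tails, hence higher top-clone occupancy.
.zipfCounts <- function(n, exponent, kmin = 10L, kmax = 100000L) {
  k <- kmin:kmax
  sample(k, n, replace = TRUE, prob = k^(-exponent))
}

# ---- cohort configuration --------------------------------------------------

#' Configuration for a synthetic paired blood/tumor cohort
#'
#' Defaults describe the study design the package targets: 15 patients with
#' paired blood tumor-reactive and TIL repertoires, 5 of them lymph-node
#' positive and 10 negative; 47 blood-reactive clonotypes per patient (the
#' typical per-patient unique CDR3beta yield of a tumor-reactive line);
#' 1000 TIL clonotypes; a true shared-clonotype fraction theta of 0.04 in
#' node-negative and 0.01 in node-positive patients (tumor-reactive TIL are
#' rarer under nodal metastasis); clone sizes from a discrete power law with
#' exponent 2 truncated at the abundance filter threshold; 5 near-miss TIL
#' CDR3s per patient (one interior mismatch from a reactive CDR3); 1% of
#' TIL CDR3s copied from HLA-compatible pathogen epitope-database records.
#'
#' @param nPatients total patients.
#' @param nNodePositive patients with lymph-node metastasis (group "yes").
#' @param nBloodReactive blood tumor-reactive clonotypes per patient.
#' @param nTIL TIL clonotypes per patient.
#' @param theta named numeric: true shared fraction per lymph-node group,
#'   \code{c(no = ..., yes = ...)}.
#' @param zipfExponent power-law exponent for clone sizes (> 1).
#' @param cdr3LengthDist named probability vector over CDR3 lengths.
#' @param vGenes,jGenes gene catalogs.
#' @param nNearMiss near-miss TIL CDR3s per patient.
#' @param pathogenSpike fraction of TIL CDR3s copied from compatible
#'   pathogen epitope records.
#' @param minCount abundance floor for simulated counts (the downstream
#'   filter threshold); set \code{lowCountFraction > 0} to inject
#'   below-threshold clonotypes for filter testing.
#' @param lowCountFraction fraction of clonotypes drawn below minCount.
#' @param chain simulated chain.
#' @param seed root seed.
#' @return validated config list (class "CohortConfig").
#' @export
cohortConfig <- function(nPatients = 15L,
                         nNodePositive = max(1L, round(nPatients / 3)),
                         nBloodReactive = 47L, nTIL = 1000L,
                         theta = c(no = 0.04, yes = 0.01),
                         zipfExponent = 2, cdr3LengthDist = defaultCdr3LengthDist(),
                         vGenes = defaultVGenes("TRB"),
                         jGenes = defaultJGenes("TRB"),
                         nNearMiss = 5L, pathogenSpike = 0.01,
                         minCount = 10L, lowCountFraction = 0,
                         chain = "TRB", seed = 1L) {
  stopifnot(nPatients >= 1L, nNodePositive >= 0L, nNodePositive <= nPatients,
            all(theta >= 0), all(theta <= 1),
            all(c("no", "yes") %in% names(theta)),
            zipfExponent > 1, length(vGenes) > 0, length(jGenes) > 0,
            pathogenSpike >= 0, pathogenSpike < 1,
            lowCountFraction >= 0, lowCountFraction < 1)
  if (abs(sum(cdr3LengthDist) - 1) > 1e-9)
    stop("cdr3LengthDist must sum to 1")
  structure(list(nPatients = as.integer(nPatients),
                 nNodePositive = as.integer(nNodePositive),
                 nBloodReactive = as.integer(nBloodReactive),
                 nTIL = as.integer(nTIL), theta = theta,
                 zipfExponent = zipfExponent,
                 cdr3LengthDist = cdr3LengthDist,
                 vGenes = vGenes, jGenes = jGenes,
                 nNearMiss = as.integer(nNearMiss),
                 pathogenSpike = pathogenSpike,
                 minCount = as.integer(minCount),
                 lowCountFraction = lowCountFraction,
                 chain = chain, seed = as.integer(seed)),
            class = "CohortConfig")
}

# ---- repertoire simulation -------------------------------------------------

#' Simulate one clonotype repertoire
#'
#' CDR3s are built as "C" + uniform-residue interior + "F" with lengths from
#' the configured distribution; V/J genes sampled from the catalog; counts
#' drawn i.i.d. from a discrete power law truncated below at
#' \code{minCount}, so that by default every simulated clonotype survives
#' the abundance filter (set \code{lowCountFraction} to inject sub-threshold
#' clonotypes). Deterministic per seed; all clonotypes unique.
#'
#' @param n number of unique clonotypes.
#' @param seed integer seed.
#' @param cfg a [cohortConfig()] supplying catalogs and distributions.
#' @param fixedCdr3 optional character vector of CDR3s to plant as the first
#'   clonotypes (counts still random).
#' @param plantMotif optional positional-bias model for motif-enrichment
#'   testing: \code{list(motif = "...", offset = <0-based interior offset>,
#'   fraction = <share of clonotypes>)}; the motif is written into the
#'   interior at that fixed offset in a random subset of the generated
#'   CDR3s (long enough ones only).
#' @param sampleID,patientID,compartment sample annotation.
#' @return A [RepertoireTable-class] with exactly n unique clonotypes.
#' @export
simulateRepertoire <- function(n, seed, cfg = cohortConfig(),
                               fixedCdr3 = character(), plantMotif = NULL,
                               sampleID = "sim", patientID = sampleID,
                               compartment = "other") {
  stopifnot(n >= length(fixedCdr3))
  .withSeed(seed, {
    cdr3 <- c(fixedCdr3,
              .uniqueCdr3(n - length(fixedCdr3), cfg$cdr3LengthDist,
                          avoid = fixedCdr3))
    if (!is.null(plantMotif)) {
      stopifnot(all(c("motif", "offset", "fraction") %in% names(plantMotif)))
      nHead <- 3L
      start <- nHead + 1L + plantMotif$offset
      fits <- which(seq_along(cdr3) > length(fixedCdr3) &
                    nchar(cdr3) - 2L >= start + nchar(plantMotif$motif) - 1L)
      pick <- sample(fits, min(length(fits),
                               round(plantMotif$fraction * n)))
      for (i in pick) {
        cand <- paste0(substr(cdr3[i], 1L, start - 1L), plantMotif$motif,
                       substr(cdr3[i], start + nchar(plantMotif$motif),
                              nchar(cdr3[i])))
        if (!cand %in% cdr3) cdr3[i] <- cand
      }
    }
    counts <- .zipfCounts(n, cfg$zipfExponent, kmin = cfg$minCount)
    if (cfg$lowCountFraction > 0 && cfg$minCount > 1L) {
      nLow <- round(cfg$lowCountFraction * n)
      low <- sample.int(n, nLow)
      counts[low] <- sample.int(cfg$minCount - 1L, nLow, replace = TRUE)
    }
    RepertoireTable(data.frame(chain = cfg$chain,
                               v_gene = sample(cfg$vGenes, n, replace = TRUE),
                               j_gene = sample(cfg$jGenes, n, replace = TRUE),
                               cdr3_aa = cdr3, count = counts,
                               stringsAsFactors = FALSE),
                    sampleID, patientID, compartment)
  })
}

# mutate exactly one interior residue (keeps length, guarantees a change)
.mutateInterior <- function(cdr3, nHead = 3L, nTail = 2L) {
  L <- nchar(cdr3)
  stopifnot(L > nHead + nTail)
  pos <- sample((nHead + 1L):(L - nTail), 1L)
  old <- substr(cdr3, pos, pos)
  new <- sample(setdiff(AA_STANDARD, old), 1L)
  paste0(substr(cdr3, 1L, pos - 1L), new, substr(cdr3, pos + 1L, L))
}

#' Simulate a synthetic epitope database
#'
#' VDJdb-shaped records over a mix of pathogen species and host
#' self-antigens, each restricted to a class-I allele; a fraction of records
#' carry group-level (one-field) alleles to exercise low-resolution
#' matching.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param cfg a [cohortConfig()].
#' @param allelePool character vector of two-field alleles to draw from.
#' @return data.frame in the shape returned by [readVDJdb()].
#' @export
simulateEpitopeDb <- function(n = 300L, seed = 1L, cfg = cohortConfig(),
                              allelePool = c("HLA-A*01:01", "HLA-A*02:01",
                                             "HLA-A*03:01", "HLA-B*07:02",
                                             "HLA-B*08:01", "HLA-C*07:01")) {
  .withSeed(seed, {
    species <- sample(c("CMV", "EBV", "InfluenzaA", "HomoSapiens"), n,
                      replace = TRUE, prob = c(0.3, 0.25, 0.25, 0.2))
    allele <- sample(allelePool, n, replace = TRUE)
    grp <- sample.int(n, round(0.1 * n))   # 10% group-level records
    allele[grp] <- sub(":.*$", "", allele[grp])
    data.frame(chain = cfg$chain,
               cdr3_aa = .uniqueCdr3(n, cfg$cdr3LengthDist),
               v_gene = sample(cfg$vGenes, n, replace = TRUE),
               j_gene = sample(cfg$jGenes, n, replace = TRUE),
               mhc_allele = allele,
               mhc_group_level = isGroupLevelHLA(allele),
               antigen_species = species,
               antigen_epitope = vapply(seq_len(n), function(i)
                 paste(sample(AA_STANDARD, 9, replace = TRUE), collapse = ""),
                 character(1)),
               antigen_category = ifelse(species %in% defaultPathogenSpecies(),
                                         "pathogen", "other"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a paired blood/tumor cohort with ground truth
#'
#' For each patient: a blood tumor-reactive repertoire; a TIL repertoire in
#' which \code{ceiling(theta * nTIL)} clonotypes copy reactive CDR3s,
#' \code{nNearMiss} CDR3s differ from a reactive CDR3 by exactly one
#' interior residue, and \code{round(pathogenSpike * nTIL)} CDR3s are copied
#' from pathogen epitope-database records whose restricting allele matches
#' the patient's simulated HLA typing. Metadata assigns lymph-node groups
#' with the group-specific theta. The returned truth object records every
#' planted set.
#'
#' @param cfg a [cohortConfig()].
#' @return list: \code{reactive} and \code{til} (named lists of
#'   [RepertoireTable-class]), \code{epitopeDb}, \code{hla} (named list of
#'   allele vectors), \code{metadata} (data.frame), \code{truth} (per-patient
#'   list: theta_true, shared, near_miss, pathogen CDR3 sets).
#' @export
simulatePairedCohort <- function(cfg = cohortConfig()) {
  nP <- cfg$nPatients
  seeds <- splitSeed(cfg$seed, 3L * nP + 2L)
  epitopeDb <- simulateEpitopeDb(seed = seeds[3L * nP + 1L], cfg = cfg)
  pathDb <- epitopeDb[epitopeDb$antigen_category == "pathogen", ]
  groups <- rep(c("yes", "no"),
                c(cfg$nNodePositive, nP - cfg$nNodePositive))
  ids <- sprintf("P%02d", seq_len(nP))

  metadata <- .withSeed(seeds[3L * nP + 2L], data.frame(
    patient_id = ids,
    histology = sample(c("ductal", "lobular", "mucinous"), nP,
                       replace = TRUE, prob = c(14, 7, 2) / 23),
    lymph_node_metastasis = groups,
    stringsAsFactors = FALSE))

  reactive <- list(); til <- list(); hla <- list(); truth <- list()
  for (i in seq_len(nP)) {
    pid <- ids[i]
    th <- cfg$theta[[groups[i]]]
    rt <- simulateRepertoire(cfg$nBloodReactive, seeds[i], cfg,
                             sampleID = paste0(pid, "_reactive"),
                             patientID = pid, compartment = "blood_reactive")
    rCdr3 <- clonotypes(rt)$cdr3_aa

    nShared <- min(ceiling(th * cfg$nTIL), cfg$nBloodReactive)
    if (nShared < ceiling(th * cfg$nTIL))
      warning("patient ", pid, ": planted shared set capped at ",
              "nBloodReactive; theta_planted < theta")
    if (th * cfg$nTIL < 1 && cfg$nNearMiss > 0L)
      warning("theta * nTIL < 1 for patient ", pid,
              " while near-misses are requested")

    planted <- .withSeed(seeds[nP + i], {
      shared <- sample(rCdr3, nShared)
      nmSrc <- sample(setdiff(rCdr3, shared),
                      min(cfg$nNearMiss, cfg$nBloodReactive - nShared))
      nearMiss <- character()
      for (s in nmSrc) {
        repeat {
          cand <- .mutateInterior(s)
          if (!cand %in% c(rCdr3, shared, nearMiss)) break
        }
        nearMiss <- c(nearMiss, cand)
      }
      myHla <- normalizeHLA(sample(c("A*01:01", "A*02:01", "A*03:01",
                                     "B*07:02", "B*08:01", "C*07:01"), 4))
      compat <- pathDb$cdr3_aa[vapply(pathDb$mhc_allele, .hlaMatches,
                                      logical(1), patientAlleles = myHla)]
      nPath <- min(round(cfg$pathogenSpike * cfg$nTIL), length(compat))
      pathogen <- if (nPath > 0) sample(compat, nPath) else character()
      list(shared = shared, nearMiss = nearMiss, pathogen = pathogen,
           hla = myHla)
    })

    fixed <- unique(c(planted$shared, planted$nearMiss, planted$pathogen))
    tt <- simulateRepertoire(cfg$nTIL, seeds[2L * nP + i], cfg,
                             fixedCdr3 = fixed,
                             sampleID = paste0(pid, "_til"),
                             patientID = pid, compartment = "til")
    reactive[[pid]] <- rt
    til[[pid]] <- tt
    hla[[pid]] <- planted$hla
    truth[[pid]] <- list(theta_true = th,
                         theta_planted = nShared / cfg$nTIL,
                         shared = sort(planted$shared),
                         near_miss = sort(planted$nearMiss),
                         pathogen = sort(planted$pathogen))
  }
  list(reactive = reactive, til = til, epitopeDb = epitopeDb, hla = hla,
       metadata = metadata, truth = truth, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits AIRR TSVs (one per sample), a VDJdb-style TSV, an HLA typing TSV, a
#' metadata TSV and a ground-truth JSON, all parseable by the package's
#' readers.
#'
#' @param cohort result of [simulatePairedCohort()].
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(cohort$reactive)) {
    writeClonotypes(cohort$reactive[[pid]],
                    file.path(dir, paste0(pid, "_reactive.tsv")))
    writeClonotypes(cohort$til[[pid]],
                    file.path(dir, paste0(pid, "_til.tsv")))
  }
  db <- cohort$epitopeDb
  write.table(data.frame(gene = db$chain, cdr3 = db$cdr3_aa,
                         v.segm = db$v_gene, j.segm = db$j_gene,
                         mhc.a = db$mhc_allele,
                         antigen.species = db$antigen_species,
                         antigen.epitope = db$antigen_epitope),
              file.path(dir, "vdjdb.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hlaDf <- data.frame(patient_id = names(cohort$hla))
  for (k in 1:6)
    hlaDf[[paste0("allele_", k)]] <- vapply(cohort$hla, function(a)
      if (length(a) >= k) a[k] else "", character(1))
  write.table(hlaDf, file.path(dir, "hla.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- expression simulation -------------------------------------------------

#' Simulate a count matrix with a spiked gene signature
#'
#' Baseline counts are negative binomial with lognormal gene means
#' (dispersion size = 2, the overdispersion typical of droplet scRNA-seq
#' pseudo-counts); in a designated fraction of cells the signature genes'
#' means are multiplied by \code{exp(delta)}. Cell labels and patient labels
#' are emitted so scoring and per-patient frequency can be tested against
#' the planted truth.
#'
#' @param nGenes,nCells matrix dimensions.
#' @param nSignature number of signature genes (<= nGenes).
#' @param delta log-scale spike effect size.
#' @param spikedFraction fraction of cells spiked, in (0, 1).
#' @param nPatients patients to spread cells over (round-robin).
#' @param seed integer seed; fixed seed gives a bit-identical matrix.
#' @return list: \code{counts} (gene x cell integer matrix),
#'   \code{signature} (gene names), \code{cellGroup} ("spiked"/"control"),
#'   \code{patient} (per-cell labels).
#' @export
simulateExpression <- function(nGenes = 2000L, nCells = 500L,
                               nSignature = 25L, delta = 1,
                               spikedFraction = 0.3, nPatients = 4L,
                               seed = 1L) {
  stopifnot(nSignature <= nGenes)
  if (spikedFraction <= 0 || spikedFraction >= 1)
    stop("spikedFraction must lie in (0, 1)")
  .withSeed(seed, {
    genes <- sprintf("G%05d", seq_len(nGenes))
    cells <- sprintf("c%04d", seq_len(nCells))
    mu <- stats::rlnorm(nGenes, meanlog = log(0.5), sdlog = 1)
    sig <- sample(genes, nSignature)
    spiked <- sort(sample.int(nCells, round(spikedFraction * nCells)))
    group <- ifelse(seq_len(nCells) %in% spiked, "spiked", "control")
    M <- matrix(stats::rnbinom(nGenes * nCells, size = 2, mu = mu),
                nrow = nGenes, dimnames = list(genes, cells))
    sIdx <- match(sig, genes)
    M[sIdx, spiked] <- stats::rnbinom(length(sIdx) * length(spiked),
                                      size = 2, mu = mu[sIdx] * exp(delta))
    list(counts = M, signature = sort(sig), cellGroup = group,
         patient = sprintf("pt%d", (seq_len(nCells) %% nPatients) + 1L))
  })
}
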