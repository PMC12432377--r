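#' @importFrom utils read.delim write.table head
NULL

# Column sets that identify each dialect. Sniffing is exact-name keyed;
# files carrying sentinels of both dialects are rejected, not guessed.
.AIRR_SENTINELS  <- c("junction_aa", "v_call")
.MIXCR_SENTINELS <- c("aaSeqCDR3", "allVHitsWithScore")

#' Strip allele suffix from a V/J gene call
#'
#' Gene calls are truncated at the first \code{"*"} to gene level
#' (\code{"TRBV27*01"} -> \code{"TRBV27"}); MiXCR hit scores in parentheses
#' are dropped first. Allele-level calls from short-read bulk data are
#' unreliable, and all downstream analysis is at gene level. Idempotent.
#'
#' @param x character vector of gene calls.
#' @return character vector of gene-level names.
#' @examples
#' normalizeGene(c("TRBV27*01", "TRBV27*00(123.5)", "TRBV27"))
#' @export
normalizeGene <- function(x) {
  x <- sub("\\(.*$", "", x)        # MiXCR "GENE*00(score)"
  x <- sub("\\*.*$", "", x)
  x <- sub(",.*$", "", x)          # multi-hit lists: keep best hit
  trimws(x)
}

.chainFromGene <- function(v) ifelse(startsWith(v, "TRAV"), "TRA",
                              ifelse(startsWith(v, "TRBV"), "TRB", NA_character_))

.dropInvalidCdr3 <- function(df) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$cdr3_aa) & nchar(df$cdr3_aa) >= 5L
  nbad <- sum(!ok)
  if (nbad > 0)
    message(sprintf("dropped %d record(s) with stop codons, non-standard residues or CDR3 < 5 aa", nbad))
  df[ok, , drop = FALSE]
}

#' Read a clonotype table
#'
#' Reads one sample's clonotype table in either the AIRR Rearrangement TSV
#' dialect (\code{junction_aa}, \code{v_call}, \code{j_call},
#' \code{duplicate_count}, optional \code{locus}) or the MiXCR-export dialect
#' (\code{aaSeqCDR3}, \code{allVHitsWithScore}, \code{allJHitsWithScore},
#' \code{cloneCount}), normalizing into the internal model: CDR3s uppercased,
#' gene calls truncated to gene level, records with stop codons or
#' non-standard residues dropped with a message. Counts are taken as given
#' (reads or UMIs); no re-collapsing is performed.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect "airr", "mixcr" or "auto" (sniff by column names; a file
#'   carrying both dialects' sentinel columns is an error).
#' @param sampleID,patientID,compartment sample annotation
#'   (see [RepertoireTable()]).
#' @return An unfiltered [RepertoireTable-class] with raw counts.
#' @seealso [filterClonotypes()], [writeClonotypes()]
#' @export
readClonotypes <- function(path, dialect = c("auto", "airr", "mixcr"),
                           sampleID = basename(path), patientID = sampleID,
                           compartment = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- colnames(df)
  isAirr  <- all(.AIRR_SENTINELS %in% cols)
  isMixcr <- all(.MIXCR_SENTINELS %in% cols)
  if (dialect == "auto") {
    if (isAirr && isMixcr)
      stop("ambiguous dialect: file carries both AIRR and MiXCR sentinel columns")
    if (isAirr) dialect <- "airr"
    else if (isMixcr) dialect <- "mixcr"
    else stop("unknown dialect: no AIRR or MiXCR sentinel columns found")
  }
  map <- switch(dialect,
    airr  = c(cdr3 = "junction_aa", v = "v_call", j = "j_call",
              count = "duplicate_count"),
    mixcr = c(cdr3 = "aaSeqCDR3", v = "allVHitsWithScore",
              j = "allJHitsWithScore", count = "cloneCount"))
  miss <- setdiff(unname(map), cols)
  if (length(miss))
    stop("schema error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(RepertoireTable(data.frame(), sampleID, patientID, compartment))
  counts <- suppressWarnings(as.numeric(df[[map["count"]]]))
  if (anyNA(counts))
    stop("unparseable count at row(s): ",
         paste(which(is.na(counts)), collapse = ", "))
  out <- data.frame(
    v_gene  = normalizeGene(df[[map["v"]]]),
    j_gene  = normalizeGene(df[[map["j"]]]),
    cdr3_aa = toupper(trimws(df[[map["cdr3"]]])),
    count   = as.integer(round(counts)),
    stringsAsFactors = FALSE)
  out$chain <- if (dialect == "airr" && "locus" %in% cols)
    toupper(df$locus) else .chainFromGene(out$v_gene)
  out <- out[!is.na(out$chain), , drop = FALSE]
  out <- .dropInvalidCdr3(out)
  RepertoireTable(out, sampleID, patientID, compartment)
}

#' Write a clonotype table
#'
#' Writes a [RepertoireTable-class] back to disk. Write-then-read is the
#' identity on the internal model.
#'
#' @param x a RepertoireTable.
#' @param path output TSV path.
#' @param dialect "airr" (default) or "mixcr".
#' @return \code{path}, invisibly.
#' @export
writeClonotypes <- function(x, path, dialect = c("airr", "mixcr")) {
  dialect <- match.arg(dialect)
  cl <- as.data.frame(clonotypes(x))
  out <- switch(dialect,
    airr = data.frame(junction_aa = cl$cdr3_aa, v_call = cl$v_gene,
                      j_call = cl$j_gene, duplicate_count = cl$count,
                      locus = cl$chain, stringsAsFactors = FALSE),
    mixcr = data.frame(cloneCount = cl$count, aaSeqCDR3 = cl$cdr3_aa,
                       allVHitsWithScore = cl$v_gene,
                       allJHitsWithScore = cl$j_gene,
                       stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- HLA normalization -----------------------------------------------------

#' Normalize an HLA class-I allele string
#'
#' Normalizes to \code{"HLA-<locus>*<group>:<protein>"} (two-field) or to the
#' group-level prefix \code{"HLA-<locus>*<group>"} when only one field is
#' given. Extra fields beyond two are truncated; a missing \code{"HLA-"}
#' prefix is added. Idempotent.
#'
#' @param x character vector of allele strings (e.g. "A*02:01:03", "HLA-A*02").
#' @return character vector of normalized alleles.
#' @examples
#' normalizeHLA(c("A*02:01:03", "HLA-B*08", "hla-a*02:01"))
#' @export
normalizeHLA <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^HLA-", "", x)
  m <- regmatches(x, regexec("^([ABC])\\*?([0-9]+)(?::([0-9]+))?", x))
  vapply(seq_along(x), function(i) {
    p <- m[[i]]
    if (length(p) == 0L || p[2] == "") return(NA_character_)
    if (p[4] == "") sprintf("HLA-%s*%s", p[2], p[3])
    else sprintf("HLA-%s*%s:%s", p[2], p[3], p[4])
  }, character(1))
}

#' Is an allele string group-level (low resolution)?
#'
#' @param x normalized allele strings.
#' @return logical: TRUE where the allele lacks the protein field.
#' @export
isGroupLevelHLA <- function(x) !grepl(":", x)

# ---- VDJdb -----------------------------------------------------------------

#' Default pathogen species list
#'
#' Species names (VDJdb \code{antigen.species} convention) counted as
#' pathogens when annotating TIL clonotypes. The host species
#' ("HomoSapiens") and other self/tumor entries are deliberately excluded.
#'
#' @return character vector of species names.
#' @export
defaultPathogenSpecies <- function() {
  c("CMV", "EBV", "InfluenzaA", "HIV-1", "HCV", "HBV", "SARS-CoV-2",
    "HTLV-1", "YellowFeverVirus", "M.tuberculosis", "HSV-2", "DENV1",
    "DENV2", "DENV3/4", "HPV", "AdV")
}

#' Read a VDJdb-format epitope table
#'
#' Expects the VDJdb TSV export columns \code{gene} (chain), \code{cdr3},
#' \code{mhc.a}, \code{antigen.species} and optionally \code{antigen.epitope},
#' \code{v.segm}, \code{j.segm}. MHC alleles are normalized with
#' [normalizeHLA()]; records whose species is on \code{pathogenSpecies} are
#' flagged \code{antigen_category = "pathogen"}, all others (including host
#' self-antigens) \code{"other"}.
#'
#' @param path TSV path.
#' @param pathogenSpecies character vector of species counted as pathogens.
#' @return data.frame with columns chain, cdr3_aa, v_gene, j_gene,
#'   mhc_allele, mhc_group_level, antigen_species, antigen_epitope,
#'   antigen_category.
#' @export
readVDJdb <- function(path, pathogenSpecies = defaultPathogenSpecies()) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"mhc.a" %in% colnames(df))
    stop("schema error: missing MHC column 'mhc.a'")
  need <- c("gene", "cdr3", "antigen.species")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  allele <- normalizeHLA(df[["mhc.a"]])
  data.frame(
    chain = toupper(df$gene),
    cdr3_aa = toupper(trimws(df$cdr3)),
    v_gene = if ("v.segm" %in% colnames(df)) normalizeGene(df$v.segm) else NA_character_,
    j_gene = if ("j.segm" %in% colnames(df)) normalizeGene(df$j.segm) else NA_character_,
    mhc_allele = allele,
    mhc_group_level = isGroupLevelHLA(allele),
    antigen_species = df[["antigen.species"]],
    antigen_epitope = if ("antigen.epitope" %in% colnames(df))
      df[["antigen.epitope"]] else NA_character_,
    antigen_category = ifelse(df[["antigen.species"]] %in% pathogenSpecies,
                              "pathogen", "other"),
    stringsAsFactors = FALSE)
}

# ---- HLA typings & metadata ------------------------------------------------

#' Read per-patient HLA typings
#'
#' TSV with a \code{patient_id} column and up to six class-I allele columns
#' (any column whose name starts with "allele"). Alleles are normalized;
#' more than six alleles or a duplicated patient is an integrity error.
#'
#' @param path TSV path.
#' @return named list: patient_id -> character vector of normalized alleles.
#' @export
readHLA <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% colnames(df)) stop("schema error: missing patient_id")
  if (anyDuplicated(df$patient_id))
    stop("integrity error: duplicated patient_id in HLA table")
  acols <- grep("^allele", colnames(df), value = TRUE)
  if (!length(acols)) stop("schema error: no allele columns")
  out <- lapply(seq_len(nrow(df)), function(i) {
    al <- unlist(df[i, acols], use.names = FALSE)
    al <- al[!is.na(al) & nzchar(al)]
    if (length(al) > 6L)
      stop("integrity error: more than 6 class-I alleles for patient ",
           df$patient_id[i])
    al <- normalizeHLA(al)
    if (anyNA(al))
      stop("unparseable HLA allele for patient ", df$patient_id[i])
    if (!length(al))
      stop("integrity error: empty HLA typing for patient ", df$patient_id[i])
    al
  })
  stats::setNames(out, df$patient_id)
}

#' Read patient metadata
#'
#' TSV with columns \code{patient_id}, \code{histology} (ductal, lobular,
#' mucinous or other), \code{lymph_node_metastasis} (yes, no, ND) and
#' optionally \code{responder} (logical). Enum values are validated and a
#' duplicated patient is an integrity error.
#'
#' @param path TSV path.
#' @return data.frame of patient metadata.
#' @export
readMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "histology", "lymph_node_metastasis")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("integrity error: duplicated patient_id in metadata")
  if (!all(df$histology %in% c("ductal", "lobular", "mucinous", "other")))
    stop("invalid histology value(s)")
  if (!all(df$lymph_node_metastasis %in% c("yes", "no", "ND")))
    stop("invalid lymph_node_metastasis value(s)")
  if ("responder" %in% colnames(df)) df$responder <- as.logical(df$responder)
  df
}

# ---- expression matrices ---------------------------------------------------

#' Read a gene-by-cell expression matrix
#'
#' Either a Matrix-Market triplet directory (\code{matrix.mtx},
#' \code{genes.tsv}, \code{barcodes.tsv}) or a dense TSV with gene names in
#' the first column and one column per cell.
#'
#' @param path directory (MTX triplet) or TSV file (dense).
#' @return a sparse \link[Matrix]{dgCMatrix}, genes in rows, cells in columns.
#' @export
readExpressionMatrix <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- read.delim(file.path(path, "genes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    dimnames(m) <- list(genes, cells)
    return(methods::as(m, "CsparseMatrix"))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write a gene-by-cell matrix as an MTX triplet directory
#'
#' @param m matrix or sparse Matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeExpressionMatrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
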