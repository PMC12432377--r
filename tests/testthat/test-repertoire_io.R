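test_that("AIRR rows map onto the internal clonotype model", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count\tlocus",
               "CASSLGQETQYF\tTRBV27*01\tTRBJ2-5*01\t12\tTRB"), f)
  rt <- readClonotypes(f)
  cl <- clonotypes(rt)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$chain, "TRB")
  expect_equal(cl$cdr3_aa, "CASSLGQETQYF")
  expect_equal(cl$v_gene, "TRBV27")       # allele suffix stripped
  expect_equal(cl$j_gene, "TRBJ2-5")
  expect_equal(cl$count, 12L)
  expect_equal(cl$proportion, 1)
})

test_that("MiXCR-export rows map, with hit scores stripped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cloneCount\taaSeqCDR3\tallVHitsWithScore\tallJHitsWithScore",
               "40\tCASSIRSSYEQYF\tTRBV19*00(1024.5)\tTRBJ2-7*00(210)"), f)
  cl <- clonotypes(readClonotypes(f))
  expect_equal(cl$v_gene, "TRBV19")
  expect_equal(cl$j_gene, "TRBJ2-7")
  expect_equal(cl$chain, "TRB")
  expect_equal(cl$count, 40L)
})

test_that("header-only files give an empty repertoire", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("junction_aa\tv_call\tj_call\tduplicate_count\tlocus", f)
  expect_equal(nClonotypes(readClonotypes(f)), 0L)
})

test_that("dialect errors: ambiguous, unknown, missing column, bad count", {
  amb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("junction_aa", "v_call", "j_call", "duplicate_count",
                     "aaSeqCDR3", "allVHitsWithScore", sep = "\t"),
               "CASSLGQETQYF\tTRBV27\tTRBJ2-5\t12\tCASSLGQETQYF\tTRBV27"),
             amb)
  expect_error(readClonotypes(amb), "ambiguous dialect")

  unk <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), unk)
  expect_error(readClonotypes(unk), "unknown dialect")

  mis <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tduplicate_count",
               "CASSLGQETQYF\tTRBV27\t5"), mis)
  expect_error(readClonotypes(mis), "missing mandatory column")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count\tlocus",
               "CASSLGQETQYF\tTRBV27\tTRBJ2-5\t10\tTRB",
               "CASSLGRETQYF\tTRBV27\tTRBJ2-5\tnot_a_number\tTRB"), bad)
  expect_error(readClonotypes(bad), "row.*2")
})

test_that("records with stop codons or short CDR3s are dropped with a message", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count\tlocus",
               "CASSLGQETQYF\tTRBV27\tTRBJ2-5\t10\tTRB",
               "CASS_GQETQYF\tTRBV27\tTRBJ2-5\t10\tTRB",
               "CAF\tTRBV27\tTRBJ2-5\t10\tTRB"), f)
  expect_message(rt <- readClonotypes(f), "dropped 2")
  expect_equal(nClonotypes(rt), 1L)
})

test_that("write-then-read is the identity for both dialects (seeded property)", {
  for (seed in 1:5) {
    rt <- randomRepertoire(25, seed)
    for (d in c("airr", "mixcr")) {
      f <- withr::local_tempfile(fileext = ".tsv")
      writeClonotypes(rt, f, dialect = d)
      back <- readClonotypes(f, dialect = d)
      expect_equal(as.data.frame(clonotypes(back)),
                   as.data.frame(clonotypes(rt)))
    }
  }
})

test_that("gene and HLA normalization are idempotent", {
  g <- c("TRBV27*01", "TRBV20-1*00(42)", "TRAJ33")
  expect_identical(normalizeGene(normalizeGene(g)), normalizeGene(g))
  h <- c("A*02:01:03", "HLA-B*08", "hla-c*07:01")
  expect_identical(normalizeHLA(normalizeHLA(h)), normalizeHLA(h))
  expect_equal(normalizeHLA("A*02:01:03"), "HLA-A*02:01")
  expect_equal(normalizeHLA("HLA-A*02"), "HLA-A*02")
  expect_true(isGroupLevelHLA("HLA-A*02"))
  expect_false(isGroupLevelHLA("HLA-A*02:01"))
})

test_that("VDJdb reader flags pathogens, excludes host species, keeps low-res alleles", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcdr3\tv.segm\tj.segm\tmhc.a\tantigen.species\tantigen.epitope",
               "TRB\tCASSIRSSYEQYF\tTRBV19*01\tTRBJ2-7\tHLA-A*02:01\tInfluenzaA\tGILGFVFTL",
               "TRB\tCASSLAPGATNEKLFF\tTRBV7-9\tTRBJ1-4\tHLA-A*02\tCMV\tNLVPMVATV",
               "TRB\tCASSPTGGELFF\tTRBV28\tTRBJ2-2\tHLA-B*08:01\tHomoSapiens\tELAGIGILTV"),
             f)
  db <- readVDJdb(f)
  expect_equal(db$antigen_category, c("pathogen", "pathogen", "other"))
  expect_equal(db$mhc_allele[2], "HLA-A*02")
  expect_true(db$mhc_group_level[2])
  expect_false(db$mhc_group_level[1])

  nom <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcdr3\tantigen.species", "TRB\tCASSLGQETQYF\tCMV"), nom)
  expect_error(readVDJdb(nom), "missing MHC column")
})

test_that("HLA reader normalizes and enforces integrity limits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tallele_1\tallele_2\tallele_3\tallele_4",
               "P1\tA*02:01\tA*01:01\tB*07:02\tC*07:01",
               "P2\tHLA-A*03:01\tB*08:01\t\t"), f)
  hla <- readHLA(f)
  expect_equal(hla$P1[1], "HLA-A*02:01")
  expect_length(hla$P2, 2L)

  seven <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste0("patient_id\t", paste0("allele_", 1:7, collapse = "\t")),
               paste0("P1\t", paste(rep("A*02:01", 7), collapse = "\t"))),
             seven)
  expect_error(readHLA(seven), "more than 6")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tallele_1", "P1\tA*02:01", "P1\tA*01:01"), dup)
  expect_error(readHLA(dup), "duplicated patient_id")
})

test_that("the packaged cohort roster parses into 23 patient records", {
  meta <- readMetadata(rosterPath())
  expect_equal(nrow(meta), 23L)
  expect_equal(as.integer(table(meta$histology)[c("ductal", "lobular", "mucinous")]),
               c(14L, 7L, 2L))
  expect_equal(as.integer(table(meta$lymph_node_metastasis)[c("yes", "no", "ND")]),
               c(10L, 12L, 1L))
})

test_that("metadata reader validates enums and duplicates", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\thistology\tlymph_node_metastasis",
               "P1\tductal\tmaybe"), bad)
  expect_error(readMetadata(bad), "lymph_node_metastasis")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\thistology\tlymph_node_metastasis",
               "P1\tductal\tyes", "P1\tlobular\tno"), dup)
  expect_error(readMetadata(dup), "duplicated")
})

test_that("expression matrices round-trip through MTX and dense TSV", {
  m <- matrix(rpois(20, 3), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("c", 1:4)))
  d <- withr::local_tempdir()
  writeExpressionMatrix(m, d)
  back <- readExpressionMatrix(d)
  expect_equal(as.matrix(back), m)

  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  dense <- readExpressionMatrix(f)
  expect_equal(as.matrix(dense), m)
})
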