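tilOf <- function(cdr3, v = "TRBV27") {
  n <- length(cdr3)
  RepertoireTable(data.frame(chain = rep_len("TRB", n),
                             v_gene = rep_len(v, n),
                             j_gene = rep_len("TRBJ2-5", n),
                             cdr3_aa = cdr3, count = rep(10L, n),
                             stringsAsFactors = FALSE),
                  sampleID = "til", compartment = "til")
}

test_that("exact match fraction counts TIL clonotypes over TIL clonotypes", {
  reactive <- tilOf("CASSLGQETQYF")
  til <- tilOf(c("CASSLGQETQYF", "CASSAPLGQYNEQFF", "CAWSVGDMNTEAFF",
                 "CASRPGLAGGRPEQYF"))
  r <- exactMatchFraction(reactive, til)
  expect_equal(r@exactFraction, 0.25)          # 1 of 4
  expect_equal(r@nTIL, 4L)

  none <- exactMatchFraction(reactive, tilOf(c("CAWSVGDMNTEAFF",
                                               "CASRPGLAGGRPEQYF")))
  expect_equal(none@exactFraction, 0)
  expect_error(exactMatchFraction(reactive, tilOf(character())), "undefined")
})

test_that("matching is CDR3-only: same CDR3 under two V genes counts twice", {
  reactive <- tilOf("CASSLGQETQYF")
  til <- RepertoireTable(data.frame(
    chain = "TRB", v_gene = c("TRBV27", "TRBV19", "TRBV28", "TRBV9"),
    j_gene = "TRBJ2-5",
    cdr3_aa = c("CASSLGQETQYF", "CASSLGQETQYF", "CAWSVGDMNTEAFF",
                "CASRPGLAGGRPEQYF"),
    count = rep(10L, 4)), compartment = "til")
  r <- exactMatchFraction(reactive, til)
  expect_equal(r@nExact, 2L)                   # both clonotypes
  expect_equal(r@exactFraction, 0.5)
  # optional V/J-restricted mode only matches the right V
  rv <- exactMatchFraction(reactive, til, requireVJ = TRUE)
  expect_equal(rv@nExact, 1L)
  # sequence-counting mode counts the CDR3 string once
  rs <- exactMatchFraction(reactive, til, countSequences = TRUE)
  expect_equal(rs@nExact, 1L)
})

test_that("cluster extension adds similar sequences, denominator unchanged", {
  reactive <- tilOf("CASSWWQETQYF")
  tilSeqs <- c("CASSWWQETQYF",                # exact
               "CASSWWRETQYF",                # one interior mismatch
               paste0("CASS", strsplit("ADEGHKLNPRSTVWYQIMFC", "")[[1]][1:18],
                      "PLGNTIYF"))            # 18 unrelated
  til <- tilOf(tilSeqs)
  cs <- buildClusters(list(reactive = "CASSWWQETQYF",
                           til = unique(tilSeqs)))
  r <- clusterExtendedFraction(reactive, til, cs)
  expect_equal(r@nTIL, 20L)
  expect_equal(r@exactFraction, 1 / 20)
  expect_equal(r@extendedFraction - r@exactFraction, 0.05)  # one similar in 20
  expect_true(all(c("exact", "cluster") %in% r@matches$match_type))

  # no similar sequences: extended == exact
  cs0 <- buildClusters(list(reactive = "CASSWWQETQYF",
                            til = "CAWSVGDMNTEAFF"))
  r0 <- clusterExtendedFraction(reactive, tilOf("CAWSVGDMNTEAFF"), cs0)
  expect_equal(r0@extendedFraction, r0@exactFraction)

  # saturation: every TIL CDR3 in a reactive cluster
  sat <- tilOf(c("CASSWWQETQYF", "CASSWWRETQYF"))
  csS <- buildClusters(list(reactive = "CASSWWQETQYF",
                            til = c("CASSWWQETQYF", "CASSWWRETQYF")))
  expect_equal(clusterExtendedFraction(reactive, sat, csS)@extendedFraction, 1)
})

test_that("pathogen fraction enforces HLA restriction at both resolutions", {
  db <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSIRSSYEQYF", "CASSLAPGATNEKLFF", "CASSPTGGELFF"),
    v_gene = NA, j_gene = NA,
    mhc_allele = c("HLA-A*02:01", "HLA-A*02", "HLA-B*08:01"),
    mhc_group_level = c(FALSE, TRUE, FALSE),
    antigen_species = c("InfluenzaA", "CMV", "HomoSapiens"),
    antigen_epitope = NA,
    antigen_category = c("pathogen", "pathogen", "other"),
    stringsAsFactors = FALSE)
  til <- tilOf(c("CASSIRSSYEQYF", "CASSLAPGATNEKLFF", "CASSPTGGELFF",
                 "CAWSVGDMNTEAFF"))

  # patient lacks any A*02 allele: the A*02:01-restricted match is not counted
  r1 <- pathogenFraction(til, db, c("HLA-A*01:01", "HLA-B*07:02"))
  expect_equal(r1@pathogenFraction, 0)

  # two-field patient allele matches both the exact record and the
  # group-level record by prefix
  r2 <- pathogenFraction(til, db, c("HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(r2@pathogenFraction, 2 / 4)

  # host-species (self) records never count toward the pathogen fraction
  r3 <- pathogenFraction(til, db, "HLA-B*08:01")
  expect_equal(r3@pathogenFraction, 0)

  # row order of the database is irrelevant
  r4 <- pathogenFraction(til, db[c(3, 1, 2), ], c("HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(r4@pathogenFraction, r2@pathogenFraction)

  expect_error(pathogenFraction(til, db, character()), "empty HLA")
})

test_that("exact fraction recovers the planted theta and vanishes at theta 0", {
  cfg <- cohortConfig(nPatients = 1, nNodePositive = 0, nTIL = 500,
                      nBloodReactive = 150,
                      theta = c(no = 0.2, yes = 0), seed = 5)
  ch <- simulatePairedCohort(cfg)
  r <- exactMatchFraction(ch$reactive$P01, ch$til$P01)
  expect_equal(r@exactFraction, ch$truth$P01$theta_planted)
  expect_equal(r@exactFraction, 0.2, tolerance = 0.05)

  cfg0 <- cohortConfig(nPatients = 2, nNodePositive = 1, nTIL = 200,
                       theta = c(no = 0, yes = 0), nNearMiss = 0, seed = 6)
  ch0 <- suppressWarnings(simulatePairedCohort(cfg0))
  for (pid in names(ch0$til))
    expect_equal(exactMatchFraction(ch0$reactive[[pid]],
                                    ch0$til[[pid]])@exactFraction, 0)
})

test_that("estimator bias shrinks with repertoire size (parameter recovery)", {
  bias <- vapply(c(100L, 1000L), function(n) {
    cfg <- cohortConfig(nPatients = 1, nNodePositive = 0, nTIL = n,
                        nBloodReactive = 200,
                        theta = c(no = 0.1, yes = 0), seed = 11)
    ch <- simulatePairedCohort(cfg)
    exactMatchFraction(ch$reactive$P01, ch$til$P01)@exactFraction - 0.1
  }, numeric(1))
  expect_lte(abs(bias[2]), abs(bias[1]) + 1e-9)
  expect_lte(abs(bias[2]), 0.001)     # ceiling(0.1 * 1000)/1000 is exact
})

test_that("cohort report groups by lymph-node status and orders group medians", {
  cfg <- cohortConfig(nPatients = 6, nNodePositive = 3, nTIL = 300,
                      theta = c(no = 0.10, yes = 0.01), seed = 21)
  ch <- simulatePairedCohort(cfg)
  reports <- lapply(names(ch$til), function(pid)
    exactMatchFraction(ch$reactive[[pid]], ch$til[[pid]]))
  cr <- cohortReport(reports, ch$metadata)
  byLN <- cr$by_lymph_node
  expect_gt(byLN$median_fraction[byLN$group == "no"],
            byLN$median_fraction[byLN$group == "yes"])
  expect_equal(sum(byLN$n), 6L)
  expect_true(is.finite(cr$p_lymph_node))

  # a patient absent from metadata is an integrity error
  expect_error(cohortReport(reports, ch$metadata[-1, ]), "integrity")

  # ND status: excluded from grouping, retained per patient
  meta2 <- ch$metadata
  meta2$lymph_node_metastasis[1] <- "ND"
  cr2 <- cohortReport(reports, meta2)
  expect_equal(nrow(cr2$per_patient), 6L)
  expect_equal(sum(cr2$by_lymph_node$n), 5L)
})

test_that("extended fraction dominates exact fraction across a cohort", {
  cfg <- cohortConfig(nPatients = 4, nNodePositive = 2, nTIL = 200,
                      nNearMiss = 3, seed = 31)
  ch <- simulatePairedCohort(cfg)
  for (pid in names(ch$til)) {
    rC <- unique(clonotypes(ch$reactive[[pid]])$cdr3_aa)
    tC <- unique(clonotypes(ch$til[[pid]])$cdr3_aa)
    cs <- buildClusters(list(reactive = rC, til = tC))
    r <- clusterExtendedFraction(ch$reactive[[pid]], ch$til[[pid]], cs)
    expect_gte(r@extendedFraction, r@exactFraction)
  }
})
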