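test_that("interior trimming follows the head/tail convention", {
  expect_equal(cdr3Interior("CASSKGASGNEQFF"), "SKGASGNEQ")
  expect_equal(cdr3Interior("CASSF"), "")          # 5 residues: empty interior
  expect_true(is.na(cdr3Interior("CASF")))         # too short: flagged
  expect_equal(cdr3Interior("CASSKGF", 0, 0), "CASSKGF")
})

test_that("motif enrichment agrees with a fisher.test oracle", {
  # motif GQE present in 5/10 sample interiors and 0/1000 reference interiors
  sample10 <- c(sprintf("CASS%sGQETQYF", c("A", "D", "E", "G", "H")),
                sprintf("CASS%sWNPTQYF", c("A", "D", "E", "G", "H")))
  set.seed(42)
  ref <- vapply(1:1000, function(i)
    paste0("CASS", paste(sample(c("A", "D", "E", "H", "K", "L", "N", "P",
                                  "R", "S", "T", "V", "W", "Y"), 7,
                                replace = TRUE), collapse = ""), "F"),
    character(1))
  ref <- unique(ref[!grepl("GQE", cdr3Interior(ref))])
  mots <- enrichedMotifs(sample10, ref, kSet = 3, minOcc = 3)
  expect_true("GQE" %in% mots$motif)
  row <- mots[mots$motif == "GQE", ]
  expect_equal(row$sample_count, 5L)
  expect_equal(row$ref_count, 0L)
  # independent oracle: one-sided Fisher exact on the same 2x2 table
  ns <- length(unique(sample10)); nr <- length(ref)
  oracle <- fisher.test(matrix(c(5, ns - 5, 0, nr), 2, byrow = TRUE),
                        alternative = "greater")$p.value
  expect_equal(row$p_value, oracle, tolerance = 1e-12)
  # fold with reference pseudocount: (5/10) / (1/nr)
  expect_equal(row$fold, (5 / ns) / (1 / nr))
})

test_that("motif thresholds: null enrichment, occurrence floor, empty sample", {
  seqs <- sprintf("CASS%sGQETQYF", c("A", "D", "E", "G", "H", "K", "L", "N"))
  expect_equal(nrow(enrichedMotifs(seqs, seqs)), 0L)   # sample == reference
  # motif in only 2 sample CDR3s is rejected regardless of p
  two <- c("CASSWWQETQYF", "CASSWWPDTQYF")
  ref <- sprintf("CASS%sGQETQYF", c("A", "D", "E", "G", "H", "K", "L", "N"))
  m <- enrichedMotifs(two, ref, kSet = 2, minOcc = 3)
  expect_false("WW" %in% m$motif)
  expect_equal(nrow(enrichedMotifs(character(), ref)), 0L)
  expect_error(enrichedMotifs(two, character()), "reference")
})

test_that("global pairs require equal length and one interior mismatch", {
  # printed sequences from distinct specificity groups: no pair
  expect_equal(nrow(globalPairs(c("CASSPLGPQETQYF", "CASSKGASGNEQFF"))), 0L)
  # identical strings collapse to one node: no self-pair
  expect_equal(nrow(globalPairs(c("CASSLGQETQYF", "CASSLGQETQYF"))), 0L)
  # exactly one interior mismatch: paired
  gp <- globalPairs(c("CASSLGQETQYF", "CASSLGRETQYF"))
  expect_equal(nrow(gp), 1L)
  expect_equal(oracleHamming("CASSLGQETQYF", "CASSLGRETQYF"), 1)
  # two interior mismatches: not paired
  expect_equal(nrow(globalPairs(c("CASSLGQETQYF", "CASSLGRRTQYF"))), 0L)
  # length mismatch: not paired even if interiors align
  expect_equal(nrow(globalPairs(c("CASSLGQETQYF", "CASSLGQETQYFF"))), 0L)
})

test_that("global pairs match a per-pair Hamming oracle on random sets", {
  cfg <- cohortConfig()
  for (seed in 1:3) {
    cdr3s <- unique(clonotypes(simulateRepertoire(60, seed, cfg))$cdr3_aa)
    gp <- globalPairs(cdr3s)
    found <- paste(gp$from, gp$to)
    for (i in seq_along(cdr3s)) for (j in seq_len(i - 1L)) {
      a <- cdr3s[j]; b <- cdr3s[i]
      ok <- nchar(a) == nchar(b) &&
        oracleHamming(cdr3Interior(a), cdr3Interior(b)) <= 1
      pair <- paste(min(a, b), max(a, b))
      expect_equal(pair %in% found, ok)
    }
  }
})

test_that("clusters are connected components (incl. mixed edge types)", {
  # no edges: all singleton clusters
  iso <- c("CASSAPLGQYNEQFF", "CAWSVGDMNTEAFF", "CASRPGLAGGRPEQYF")
  cs <- buildClusters(list(s = iso))
  expect_equal(length(unique(clusterMembership(cs))), 3L)

  # a-b global, b-c local (shared planted motif) -> one cluster
  a <- "CASSWWQETQYF"; b <- "CASSWWRETQYF"; c3 <- "CASSPDWWGNTIYF"
  ref <- unique(clonotypes(randomRepertoire(300, 99))$cdr3_aa)
  ref <- ref[!grepl("WW", ref)]
  cs2 <- buildClusters(list(s = c(a, b, c3)), reference = ref,
                       kSet = 2, minOcc = 3)
  memb <- clusterMembership(cs2)
  expect_equal(length(unique(memb)), 1L)
  expect_true(all(c("global", "local") %in% cs2@edges$type))
})

test_that("components equal the brute-force transitive-closure oracle", {
  cfg <- cohortConfig()
  for (seed in 1:5) {
    cdr3s <- unique(clonotypes(simulateRepertoire(50, seed, cfg))$cdr3_aa)
    cs <- buildClusters(list(s = cdr3s))
    ed <- as.data.frame(cs@edges)
    oracle <- oracleComponents(sort(cdr3s), ed$from, ed$to)
    expect_equal(canonicalPartition(clusterMembership(cs)),
                 canonicalPartition(oracle))
  }
})

test_that("clustering is invariant to input order and label renaming", {
  cdr3s <- unique(clonotypes(randomRepertoire(40, 13))$cdr3_aa)
  cs1 <- buildClusters(list(x = cdr3s))
  cs2 <- buildClusters(list(zz = rev(cdr3s)))
  expect_equal(canonicalPartition(clusterMembership(cs1)),
               canonicalPartition(clusterMembership(cs2)))
})

test_that("stricter motif thresholds never merge clusters", {
  # plant a 3-mer motif in several sequences so local edges exist; members
  # differ pairwise at two interior positions, so no global edges join them
  planted <- sprintf("CASS%sWGY%sQYF", c("A", "D", "E", "G", "H"),
                     c("D", "E", "G", "H", "A"))
  other <- c("CAWSVGDMNTEAFF", "CASRPGLAGGRPEQYF", "CASSFQGYNEQFHF")
  ref <- unique(clonotypes(randomRepertoire(300, 77))$cdr3_aa)
  ref <- ref[!grepl("WGY", ref)]
  loose <- buildClusters(list(s = c(planted, other)), reference = ref,
                         maxP = 1e-2, minFold = 2)
  strict <- buildClusters(list(s = c(planted, other)), reference = ref,
                          maxP = 1e-8, minFold = 1e6)
  expect_gte(length(unique(clusterMembership(strict))),
             length(unique(clusterMembership(loose))))
})

test_that("cluster-based expansion returns similar-but-not-identical TILs", {
  reactive <- c("CASSWWQETQYF", "CASSAPLGQYNEQFF")
  til <- c("CASSWWRETQYF",      # one interior mismatch: expand
           "CASSWWQETQYF",      # exact: excluded from expansion
           "CAWSVGDMNTEAFF")    # unrelated
  cs <- buildClusters(list(reactive = reactive, til = til))
  ex <- expandReactiveSet(reactive, til, cs)
  expect_equal(ex, "CASSWWRETQYF")
  # disjoint clusters -> empty expansion
  cs2 <- buildClusters(list(reactive = "CASSAPLGQYNEQFF",
                            til = "CAWSVGDMNTEAFF"))
  expect_equal(expandReactiveSet("CASSAPLGQYNEQFF", "CAWSVGDMNTEAFF", cs2),
               character(0))
  # coverage check
  expect_error(expandReactiveSet("CASSMISSINGF", til, cs), "cover")
  # summary reflects origins
  sm <- clusterSummary(cs)
  expect_true(any(sm$multi_origin))
})
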