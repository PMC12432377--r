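# shared fixtures and independent oracles for the test suite

# tiny repertoire from counts; CDR3s auto-generated unless given
makeRepertoire <- function(counts, cdr3 = NULL, chain = "TRB",
                           v = "TRBV27", j = "TRBJ2-5", sampleID = "s1",
                           compartment = "other") {
  n <- length(counts)
  if (is.null(cdr3))
    cdr3 <- if (n == 0L) character() else
      paste0("CASS", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(n)],
             "GANVLTF")
  RepertoireTable(data.frame(chain = rep_len(chain, n),
                             v_gene = rep_len(v, n), j_gene = rep_len(j, n),
                             cdr3_aa = cdr3, count = as.integer(counts),
                             stringsAsFactors = FALSE),
                  sampleID = sampleID, compartment = compartment)
}

# random valid clonotype table for round-trip property tests
randomRepertoire <- function(n, seed, chain = "TRB") {
  cfg <- cohortConfig(chain = chain,
                      vGenes = defaultVGenes(chain),
                      jGenes = defaultJGenes(chain))
  simulateRepertoire(n, seed, cfg, sampleID = paste0("rnd", seed))
}

# brute-force transitive closure over an edge list: boolean matrix powers
oracleComponents <- function(nodes, edgeFrom, edgeTo) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  for (i in seq_along(edgeFrom)) {
    A[edgeFrom[i], edgeTo[i]] <- TRUE
    A[edgeTo[i], edgeFrom[i]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # component id = index of first reachable node
  apply(A, 1, function(r) which(r)[1])
}

# independent Hamming distance via strsplit loop
oracleHamming <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  sum(sa != sb)
}

# canonical partition label: nodes sorted, cluster ids relabeled by first
# appearance, so two partitions compare as sets
canonicalPartition <- function(membership) {
  nodes <- sort(names(membership))
  m <- membership[nodes]
  match(m, unique(m))
}

rosterPath <- function() system.file("extdata", "cohort_roster.tsv",
                                     package = "tcrtrack")
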