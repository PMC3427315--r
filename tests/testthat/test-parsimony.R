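test_that("parsimony probability matches an independent straight-line implementation", {
  expect_equal(parsimonyProbability(0, 100), 1)
  expect_error(parsimonyProbability(101, 100),
               class = "taxlines_parsimony_error")
  # straight-line re-implementation, written directly from the estimator's
  # definition (product over already-hit site fractions)
  straight <- function(j, L) {
    out <- 1
    if (j >= 1) for (i in 0:(j - 1)) out <- out * (1 - i / L)
    out
  }
  for (L in c(100L, 500L, 613L, 1000L))
    for (j in c(1L, 2L, 5L, 10L, 20L))
      expect_equal(parsimonyProbability(j, L), straight(j, L),
                   tolerance = 1e-12)
})

test_that("parsimony probability matches a Monte-Carlo uniform-hits oracle", {
  set.seed(99)
  L <- 100L; j <- 6L; n <- 20000L
  hits <- replicate(n, anyDuplicated(sample.int(L, j, replace = TRUE)) == 0L)
  mc <- mean(hits)
  p <- parsimonyProbability(j, L)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(p - mc), 4 * se + 1e-6)
})

test_that("parsimony probability is monotone in steps and sites", {
  p <- parsimonyProbability(1:30, 600)
  expect_true(all(diff(p) < 0))
  expect_true(all(parsimonyProbability(1:20, 1000) >=
                    parsimonyProbability(1:20, 500)))
})

test_that("connection limit honours its definition and monotonicities", {
  for (L in c(360L, 613L, 700L)) {
    cl <- connectionLimit(L)
    expect_equal(cl@jMax, sum(parsimonyProbability(seq_len(cl@jMax + 1L), L)
                              >= 0.95))
    expect_gte(parsimonyProbability(cl@jMax, L), 0.95)
    expect_lt(parsimonyProbability(cl@jMax + 1L, L), 0.95)
    # table populated up to the first failure
    expect_length(cl@probabilities, cl@jMax + 1L)
    expect_true(all(diff(cl@probabilities) < 0))
  }
  # stricter limit (smaller alpha) -> smaller jMax; more sites -> larger jMax
  expect_lte(connectionLimit(600, alpha = 0.001)@jMax,
             connectionLimit(600, alpha = 0.05)@jMax)
  expect_lte(connectionLimit(600, alpha = 0.05)@jMax,
             connectionLimit(600, alpha = 0.2)@jMax)
  expect_lte(connectionLimit(600)@jMax, connectionLimit(1200)@jMax)
})

# haplotype set built by seeding a base sequence and mutating controlled
# numbers of distinct sites
mutatedHapSet <- function(steps, L = 300L, pops = NULL) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(steps, function(k) {
    s <- base
    if (k > 0) {
      sites <- sample.int(L, k)
      for (x in sites) s[x] <- setdiff(c("A", "C", "G", "T"), s[x])[1]
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("h%02d", seq_along(seqs))
  if (is.null(pops)) pops <- rep("P1", length(seqs))
  aln <- markerAlignment("m", seqs, tinyMeta(names(seqs), pops))
  collapseHaplotypes(aln, policy = "strict")
}

test_that("networks match brute-force graph components on small instances", {
  set.seed(55)
  hs <- mutatedHapSet(c(0, 1, 2, 25))
  np <- buildNetworks(hs)
  expect_s4_class(np, "NetworkPartition")
  # close haplotypes share a component, the 25-step one is independent
  expect_equal(np@membership[1], np@membership[2])
  expect_false(np@membership[1] == np@membership[4])

  for (rep in 1:20) {
    k <- sample(2:8, 1)
    hs <- mutatedHapSet(sample(0:20, k, replace = TRUE))
    np <- buildNetworks(hs)
    s <- hs@sequences
    n <- length(s)
    d <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      d[i, j] <- oracleSteps(s[i], s[j])
    oracle <- oracleComponents(d, np@limit@jMax)
    expect_identical(canonicalPartition(np@membership),
                     canonicalPartition(oracle))
    # all haplotypes within one step form a single component
    if (all(d <= 1)) expect_equal(nComponents(np), 1L)
  }
})

test_that("stricter limits only refine, looser limits only coarsen the partition", {
  set.seed(67)
  for (rep in 1:10) {
    hs <- mutatedHapSet(sample(0:12, 6, replace = TRUE), L = 250L)
    # smaller alpha demands higher confidence -> smaller jMax -> refinement
    strict <- buildNetworks(hs, connectionLimit(250L, alpha = 0.01))
    loose <- buildNetworks(hs, connectionLimit(250L, alpha = 0.2))
    expect_lte(strict@limit@jMax, loose@limit@jMax)
    # every strict component is contained in one loose component
    for (comp in strict@components)
      expect_length(unique(loose@membership[comp]), 1L)
  }
})

test_that("independence is exclusivity, not connectivity", {
  set.seed(21)
  # population X split over two far-apart haplotypes, population Y far from
  # both: X is independent although internally disconnected
  hs <- mutatedHapSet(c(0, 60, 120), pops = c("X", "X", "Y"))
  np <- buildNetworks(hs)
  expect_equal(nComponents(np), 3L)
  expect_true(isIndependentNetwork(np, "X"))
  expect_true(isIndependentNetwork(np, "Y"))
  expect_error(isIndependentNetwork(np, "Z"),
               class = "taxlines_population_error")

  # a shared haplotype breaks independence for both carriers
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  aln <- markerAlignment("m", c(a = base, b = base),
                         tinyMeta(c("a", "b"), c("X", "Y")))
  np2 <- buildNetworks(collapseHaplotypes(aln))
  expect_false(isIndependentNetwork(np2, "X"))
  expect_false(isIndependentNetwork(np2, "Y"))
})

test_that("edges carry step annotations and intermediate counts", {
  set.seed(3)
  hs <- mutatedHapSet(c(0, 3))
  np <- buildNetworks(hs)
  expect_equal(nrow(np@edges), 1L)
  expect_equal(np@edges$steps, 3L)
  expect_equal(np@edges$intermediates, 2L)

  csv <- tempfile(fileext = ".csv")
  writeNetwork(np, csv)
  expect_equal(read.csv(csv)$steps, 3L)
  gml <- tempfile(fileext = ".gml")
  writeNetwork(np, gml, format = "gml")
  txt <- readLines(gml)
  expect_equal(sum(grepl("^  node \\[", txt)), nHaplotypes(hs))
  expect_equal(sum(grepl("^  edge \\[", txt)), 1L)
})
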