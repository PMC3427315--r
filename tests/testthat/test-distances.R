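test_that("pDistance handles forced cases and missing data", {
  expect_equal(pDistance("ACGT", "ACGT"), 0)
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  # gap excluded under pairwise deletion: 0 differences over 3 sites
  expect_equal(pDistance("AC-T", "ACGT"), 0)
  expect_equal(pDistance("ACRT", "ACGT"), 0)  # ambiguity treated as missing
  expect_error(pDistance("NNNN", "ACGT"), class = "taxlines_distance_error")
  expect_error(pDistance("ACG", "ACGT"), class = "taxlines_alignment_error")
})

test_that("distanceMatrix matches an independent double loop to machine precision", {
  md3 <- tinyMeta(c("a", "b", "c"), rep("P1", 3))
  zero <- distanceMatrix(markerAlignment("m", c(a = "ACGT", b = "ACGT",
                                                c = "ACGT"), md3))
  expect_true(all(zero@d == 0))

  two <- distanceMatrix(markerAlignment("m", c(a = "ACGTACGT", b = "ACCTACGA"),
                                        tinyMeta(c("a", "b"), c("P1", "P2"))))
  expect_equal(two@d["a", "b"], pDistance("ACGTACGT", "ACCTACGA"))

  set.seed(23)
  for (rep in 1:5) {
    aln <- randomAlignment(5, 20, missFrac = 0.15)
    dm <- distanceMatrix(aln)
    s <- as.character(aln@seqs)
    for (i in 1:4) for (j in (i + 1):5)
      expect_identical(dm@d[i, j], oraclePDist(s[[i]], s[[j]]))
    expect_identical(dm@d, t(dm@d))
  }
})

test_that("distanceMatrix agrees with ape's raw pairwise-deletion distance", {
  skip_if_not_installed("ape")
  set.seed(5)
  aln <- randomAlignment(6, 200, missFrac = 0.05)
  dm <- distanceMatrix(aln)
  bin <- ape::as.DNAbin(strsplit(tolower(as.character(aln@seqs)), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm@d), unname(ref[sampleIDs(aln), sampleIDs(aln)]),
               tolerance = 1e-12)
})

test_that("group summaries match exhaustive enumeration and flag singletons", {
  set.seed(31)
  pops <- rep(c("A", "B", "C"), each = 2)
  aln <- randomAlignment(6, 40, pops = pops)
  dm <- distanceMatrix(aln)
  sm <- groupDistanceSummary(dm, as.data.frame(aln@metadata))
  tab <- summaryTable(sm)
  # oracle: classify every unordered sample pair by hand
  s <- as.character(aln@seqs)
  vals <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    key <- paste(sort(c(pops[i], pops[j])), collapse = "|")
    vals[[key]] <- c(vals[[key]], 100 * oraclePDist(s[[i]], s[[j]]))
  }
  for (r in seq_len(nrow(tab))) {
    key <- paste(sort(c(tab$group1[r], tab$group2[r])), collapse = "|")
    expect_equal(tab$n_pairs[r], length(vals[[key]]))
    expect_equal(tab$min[r], round(min(vals[[key]]), 1))
    expect_equal(tab$mean[r], round(mean(vals[[key]]), 1))
    expect_equal(tab$max[r], round(max(vals[[key]]), 1))
  }
  # singleton population: within record absent (NA), not zero
  aln1 <- randomAlignment(3, 40, pops = c("A", "A", "B"))
  tab1 <- summaryTable(groupDistanceSummary(distanceMatrix(aln1),
                                            as.data.frame(aln1@metadata)))
  w <- tab1[tab1$scope == "within" & tab1$group1 == "B", ]
  expect_equal(w$n_pairs, 0)
  expect_true(is.na(w$max))
})

test_that("clade-pair max equals max over constituent population-pair maxima", {
  set.seed(77)
  pops <- rep(c("A", "B", "C", "D"), each = 3)
  clades <- c(A = "X", B = "X", C = "Y", D = "Y")
  aln <- randomAlignment(12, 60, pops = pops)
  dm <- distanceMatrix(aln)
  md <- as.data.frame(aln@metadata)
  popTab <- summaryTable(groupDistanceSummary(dm, md))
  clTab <- summaryTable(groupDistanceSummary(dm, md, grouping = clades))
  xy <- clTab[clTab$scope == "between", ]
  cross <- popTab[popTab$scope == "between" &
                    clades[popTab$group1] != clades[popTab$group2], ]
  expect_equal(xy$max, max(cross$max))
})

test_that("threshold comparison is inclusive at the boundary", {
  mk <- function(pct) {
    L <- 1000L
    base <- paste(rep("A", L), collapse = "")
    other <- paste(c(rep("C", round(pct * 10)),
                     rep("A", L - round(pct * 10))), collapse = "")
    aln <- markerAlignment("COI", c(a = base, b = other),
                           tinyMeta(c("a", "b"), c("P1", "P2")))
    groupDistanceSummary(distanceMatrix(aln), as.data.frame(aln@metadata))
  }
  atBoundary <- thresholdComparison(mk(8.3), 8.3)
  expect_equal(atBoundary@table$relation, "meets-or-exceeds")
  above <- thresholdComparison(mk(9.1), 8.3)
  expect_equal(above@table$relation, "meets-or-exceeds")
  below <- thresholdComparison(mk(5.8), 8.3)
  expect_equal(below@table$relation, "below")
})

test_that("UPGMA grouping recovers the two island clades and breaks ties lexicographically", {
  pops <- c("Anjouan", "GrandComoro", "Mayotte", "Moheli")
  d <- matrix(0.095, 4, 4, dimnames = list(pops, pops))
  diag(d) <- 0
  d["Anjouan", "Mayotte"] <- d["Mayotte", "Anjouan"] <- 0.054
  d["GrandComoro", "Moheli"] <- d["Moheli", "GrandComoro"] <- 0.077
  dm <- methods::new("DistanceMatrix", samples = pops, d = d,
                     marker = "cytb", deletion = "pairwise")
  md <- tinyMeta(pops, pops)
  g <- upgmaGrouping(dm, md, k = 2)
  expect_equal(g[["Anjouan"]], g[["Mayotte"]])
  expect_equal(g[["GrandComoro"]], g[["Moheli"]])
  expect_false(g[["Anjouan"]] == g[["GrandComoro"]])

  g4 <- upgmaGrouping(dm, md, k = 4)
  expect_equal(length(unique(g4)), 4L)
  expect_error(upgmaGrouping(dm, md, k = 5), class = "taxlines_grouping_error")

  # equidistant candidates: the lexicographically first pair merges
  pops3 <- c("Alpha", "Beta", "Gamma")
  d3 <- matrix(0.5, 3, 3, dimnames = list(pops3, pops3)); diag(d3) <- 0
  dm3 <- methods::new("DistanceMatrix", samples = pops3, d = d3,
                      marker = "m", deletion = "pairwise")
  g3 <- upgmaGrouping(dm3, tinyMeta(pops3, pops3), k = 2)
  expect_equal(g3[["Alpha"]], g3[["Beta"]])
  expect_false(g3[["Gamma"]] == g3[["Alpha"]])
})

test_that("UPGMA agrees with hclust average linkage on tie-free data", {
  set.seed(13)
  pops <- paste0("P", 1:6)
  d <- matrix(0, 6, 6, dimnames = list(pops, pops))
  d[upper.tri(d)] <- runif(15, 0.01, 0.2)
  d <- d + t(d)
  dm <- methods::new("DistanceMatrix", samples = pops, d = d, marker = "m",
                     deletion = "pairwise")
  for (k in 2:4) {
    g <- upgmaGrouping(dm, tinyMeta(pops, pops), k = k)
    ref <- stats::cutree(stats::hclust(stats::as.dist(d), "average"), k = k)
    expect_identical(canonicalPartition(as.integer(factor(g[pops]))),
                     canonicalPartition(as.integer(ref[pops])))
  }
})
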