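test_that("candidate designation follows the UCS/CCS/DCL definitions", {
  expect_equal(designateCandidate(TRUE, TRUE), "CCS")
  expect_equal(designateCandidate(TRUE, FALSE), "UCS")
  expect_equal(designateCandidate(TRUE, FALSE, sympatricNoAdmixture = TRUE),
               "CCS")
  expect_equal(designateCandidate(TRUE, FALSE, admixture = TRUE), "DCL")
  expect_equal(designateCandidate(TRUE, FALSE, explicitlySlight = TRUE),
               "DCL")
  expect_true(is.na(designateCandidate(FALSE, FALSE)))
  expect_error(designateCandidate(TRUE, TRUE, sympatricNoAdmixture = TRUE,
                                  admixture = TRUE),
               class = "taxlines_evidence_error")
})

# build the preset evidence inputs once for the profile tests
presetEvidence <- local({
  cfg <- comoroPreset(seed = 11)
  alns <- lapply(setNames(names(cfg@markers), names(cfg@markers)),
                 function(m) simulateSequences(cfg, m))
  haps <- lapply(alns, collapseHaplotypes)
  parts <- lapply(haps, buildNetworks)
  morph <- simulateMorphology(cfg)
  list(cfg = cfg, haps = haps, parts = parts, morph = morph)
})

test_that("evaluateLines reproduces the island candidate profiles", {
  ev <- presetEvidence
  # single island vs its sister: independent cyt b network, one Rag2
  # substitution (below the default minimum of 2), no non-graded fixed
  # character
  anj <- evaluateLines("Anjouan", "Anjouan", "Mayotte", ev$parts, ev$haps,
                       ev$morph, designate = FALSE)
  expect_true(anj@mtdna)
  expect_false(anj@ndna)
  expect_equal(anj@detail$ndna$substitutions, 1L)
  expect_false(anj@morphology)
  expect_equal(unname(linesOfEvidence(anj)), c(TRUE, FALSE, FALSE))

  # a lowered nuclear-substitution minimum flips the nDNA line (the strict
  # reading)
  strict <- evaluateLines("Anjouan", "Anjouan", "Mayotte", ev$parts, ev$haps,
                          ev$morph,
                          config = evidenceConfig(minNuclearSubstitutions = 1L),
                          designate = FALSE)
  expect_true(strict@ndna)

  # clade vs clade: independent networks + the fixed loreal character; Rag2
  # is shared across the clade boundary (Mayotte carries the common variant)
  am <- evaluateLines("AM", c("Anjouan", "Mayotte"),
                      c("GrandComoro", "Moheli"), ev$parts, ev$haps,
                      ev$morph)
  expect_true(am@mtdna)
  expect_false(am@ndna)
  expect_true(am@morphology)
  expect_equal(am@designation, "CCS")

  expect_error(evaluateLines("x", "Anjouan", "Mayotte",
                             ev$parts["COI"], ev$haps, ev$morph),
               class = "taxlines_evidence_error")
  expect_error(evaluateLines("x", "Anjouan", "Mayotte", ev$parts,
                             ev$haps["PRLR"], ev$morph,
                             config = evidenceConfig(nuclearMarkers = "Rag2")),
               class = "taxlines_evidence_error")
})

test_that("a shared mitochondrial haplotype defeats the mtDNA line", {
  base <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  aln <- markerAlignment("cytb", c(x1 = base, y1 = base),
                         tinyMeta(c("x1", "y1"), c("X", "Y")))
  hs <- collapseHaplotypes(aln)
  np <- buildNetworks(hs)
  pr <- evaluateLines("X", "X", "Y", list(cytb = np),
                      config = evidenceConfig(nuclearMarkers = character()))
  expect_false(pr@mtdna)
  expect_equal(pr@designation, "DCL")   # haplotype sharing reads as admixture
})

test_that("rank assignment reproduces the hierarchical outcomes", {
  grouping <- c(Anjouan = "AM", Mayotte = "AM",
                GrandComoro = "GM", Moheli = "GM")
  cladeP <- list(
    AM = mkProfile("AM", c("Anjouan", "Mayotte"), c("GrandComoro", "Moheli"),
                   TRUE, FALSE, TRUE),
    GM = mkProfile("GM", c("GrandComoro", "Moheli"), c("Anjouan", "Mayotte"),
                   TRUE, FALSE, TRUE))
  oneLine <- function(cand, sib) mkProfile(cand, cand, sib, TRUE, FALSE,
                                           FALSE)
  candP <- list(Anjouan = oneLine("Anjouan", "Mayotte"),
                Mayotte = oneLine("Mayotte", "Anjouan"),
                GrandComoro = oneLine("GrandComoro", "Moheli"),
                Moheli = oneLine("Moheli", "GrandComoro"))
  ra <- assignRanks(cladeP, candP, grouping)
  expect_length(ra@species, 2L)
  expect_equal(sum(rankTable(ra)$rank == "subspecies"), 4L)

  # no candidate distinct at all: one species, no subspecies
  none <- lapply(cladeP, function(p) mkProfile(p@candidate, p@populations,
                                               p@comparison, FALSE, FALSE,
                                               FALSE))
  noneC <- lapply(candP, function(p) mkProfile(p@candidate, p@populations,
                                               p@comparison, FALSE, FALSE,
                                               FALSE))
  ra0 <- assignRanks(none, noneC, grouping)
  expect_length(ra0@species, 1L)
  expect_equal(sum(rankTable(ra0)$rank == "subspecies"), 0L)

  # strict scenario: a within-clade pair with two lines each elevates
  twoLines <- function(cand, sib) mkProfile(cand, cand, sib, TRUE, TRUE,
                                            FALSE)
  candStrict <- candP
  candStrict$Anjouan <- twoLines("Anjouan", "Mayotte")
  candStrict$Mayotte <- twoLines("Mayotte", "Anjouan")
  raS <- assignRanks(cladeP, candStrict, grouping)
  expect_gte(length(raS@species), 3L)
  expect_equal(rankTable(raS)$rank[rankTable(raS)$candidate == "Anjouan"],
               "species")
})

test_that("turning a line on never lowers a candidate's rank", {
  rankLevel <- function(r) match(r, c("not-distinct", "subspecies", "species"))
  grouping <- c(P1 = "X", P2 = "X", P3 = "Y", P4 = "Y")
  set.seed(83)
  for (rep in 1:20) {
    linesC <- matrix(sample(c(TRUE, FALSE), 12, replace = TRUE), 4)
    linesCl <- matrix(sample(c(TRUE, FALSE), 6, replace = TRUE), 2)
    build <- function(lc, lcl) {
      cladeP <- list(
        X = mkProfile("X", c("P1", "P2"), c("P3", "P4"),
                      lcl[1, 1], lcl[1, 2], lcl[1, 3]),
        Y = mkProfile("Y", c("P3", "P4"), c("P1", "P2"),
                      lcl[2, 1], lcl[2, 2], lcl[2, 3]))
      candP <- lapply(1:4, function(i) {
        sib <- c(P1 = "P2", P2 = "P1", P3 = "P4", P4 = "P3")[[paste0("P", i)]]
        mkProfile(paste0("P", i), paste0("P", i), sib,
                  lc[i, 1], lc[i, 2], lc[i, 3])
      })
      names(candP) <- paste0("P", 1:4)
      assignRanks(cladeP, candP, grouping)
    }
    before <- rankTable(build(linesC, linesCl))
    # flip one random FALSE to TRUE at candidate level
    off <- which(!linesC, arr.ind = TRUE)
    if (!nrow(off)) next
    pick <- off[sample(nrow(off), 1L), , drop = FALSE]
    linesC2 <- linesC; linesC2[pick] <- TRUE
    after <- rankTable(build(linesC2, linesCl))
    cand <- paste0("P", pick[1, 1])
    expect_gte(rankLevel(after$rank[after$candidate == cand]),
               rankLevel(before$rank[before$candidate == cand]))
  }
})

test_that("ranks are deterministic and order-invariant", {
  grouping <- c(Anjouan = "AM", Mayotte = "AM",
                GrandComoro = "GM", Moheli = "GM")
  cladeP <- list(
    AM = mkProfile("AM", c("Anjouan", "Mayotte"), c("GrandComoro", "Moheli"),
                   TRUE, FALSE, TRUE),
    GM = mkProfile("GM", c("GrandComoro", "Moheli"), c("Anjouan", "Mayotte"),
                   TRUE, TRUE, TRUE))
  candP <- list(
    Anjouan = mkProfile("Anjouan", "Anjouan", "Mayotte", TRUE, FALSE, FALSE),
    Mayotte = mkProfile("Mayotte", "Mayotte", "Anjouan", FALSE, FALSE, FALSE),
    GrandComoro = mkProfile("GrandComoro", "GrandComoro", "Moheli", TRUE,
                            TRUE, FALSE),
    Moheli = mkProfile("Moheli", "Moheli", "GrandComoro", TRUE, FALSE,
                       FALSE))
  a <- rankTable(assignRanks(cladeP, candP, grouping))
  b <- rankTable(assignRanks(rev(cladeP), rev(candP),
                             grouping[c(3, 1, 4, 2)]))
  b <- b[match(a$candidate, b$candidate), ]
  expect_equal(a$rank, b$rank)
  expect_equal(a$n_lines, b$n_lines)
})
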