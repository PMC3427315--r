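test_that("morphology CSV round-trips with types and flags", {
  path <- writeDemoMorphCsv()
  mm <- readMorphMatrix(path)
  expect_s4_class(mm, "MorphMatrix")
  expect_equal(nrow(mm@data), 8L)
  expect_equal(unname(mm@types[["SVL"]]), "metric")
  expect_equal(mm@graded, "pattern")
  # bilateral accessor returns (L+R)/2
  avg <- bilateralMeans(mm)
  expect_true("SLAB" %in% names(avg@types))
  expect_equal(avg@data$SLAB,
               (demoMorph()@data$SLAB_L + demoMorph()@data$SLAB_R) / 2)
})

test_that("morphology reader rejects malformed tables", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("specimen,population,sex,SVL",
               "id,population,sex,lengthy",   # unknown tag
               "s1,P1,male,50"), bad)
  expect_error(readMorphMatrix(bad), class = "taxlines_schema_error")

  emptyd <- tempfile(fileext = ".csv")
  writeLines(c("specimen,population,sex,SVL", "id,population,sex,metric"),
             emptyd)
  expect_error(readMorphMatrix(emptyd), class = "taxlines_schema_error")

  nonnum <- tempfile(fileext = ".csv")
  writeLines(c("specimen,population,sex,SVL", "id,population,sex,metric",
               "s1,P1,male,tall", "s2,P2,male,50"), nonnum)
  expect_error(readMorphMatrix(nonnum), class = "taxlines_schema_error")
})

test_that("MANOVA behaves on degenerate and single-character cases", {
  mm <- demoMorph()
  # two identical groups: duplicate the North rows under another label
  dat <- mm@data[mm@data$population == "North", ]
  dat2 <- dat; dat2$population <- "North2"
  dat2$specimen <- paste0(dat2$specimen, "b")
  both <- morphMatrix(rbind(dat, dat2), mm@types, mm@graded, mm@sexLimited)
  res <- morphManova(both, characters = c("SVL", "V"))
  expect_gt(res@wilks, 0.999)
  expect_gt(res@pValue, 0.99)

  # single character: Hotelling reduces exactly to the two-sample t-test
  res1 <- morphManova(mm, characters = "SVL")
  tt <- t.test(SVL ~ population, data = mm@data, var.equal = TRUE)
  pw <- res1@pairwise
  expect_equal(pw$T2[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(pw$p[1], tt$p.value, tolerance = 1e-10)

  # too many characters for the group sizes: untestable, not silent NA
  wide <- mm@data
  wide$extra1 <- rnorm(8); wide$extra2 <- rnorm(8); wide$extra3 <- rnorm(8)
  wide$extra4 <- rnorm(8); wide$extra5 <- rnorm(8); wide$extra6 <- rnorm(8)
  types <- c(mm@types, extra1 = "metric", extra2 = "metric",
             extra3 = "metric", extra4 = "metric", extra5 = "metric",
             extra6 = "metric")
  mmw <- morphMatrix(wide, types, mm@graded, mm@sexLimited)
  resw <- suppressWarnings(
    morphManova(mmw, characters = c("SVL", "V", paste0("extra", 1:6))))
  expect_false(any(resw@pairwise$testable))
})

test_that("MANOVA and Hotelling are invariant to specimen order", {
  set.seed(101)
  mm <- demoMorph()
  perm <- sample(nrow(mm@data))
  shuffled <- morphMatrix(mm@data[perm, ], mm@types, mm@graded,
                          mm@sexLimited)
  a <- morphManova(mm, characters = c("SVL", "V"))
  b <- morphManova(shuffled, characters = c("SVL", "V"))
  expect_equal(a@wilks, b@wilks)
  expect_equal(a@pairwise$p, b@pairwise$p)
})

test_that("CVA yields one axis for two groups and location-invariant loadings", {
  mm <- demoMorph()
  cv <- morphCva(mm, characters = c("SVL", "V"))
  expect_equal(ncol(cv@loadings), 1L)
  expect_equal(length(cv@eigenvalues), 1L)
  shifted <- mm@data; shifted$SVL <- shifted$SVL + 100
  cv2 <- morphCva(morphMatrix(shifted, mm@types, mm@graded, mm@sexLimited),
                  characters = c("SVL", "V"))
  expect_equal(cv@loadings, cv2@loadings, tolerance = 1e-9)
})

test_that("CVA loadings agree with MASS::lda up to scale and sign", {
  skip_if_not_installed("MASS")
  set.seed(17)
  n <- 15
  dat <- data.frame(
    specimen = sprintf("s%02d", 1:(3 * n)),
    population = rep(c("A", "B", "C"), each = n),
    sex = "unknown",
    x = rnorm(3 * n, rep(c(0, 2, 4), each = n)),
    y = rnorm(3 * n, rep(c(0, 1, 0), each = n)),
    z = rnorm(3 * n))
  mm <- morphMatrix(dat, c(x = "metric", y = "metric", z = "metric"))
  cv <- morphCva(mm)
  ld <- MASS::lda(dat[, c("x", "y", "z")], grouping = dat$population)
  for (a in 1:2) {
    corr <- abs(cor(cv@loadings[, a], ld$scaling[, a]))
    expect_gt(corr, 0.999)
  }
  expect_true(all(diff(cv@eigenvalues) <= 1e-9))
})

test_that("fixed diagnostics follow the qualitative/quantitative rules", {
  dat <- data.frame(
    specimen = sprintf("s%02d", 1:12),
    population = rep(c("Anjouan", "Mayotte", "GrandComoro", "Moheli"),
                     each = 3),
    sex = "unknown",
    loreal = rep(c("2+3", "2+3", "2", "2"), each = 3),
    MD = c(rep(19, 6), 19, 17, 19, 19, 19, 17),
    pattern = rep(c("blotched", "spotted", "uniform", "diffuse"), each = 3))
  mm <- morphMatrix(dat, c(loreal = "qualitative", MD = "meristic",
                           pattern = "qualitative"), graded = "pattern")
  rep1 <- fixedDiagnosticCharacters(mm, c("Anjouan", "Mayotte"),
                                    c("GrandComoro", "Moheli"))
  tab <- rep1@table
  expect_equal(tab$status[tab$character == "loreal"], "fixed-qualitative")
  expect_equal(tab$status[tab$character == "MD"], "overlapping")
  expect_false("pattern" %in% tab$character)   # graded excluded by default
  expect_true("pattern" %in% rep1@excluded)

  rep2 <- fixedDiagnosticCharacters(mm, "Anjouan", "GrandComoro",
                                    includeGraded = TRUE)
  expect_equal(rep2@table$status[rep2@table$character == "pattern"],
               "fixed-qualitative")
})

test_that("adding a specimen can break but never create a fixed character", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 6
    dat <- data.frame(
      specimen = sprintf("s%02d", 1:(2 * n + 1)),
      population = c(rep("A", n), rep("B", n), "A"),
      sex = "unknown",
      q = sample(c("u", "v", "w"), 2 * n + 1, replace = TRUE),
      m = sample(15:22, 2 * n + 1, replace = TRUE))
    mm_small <- morphMatrix(dat[1:(2 * n), ],
                            c(q = "qualitative", m = "meristic"))
    mm_big <- morphMatrix(dat, c(q = "qualitative", m = "meristic"))
    fixedOf <- function(mm) {
      t <- fixedDiagnosticCharacters(mm, "A", "B")@table
      t$character[t$status != "overlapping"]
    }
    expect_true(all(fixedOf(mm_big) %in% fixedOf(mm_small)))
  }
})

test_that("Amadon's 75% rule behaves at the extremes and under zero variance", {
  set.seed(41)
  a <- rnorm(20); b <- a
  same <- amadon75(a, b)
  expect_lt(same$fraction_outside, 0.25)
  expect_false(same$passes)

  far <- amadon75(rnorm(20, mean = 10), rnorm(20, sd = 1))
  expect_gt(far$fraction_outside, 0.95)
  expect_true(far$passes)

  degen <- amadon75(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(degen$fraction_outside, 1)
  expect_true(degen$passes)
  expect_error(amadon75(1, c(1, 2)), class = "taxlines_morphology_error")
})

test_that("Amadon pass rates match a Monte-Carlo oracle at staged effect sizes", {
  set.seed(59)
  nrep <- 300L; nA <- 10L; nB <- 10L
  z <- qnorm(0.995)
  for (delta in c(0, 2, 5)) {
    pkg <- logical(nrep); oracle <- logical(nrep)
    for (r in seq_len(nrep)) {
      a <- rnorm(nA, mean = delta); b <- rnorm(nB)
      pkg[r] <- amadon75(a, b)$passes
      # oracle: plain arithmetic, no package code
      lo <- mean(b) - z * sd(b); hi <- mean(b) + z * sd(b)
      oracle[r] <- sum(a < lo) + sum(a > hi) >= ceiling(0.75 * nA)
    }
    expect_lt(abs(mean(pkg) - mean(oracle)), 0.02)
  }
})

test_that("sexes pool cleanly in sex-neutral synthetic morphology", {
  mm <- simulateMorphology(comoroPreset(seed = 3))
  dat <- mm@data
  dat$population <- dat$sex   # compare the sexes instead of the islands
  bySex <- morphMatrix(dat, mm@types, mm@graded, mm@sexLimited)
  res <- morphManova(bySex, characters = c("SVL", "V", "SC"))
  expect_gt(res@pValue, 0.01)
})
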