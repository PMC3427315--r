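#' Construct a MorphMatrix
#'
#' @param data data.frame with columns `specimen`, `population`, `sex` and
#'   one column per character.
#' @param types named character vector giving each character's type
#'   (`"metric"`, `"meristic"` or `"qualitative"`).
#' @param graded characters flagged as graded (clinal; excluded from
#'   diagnosis by default).
#' @param sexLimited named character vector, character name -> sex in which
#'   the character is scored.
#' @return A [MorphMatrix].
#' @export
morphMatrix <- function(data, types, graded = character(),
                        sexLimited = character()) {
  methods::new("MorphMatrix", data = as.data.frame(data), types = types,
               graded = graded, sexLimited = sexLimited)
}

#' Read a typed morphology matrix from CSV
#'
#' The CSV carries two header rows: the first with column names, the second
#' with type tags. The leading columns must be tagged `id`, `population` and
#' `sex`; character columns are tagged `metric`, `meristic` or `qualitative`,
#' optionally extended with `|graded` and/or `|sex-limited:<sex>` flags, e.g.
#' `qualitative|graded`. Bilateral meristic characters are stored as column
#' pairs named `<char>_L` / `<char>_R` and averaged on demand by the analysis
#' functions. Character typing and the exclusion flags are data annotations,
#' not code: whether, say, coloration counts towards diagnosability is
#' decided in the table header.
#'
#' @param csvPath path to the CSV file.
#' @return A [MorphMatrix].
#' @export
readMorphMatrix <- function(csvPath) {
  hdr <- utils::read.csv(csvPath, header = FALSE, nrows = 2L,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(hdr) < 2L)
    txStop("taxlines_schema_error", "missing type header row in ", csvPath)
  nms <- as.character(hdr[1L, ]); tags <- as.character(hdr[2L, ])
  dat <- utils::read.csv(csvPath, header = FALSE, skip = 2L,
                         stringsAsFactors = FALSE, col.names = nms)
  if (nrow(dat) == 0L)
    txStop("taxlines_schema_error", "no data rows in ", csvPath)
  base <- sub("\\|.*$", "", tags)
  known <- c("id", "population", "sex", "metric", "meristic", "qualitative")
  if (any(!base %in% known))
    txStop("taxlines_schema_error", "unknown type tag(s): ",
           paste(unique(tags[!base %in% known]), collapse = ", "))
  for (role in c("id", "population", "sex"))
    if (sum(base == role) != 1L)
      txStop("taxlines_schema_error", "exactly one column must be tagged '",
             role, "'")
  names(dat)[base == "id"] <- "specimen"
  names(dat)[base == "population"] <- "population"
  names(dat)[base == "sex"] <- "sex"
  chars <- nms[!base %in% c("id", "population", "sex")]
  types <- stats::setNames(base[!base %in% c("id", "population", "sex")],
                           chars)
  for (ch in chars[types[chars] %in% c("metric", "meristic")]) {
    v <- dat[[ch]]
    num <- suppressWarnings(as.numeric(ifelse(v %in% c("", "NA"), NA, v)))
    bad <- !is.na(v) & !v %in% c("", "NA") & is.na(num)
    if (any(bad))
      txStop("taxlines_schema_error", "non-numeric value(s) in numeric ",
             "character '", ch, "': ", paste(unique(v[bad]), collapse = ", "))
    dat[[ch]] <- num
  }
  for (ch in chars[types[chars] == "qualitative"])
    dat[[ch]] <- ifelse(dat[[ch]] %in% c("", "NA"), NA_character_,
                        as.character(dat[[ch]]))
  flags <- strsplit(tags, "|", fixed = TRUE)
  graded <- chars[vapply(flags[!base %in% c("id", "population", "sex")],
                         function(f) "graded" %in% f[-1L], NA)]
  sl <- vapply(flags[!base %in% c("id", "population", "sex")], function(f) {
    hit <- grep("^sex-limited:", f[-1L], value = TRUE)
    if (length(hit)) sub("^sex-limited:", "", hit[1L]) else NA_character_
  }, "")
  sexLimited <- stats::setNames(sl[!is.na(sl)], chars[!is.na(sl)])
  morphMatrix(dat, types, graded, sexLimited)
}

#' Write a MorphMatrix to the two-header CSV format
#' @param mm a [MorphMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMorphMatrix <- function(mm, path) {
  dat <- mm@data
  nms <- colnames(dat)
  tags <- character(length(nms))
  tags[nms == "specimen"] <- "id"
  tags[nms == "population"] <- "population"
  tags[nms == "sex"] <- "sex"
  for (ch in names(mm@types)) {
    tg <- mm@types[[ch]]
    if (ch %in% mm@graded) tg <- paste0(tg, "|graded")
    if (ch %in% names(mm@sexLimited))
      tg <- paste0(tg, "|sex-limited:", mm@sexLimited[[ch]])
    tags[nms == ch] <- tg
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste(nms, collapse = ","), paste(tags, collapse = ",")), con)
  utils::write.table(dat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  invisible(path)
}

setMethod("show", "MorphMatrix", function(object) {
  cat("MorphMatrix:", nrow(object@data), "specimens,",
      length(object@types), "characters\n")
  cat("  types:", paste(names(table(object@types)), table(object@types),
                        sep = ":", collapse = ", "), "\n")
  if (length(object@graded))
    cat("  graded:", paste(object@graded, collapse = ", "), "\n")
  if (length(object@sexLimited))
    cat("  sex-limited:", paste(names(object@sexLimited), object@sexLimited,
                                sep = "->", collapse = ", "), "\n")
})

#' Average bilateral characters
#'
#' Replaces every bilateral `*_L`/`*_R` column pair by its mean, named by the
#' base character. Types and flags carry over. Analysis functions apply this
#' automatically.
#'
#' @param mm a [MorphMatrix].
#' @return A [MorphMatrix] with averaged bilateral characters.
#' @export
bilateralMeans <- function(mm) {
  dat <- mm@data; types <- mm@types
  lefts <- grep("_L$", names(types), value = TRUE)
  for (l in lefts) {
    base <- sub("_L$", "", l); r <- paste0(base, "_R")
    if (!r %in% names(types)) next
    dat[[base]] <- rowMeans(cbind(dat[[l]], dat[[r]]), na.rm = FALSE)
    types[base] <- types[[l]]
    dat[[l]] <- NULL; dat[[r]] <- NULL
    types <- types[!names(types) %in% c(l, r)]
  }
  graded <- unique(sub("_[LR]$", "", mm@graded))
  graded <- graded[graded %in% names(types)]
  sl <- mm@sexLimited
  names(sl) <- sub("_[LR]$", "", names(sl))
  sl <- sl[!duplicated(names(sl)) & names(sl) %in% names(types)]
  morphMatrix(dat, types, graded, sl)
}

.numericChars <- function(mm)
  names(mm@types)[mm@types %in% c("metric", "meristic")]

.groupLabels <- function(mm, grouping) {
  g <- mm@data$population
  if (!is.null(grouping)) {
    if (!all(g %in% names(grouping)))
      txStop("taxlines_grouping_error",
             "population(s) missing from grouping: ",
             paste(setdiff(g, names(grouping)), collapse = ", "))
    g <- unname(grouping[g])
  }
  g
}

.hotelling <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  df2 <- n1 + n2 - p - 1
  if (n1 < 2L || n2 < 2L || df2 < 1L)
    return(list(testable = FALSE, T2 = NA_real_, F = NA_real_,
                df1 = p, df2 = df2, p = NA_real_))
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  delta <- colMeans(X1) - colMeans(X2)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv))
    return(list(testable = FALSE, T2 = NA_real_, F = NA_real_,
                df1 = p, df2 = df2, p = NA_real_))
  T2 <- as.numeric(n1 * n2 / (n1 + n2) * t(delta) %*% Sinv %*% delta)
  Fv <- df2 / (p * (n1 + n2 - 2)) * T2
  list(testable = TRUE, T2 = T2, F = Fv, df1 = p, df2 = df2,
       p = stats::pf(Fv, p, df2, lower.tail = FALSE))
}

#' MANOVA across groups with pairwise Hotelling tests
#'
#' Tests equality of multivariate means across populations (or any supplied
#' grouping) with Wilks' lambda and its standard F approximation, then runs a
#' two-group Hotelling T-squared test for every group pair. Only complete
#' cases over the selected characters enter; dropped specimens are recorded.
#' Bilateral `*_L`/`*_R` character pairs are averaged before analysis. Pairs
#' whose group sizes do not support covariance estimation are reported as
#' untestable rather than silently `NA`. With a single character the pairwise
#' Hotelling test reduces exactly to the two-sample t-test (`T2 = t^2`).
#'
#' @param mm a [MorphMatrix].
#' @param characters character names to use; default all metric and meristic
#'   characters (after bilateral averaging).
#' @param grouping optional named vector population -> group label.
#' @return A [ManovaResult].
#' @export
morphManova <- function(mm, characters = NULL, grouping = NULL) {
  mmb <- bilateralMeans(mm)
  if (is.null(characters)) characters <- .numericChars(mmb)
  g <- .groupLabels(mmb, grouping)
  X <- as.matrix(mmb@data[, characters, drop = FALSE])
  keep <- stats::complete.cases(X)
  dropped <- mmb@data$specimen[!keep]
  X <- X[keep, , drop = FALSE]; g <- g[keep]
  if (length(unique(g)) < 2L)
    txStop("taxlines_morphology_error", "need at least two groups")
  # the overall Wilks test needs residual rank >= #characters; report NA
  # (rather than aborting) when the design cannot support it. With a single
  # character Wilks reduces to one-way ANOVA.
  naStats <- function() matrix(NA_real_, 1L, 6L,
                               dimnames = list(NULL,
                                               c("Df", "Wilks", "approx F",
                                                 "num Df", "den Df",
                                                 "Pr(>F)")))
  st <- if (ncol(X) == 1L) {
    a <- stats::anova(stats::lm(X[, 1L] ~ factor(g)))
    lam <- a[2L, "Sum Sq"] / sum(a[, "Sum Sq"])
    matrix(c(a[1L, "Df"], lam, a[1L, "F value"], a[1L, "Df"], a[2L, "Df"],
             a[1L, "Pr(>F)"]), 1L,
           dimnames = list(NULL, c("Df", "Wilks", "approx F", "num Df",
                                   "den Df", "Pr(>F)")))
  } else {
    tryCatch(summary(stats::manova(X ~ factor(g)), test = "Wilks")$stats,
             error = function(e) {
               warning("overall MANOVA not estimable: ",
                       conditionMessage(e))
               naStats()
             })
  }
  gs <- sort(unique(g))
  pw <- do.call(rbind, lapply(utils::combn(gs, 2L, simplify = FALSE),
    function(pr) {
      h <- .hotelling(X[g == pr[1L], , drop = FALSE],
                      X[g == pr[2L], , drop = FALSE])
      data.frame(group1 = pr[1L], group2 = pr[2L], T2 = h$T2, F = h$F,
                 df1 = h$df1, df2 = h$df2, p = h$p, testable = h$testable)
    }))
  rownames(pw) <- NULL
  methods::new("ManovaResult",
               wilks = unname(st[1L, "Wilks"]),
               statistic = unname(st[1L, "approx F"]),
               df = unname(c(st[1L, "num Df"], st[1L, "den Df"])),
               pValue = unname(st[1L, "Pr(>F)"]),
               pairwise = pw, characters = characters,
               nUsed = vapply(split(g, g), length, 1L),
               dropped = as.character(dropped))
}

setMethod("show", "ManovaResult", function(object) {
  cat(sprintf("ManovaResult: Wilks lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              object@wilks, object@df[1L], object@df[2L], object@statistic,
              object@pValue))
  cat("  pairwise Hotelling p:\n")
  print(object@pairwise[, c("group1", "group2", "p", "testable")],
        row.names = FALSE)
  if (length(object@dropped))
    cat("  dropped (incomplete):", paste(object@dropped, collapse = ", "),
        "\n")
})

#' Canonical variates analysis
#'
#' Ordination maximising between-group relative to within-group variation:
#' the generalized eigen-decomposition of the between-group scatter against
#' the pooled within-group covariance. Scores have unit pooled within-group
#' variance per axis; raw canonical coefficients are reported as loadings.
#' Axis signs are indeterminate (each axis is normalised so its largest
#' absolute loading is positive); compare loadings to published values by the
#' rank of their magnitudes only. A singular within-group scatter is
#' ridge-regularised with a warning.
#'
#' @inheritParams morphManova
#' @return A [CvaResult] with `min(#characters, #groups - 1)` axes.
#' @export
morphCva <- function(mm, characters = NULL, grouping = NULL) {
  mmb <- bilateralMeans(mm)
  if (is.null(characters)) characters <- .numericChars(mmb)
  g <- .groupLabels(mmb, grouping)
  X <- as.matrix(mmb@data[, characters, drop = FALSE])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; g <- factor(g[keep])
  ng <- nlevels(g); n <- nrow(X); p <- ncol(X)
  if (ng < 2L)
    txStop("taxlines_morphology_error", "need at least two groups")
  centers <- rowsum(X, g) / as.vector(table(g))
  Xc <- X - centers[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc)
  gm <- colMeans(X)
  B <- crossprod(sweep(centers, 2L, gm) * sqrt(as.vector(table(g))))
  Sw <- W / (n - ng)
  ridge <- 0
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(Sw))
    warning("singular within-group scatter; ridge-regularised (",
            signif(ridge, 3), ")")
    ch <- chol(Sw + ridge * diag(p))
  }
  Ci <- backsolve(ch, diag(p))
  A <- t(Ci) %*% (B / (n - ng)) %*% Ci
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- min(p, ng - 1L)
  load <- Ci %*% e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (a in seq_len(k)) {
    i <- which.max(abs(load[, a]))
    if (load[i, a] < 0) load[, a] <- -load[, a]
  }
  rownames(load) <- characters
  colnames(load) <- paste0("CV", seq_len(k))
  scores <- sweep(X, 2L, gm) %*% load
  rownames(scores) <- mmb@data$specimen[keep]
  methods::new("CvaResult", scores = scores, loadings = load,
               eigenvalues = pmax(e$values[seq_len(k)], 0), grouping = g,
               characters = characters, ridge = ridge)
}

setMethod("show", "CvaResult", function(object) {
  cat("CvaResult:", length(object@eigenvalues), "axes; eigenvalues:",
      paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
  cat("  loadings (axis signs indeterminate):\n")
  print(round(object@loadings, 3))
})

#' Amadon's 75% rule
#'
#' Quantitative subspecies diagnosability: at least 75% of the proposed
#' subspecies' sample must lie outside 99% of the range of the comparison
#' population. In `normal` mode (default) the 99% range of B is its fitted
#' normal central interval `mean(B) +/- 2.576 sd(B)` (stable for the small
#' samples typical of museum series); in `range` mode it is B's observed
#' range. Zero variance in B degenerates the interval to a point.
#'
#' @param valuesA numeric sample of the proposed subspecies (size >= 2).
#' @param valuesB numeric comparison sample (size >= 2).
#' @param mode `"normal"` or `"range"`.
#' @return List with `fraction_outside`, `passes`, and the `interval` used.
#' @export
amadon75 <- function(valuesA, valuesB, mode = c("normal", "range")) {
  mode <- match.arg(mode)
  valuesA <- valuesA[!is.na(valuesA)]; valuesB <- valuesB[!is.na(valuesB)]
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    txStop("taxlines_morphology_error", "both samples must have size >= 2")
  if (mode == "normal") {
    s <- stats::sd(valuesB)
    interval <- mean(valuesB) + c(-1, 1) * stats::qnorm(0.995) * s
  } else {
    interval <- range(valuesB)
  }
  out <- valuesA < interval[1L] | valuesA > interval[2L]
  frac <- mean(out)
  list(fraction_outside = frac, passes = frac >= 0.75, interval = interval)
}

#' Fixed and quantitative diagnostic characters between two groups
#'
#' For every character, compares the observed values of group A and group B:
#' a qualitative character is *fixed* iff the observed state sets are
#' disjoint and both non-empty; a metric/meristic character is
#' *quantitative-diagnosable* iff the observed ranges are disjoint
#' (`quantitative = "range"`, default) or Amadon's 75% rule passes in both
#' directions (`quantitative = "amadon"`). Characters flagged graded or
#' sex-limited are excluded unless `includeGraded = TRUE`. Bilateral pairs
#' are averaged first.
#'
#' @param mm a [MorphMatrix].
#' @param groupA,groupB population labels (one or more each) forming the two
#'   compared groups.
#' @param includeGraded include graded and sex-limited characters?
#' @param quantitative operationalisation of quantitative diagnosability.
#' @return A [DiagnosticReport].
#' @export
fixedDiagnosticCharacters <- function(mm, groupA, groupB,
                                      includeGraded = FALSE,
                                      quantitative = c("range", "amadon")) {
  quantitative <- match.arg(quantitative)
  mmb <- bilateralMeans(mm)
  pop <- mmb@data$population
  if (!any(pop %in% groupA) || !any(pop %in% groupB))
    txStop("taxlines_grouping_error", "both groups must be non-empty")
  excluded <- union(mmb@graded, names(mmb@sexLimited))
  chars <- names(mmb@types)
  use <- if (includeGraded) chars else setdiff(chars, excluded)
  rows <- lapply(use, function(ch) {
    a <- mmb@data[[ch]][pop %in% groupA]
    b <- mmb@data[[ch]][pop %in% groupB]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    ty <- mmb@types[[ch]]
    if (!length(a) || !length(b)) {
      status <- "overlapping"; detail <- "missing in one group"
    } else if (ty == "qualitative") {
      disjoint <- !length(intersect(unique(a), unique(b)))
      status <- if (disjoint) "fixed-qualitative" else "overlapping"
      detail <- paste0("A{", paste(sort(unique(a)), collapse = ","),
                       "} vs B{", paste(sort(unique(b)), collapse = ","), "}")
    } else if (quantitative == "range") {
      disjoint <- max(a) < min(b) || max(b) < min(a)
      status <- if (disjoint) "quantitative-diagnosable" else "overlapping"
      detail <- sprintf("A[%g,%g] vs B[%g,%g]", min(a), max(a), min(b), max(b))
    } else {
      ok <- length(a) >= 2L && length(b) >= 2L &&
        amadon75(a, b)$passes && amadon75(b, a)$passes
      status <- if (ok) "quantitative-diagnosable" else "overlapping"
      detail <- "Amadon 75% rule, both directions"
    }
    data.frame(character = ch, type = ty, status = status, detail = detail)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  methods::new("DiagnosticReport",
               groupA = paste(groupA, collapse = "+"),
               groupB = paste(groupB, collapse = "+"),
               table = tab,
               excluded = if (includeGraded) character() else
                 intersect(excluded, chars))
}

setMethod("show", "DiagnosticReport", function(object) {
  cat("DiagnosticReport:", object@groupA, "vs", object@groupB, "\n")
  print(object@table[, c("character", "type", "status")], row.names = FALSE)
  if (length(object@excluded))
    cat("  excluded (graded/sex-limited):",
        paste(object@excluded, collapse = ", "), "\n")
})

# Any diagnosable character in the report?
hasFixedDiagnostic <- function(report)
  any(report@table$status %in% c("fixed-qualitative",
                                 "quantitative-diagnosable"))
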