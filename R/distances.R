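#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites over comparable sites, with no model
#' correction. Under `pairwise` deletion a site is comparable iff neither
#' sequence is missing there (`N`, IUPAC ambiguity, `?`, and gaps unless
#' `gapAsState = TRUE`); under `complete-against-matrix` both sequences are
#' first restricted to the columns free of missing data in *both* (for a whole
#' alignment, [distanceMatrix()] restricts to columns complete across every
#' sequence).
#'
#' @param a,b aligned sequences (character strings of equal length).
#' @param deletion `"pairwise"` (default) or `"complete-against-matrix"`.
#' @param gapAsState treat `-` as a fifth state?
#' @return Fraction in `[0, 1]`.
#' @examples
#' pDistance("ACGT", "ACGA")   # 0.25
#' pDistance("AC-T", "ACGT")   # 0 over 3 comparable sites
#' @export
pDistance <- function(a, b, deletion = c("pairwise", "complete-against-matrix"),
                      gapAsState = FALSE) {
  deletion <- match.arg(deletion)
  if (nchar(a) != nchar(b))
    txStop("taxlines_alignment_error", "sequences have unequal lengths")
  m <- matrix(unlist(strsplit(toupper(c(a, b)), "", fixed = TRUE)),
              nrow = 2L, byrow = TRUE)
  miss <- missingMask(m, gapAsState = gapAsState)
  cmp <- !(miss[1L, ] | miss[2L, ])
  if (!any(cmp))
    txStop("taxlines_distance_error",
           "no comparable sites between the two sequences")
  mean(m[1L, cmp] != m[2L, cmp])
}

#' Pairwise p-distance matrix for an alignment
#'
#' Applies the uncorrected p-distance to every sample pair.
#'
#' @param aln a [MarkerAlignment].
#' @inheritParams pDistance
#' @return A [DistanceMatrix].
#' @export
distanceMatrix <- function(aln,
                           deletion = c("pairwise", "complete-against-matrix"),
                           gapAsState = FALSE) {
  deletion <- match.arg(deletion)
  m <- alnMatrix(aln)
  miss <- missingMask(m, gapAsState = gapAsState)
  if (deletion == "complete-against-matrix") {
    keep <- !apply(miss, 2L, any)
    m <- m[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cmp <- !(miss[i, ] | miss[j, ])
    if (!any(cmp))
      txStop("taxlines_distance_error", "no comparable sites between '",
             rownames(m)[i], "' and '", rownames(m)[j], "'")
    d[i, j] <- d[j, i] <- mean(m[i, cmp] != m[j, cmp])
  }
  methods::new("DistanceMatrix", samples = rownames(m), d = d,
               marker = aln@marker, deletion = deletion)
}

#' @describeIn distanceMatrix plain matrix of p-distance fractions (for CSV
#'   export via [utils::write.csv()] and interoperability).
#' @param x a `DistanceMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@d)

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix '", object@marker, "': ", length(object@samples),
      " samples (", object@deletion, " deletion)\n", sep = "")
  if (length(object@samples) > 1L) {
    off <- object@d[upper.tri(object@d)]
    cat(sprintf("  p-distance range: %.4f-%.4f\n", min(off), max(off)))
  }
})

.pairStats <- function(values) {
  if (!length(values))
    c(n_pairs = 0, min = NA_real_, mean = NA_real_, max = NA_real_)
  else
    c(n_pairs = length(values), min = min(values), mean = mean(values),
      max = max(values))
}

#' Within- and between-group p-distance summaries
#'
#' Summarises a [DistanceMatrix] per group and per unordered group pair,
#' in percent (rounded to one decimal in the table; raw fractions are used
#' internally by all downstream computations). Groups default to the
#' populations of the metadata; supplying `grouping` (population -> clade)
#' summarises clade vs clade instead, pooling all cross-clade sample pairs.
#' Within-group records for singleton groups are reported with `n_pairs = 0`
#' and `NA` statistics (absent, not zero).
#'
#' @param dm a [DistanceMatrix].
#' @param metadata data.frame (or DataFrame) with `sample_id` and
#'   `population`.
#' @param grouping optional named character vector mapping populations to
#'   clade labels.
#' @param x a `DistanceSummary` (accessor).
#' @return A [DistanceSummary].
#' @export
groupDistanceSummary <- function(dm, metadata, grouping = NULL) {
  md <- as.data.frame(metadata)
  grp <- md$population[match(dm@samples, md$sample_id)]
  if (anyNA(grp))
    txStop("taxlines_metadata_error", "sample(s) without a population: ",
           paste(dm@samples[is.na(grp)], collapse = ", "))
  level <- "population"
  if (!is.null(grouping)) {
    if (!all(grp %in% names(grouping)))
      txStop("taxlines_metadata_error", "population(s) missing from grouping: ",
             paste(setdiff(grp, names(grouping)), collapse = ", "))
    grp <- unname(grouping[grp])
    level <- "clade"
  }
  gs <- sort(unique(grp))
  rows <- list()
  for (g in gs) {
    idx <- which(grp == g)
    vals <- if (length(idx) > 1L) dm@d[idx, idx][upper.tri(diag(length(idx)))]
            else numeric()
    rows[[length(rows) + 1L]] <-
      data.frame(scope = "within", group1 = g, group2 = g,
                 t(.pairStats(100 * vals)))
  }
  if (length(gs) > 1L) {
    for (i in seq_len(length(gs) - 1L)) for (j in seq(i + 1L, length(gs))) {
      vals <- as.vector(dm@d[grp == gs[i], grp == gs[j], drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(scope = "between", group1 = gs[i], group2 = gs[j],
                   t(.pairStats(100 * vals)))
    }
  }
  tab <- do.call(rbind, rows)
  tab$min <- fmtPct(tab$min); tab$mean <- fmtPct(tab$mean)
  tab$max <- fmtPct(tab$max)
  rownames(tab) <- NULL
  methods::new("DistanceSummary", marker = dm@marker, table = tab,
               level = level)
}

#' @rdname groupDistanceSummary
#' @export
setMethod("summaryTable", "DistanceSummary", function(x) x@table)

setMethod("show", "DistanceSummary", function(object) {
  cat("DistanceSummary '", object@marker, "' (", object@level,
      " level, percent)\n", sep = "")
  print(object@table, row.names = FALSE)
})

#' Compare between-group divergences with a barcoding threshold
#'
#' For each requested between-group record of a [DistanceSummary], compares
#' the maximum p-distance (percent) with a divergence threshold; the minimum
#' is reported alongside. The comparison is inclusive at the boundary: a
#' maximum exactly equal to the threshold meets it.
#'
#' @param summary a [DistanceSummary].
#' @param thresholdPercent threshold in percent (e.g. 8.3, the COI species
#'   threshold estimated for lamprophiid snakes).
#' @param pairs optional two-column matrix/data.frame of group pairs to
#'   restrict to; default all between-group records.
#' @return A [ThresholdReport].
#' @export
thresholdComparison <- function(summary, thresholdPercent, pairs = NULL) {
  tab <- summary@table[summary@table$scope == "between", , drop = FALSE]
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    want <- paste(pmin(pairs[[1]], pairs[[2]]), pmax(pairs[[1]], pairs[[2]]))
    have <- paste(pmin(tab$group1, tab$group2), pmax(tab$group1, tab$group2))
    if (!all(want %in% have))
      txStop("taxlines_summary_error", "requested pair(s) absent from summary")
    tab <- tab[have %in% want, , drop = FALSE]
  }
  out <- data.frame(group1 = tab$group1, group2 = tab$group2,
                    min = tab$min, max = tab$max,
                    relation = ifelse(tab$max >= thresholdPercent,
                                      "meets-or-exceeds", "below"))
  rownames(out) <- NULL
  methods::new("ThresholdReport", threshold = thresholdPercent, table = out)
}

setMethod("show", "ThresholdReport", function(object) {
  cat("ThresholdReport: threshold =", object@threshold, "%\n")
  print(object@table, row.names = FALSE)
})

#' UPGMA guide grouping of populations
#'
#' Average-linkage (UPGMA) agglomeration of populations on their mean
#' between-population p-distances, cut at `k` groups. Used as the guide clade
#' grouping when no user-supplied tree or grouping is available. The
#' agglomeration is deterministic: when two candidate merges are equidistant,
#' the pair whose (lexicographically sorted) leading members compare lowest is
#' merged first.
#'
#' @param dm a [DistanceMatrix].
#' @param metadata data.frame with `sample_id` and `population`.
#' @param k target number of groups.
#' @return Named character vector: population -> clade label (`"C1"`,
#'   `"C2"`, ... ordered by each clade's lexicographically first member).
#' @export
upgmaGrouping <- function(dm, metadata, k) {
  P <- .popMeanMatrix(dm, metadata)
  .upgmaCut(P, k)
}

# mean between-population distance matrix
.popMeanMatrix <- function(dm, metadata) {
  md <- as.data.frame(metadata)
  grp <- md$population[match(dm@samples, md$sample_id)]
  pops <- sort(unique(grp))
  P <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops))
    if (i != j)
      P[i, j] <- mean(dm@d[grp == pops[i], grp == pops[j], drop = FALSE])
  P
}

.upgmaCut <- function(P, k) {
  pops <- rownames(P)
  if (k > length(pops))
    txStop("taxlines_grouping_error", "k = ", k, " exceeds the ",
           length(pops), " populations")
  clusters <- as.list(pops)
  D <- P
  while (length(clusters) > k) {
    best <- NULL; bestD <- Inf
    nc <- length(clusters)
    for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
      dd <- D[i, j]
      if (dd < bestD - 1e-15) { bestD <- dd; best <- c(i, j) }
      else if (abs(dd - bestD) <= 1e-15) {
        # lexicographic tie-break on the leading members
        cand <- c(clusters[[i]][1L], clusters[[j]][1L])
        cur <- c(clusters[[best[1L]]][1L], clusters[[best[2L]]][1L])
        if (cand[1L] < cur[1L] ||
            (cand[1L] == cur[1L] && cand[2L] < cur[2L])) best <- c(i, j)
      }
    }
    i <- best[1L]; j <- best[2L]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    # UPGMA: average over all member population pairs
    keep <- setdiff(seq_len(nc), c(i, j))
    newD <- vapply(keep, function(kk)
      mean(P[merged, clusters[[kk]], drop = FALSE]), 0)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD), c(newD, 0))
    clusters <- c(clusters[keep], list(merged))
    ord <- order(vapply(clusters, `[`, "", 1L))
    clusters <- clusters[ord]
    D <- D[ord, ord, drop = FALSE]
  }
  clusters <- clusters[order(vapply(clusters, `[`, "", 1L))]
  out <- character()
  for (i in seq_along(clusters))
    out[clusters[[i]]] <- paste0("C", i)
  out
}

#' Guide grouping from pooled multi-marker distances
#'
#' Averages the mean between-population p-distance matrices of several
#' markers (weighted, by default equally; pass alignment lengths to mimic
#' concatenation) and cuts the UPGMA agglomeration of the pooled matrix at
#' `k` groups. Pooling markers stabilises the guide grouping the way a
#' multilocus tree does, which is why the pipeline derives its default guide
#' clades from all mitochondrial markers rather than one.
#'
#' @param dms named list of [DistanceMatrix] objects.
#' @param metadataList list of metadata data.frames parallel to `dms` (or a
#'   single data.frame used for all).
#' @param k target number of groups.
#' @param weights numeric marker weights; default equal.
#' @return Named character vector population -> clade label.
#' @export
guideGrouping <- function(dms, metadataList, k = 2L, weights = NULL) {
  if (is.data.frame(metadataList) || methods::is(metadataList, "DataFrame"))
    metadataList <- rep(list(as.data.frame(metadataList)), length(dms))
  if (is.null(weights)) weights <- rep(1, length(dms))
  Ps <- mapply(.popMeanMatrix, dms, metadataList, SIMPLIFY = FALSE)
  pops <- rownames(Ps[[1L]])
  for (P in Ps)
    if (!identical(rownames(P), pops))
      txStop("taxlines_grouping_error",
             "markers cover different population sets")
  pooled <- Reduce(`+`, mapply(`*`, Ps, weights / sum(weights),
                               SIMPLIFY = FALSE))
  .upgmaCut(pooled, k)
}
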