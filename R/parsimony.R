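#' Parsimony probability of a j-step connection
#'
#' Statistical parsimony (Templeton, Crandall & Sing 1992) connects two
#' haplotypes only while the probability that the connection is free of
#' superimposed (homoplastic) change remains high. This function returns that
#' probability for a connection of `j` mutational steps across a marker of
#' `L` sites under a uniform-hits substitution model: the `j` events hit sites
#' independently and uniformly, and the connection is parsimonious when all
#' of them strike distinct sites, giving
#' `P_j = prod_{i=0}^{j-1} (1 - i/L)`.
#'
#' The estimator is strictly decreasing in `j` and non-decreasing in `L`, and
#' is deliberately transparent so the resulting limit can be audited from the
#' probability table of a [ConnectionLimit]. It is somewhat more conservative
#' (by one to a few steps at typical mitochondrial fragment lengths) than the
#' historical TCS program, whose internal estimator variant was never fully
#' documented; reports therefore always carry the table alongside the limit.
#'
#' @param j number of mutational steps (0 allowed; `P_0 = 1` by convention).
#'   May be a vector.
#' @param L number of sites.
#' @return Probability in `(0, 1]`.
#' @examples
#' parsimonyProbability(0:5, L = 613)
#' @export
parsimonyProbability <- function(j, L) {
  if (L < 1L) txStop("taxlines_parsimony_error", "'L' must be >= 1")
  if (any(j < 0L) || any(j > L))
    txStop("taxlines_parsimony_error",
           "'j' must lie in [0, L]; got j = ", paste(j[j < 0L | j > L],
                                                     collapse = ", "),
           " with L = ", L)
  vapply(j, function(jj) {
    if (jj == 0L) return(1)
    prod(1 - (seq_len(jj) - 1L) / L)
  }, 0)
}

#' Connection limit at a given confidence level
#'
#' Largest number of mutational steps `jMax` whose parsimony probability is at
#' least `1 - alpha` (the classical "95% connection limit" is
#' `alpha = 0.05`), with the probability table populated up to and including
#' the first failing step.
#'
#' @param L number of sites.
#' @param alpha significance level, default 0.05.
#' @param marker optional marker label carried along for reporting.
#' @return A [ConnectionLimit].
#' @examples
#' connectionLimit(613)
#' @export
connectionLimit <- function(L, alpha = 0.05, marker = NA_character_) {
  if (L < 1L) txStop("taxlines_parsimony_error", "'L' must be >= 1")
  probs <- numeric(); p <- 1; j <- 0L
  while (p >= 1 - alpha && j < L) {
    j <- j + 1L
    p <- p * (1 - (j - 1L) / L)   # running product = parsimonyProbability(j, L)
    probs[j] <- p
  }
  jMax <- if (length(probs)) sum(probs >= 1 - alpha) else 0L
  methods::new("ConnectionLimit", marker = as.character(marker),
               L = as.integer(L), alpha = alpha, jMax = as.integer(jMax),
               probabilities = probs)
}

setMethod("show", "ConnectionLimit", function(object) {
  cat("ConnectionLimit",
      if (!is.na(object@marker)) paste0(" '", object@marker, "'"), ": L = ",
      object@L, " sites, ", 100 * (1 - object@alpha), "% limit -> jMax = ",
      object@jMax, " steps\n", sep = "")
  cat("  P_j table (audit):",
      paste(sprintf("P_%d=%.4f", seq_along(object@probabilities),
                    object@probabilities), collapse = " "), "\n")
})

# Hamming step distances between haplotype representatives over comparable
# sites (missing excluded, consistently with the collapse policy).
stepDistances <- function(hs) {
  n <- length(hs@sequences)
  m <- matrix(unlist(strsplit(hs@sequences, "", fixed = TRUE),
                     use.names = FALSE), nrow = n, byrow = TRUE)
  miss <- missingMask(m, gapAsState = hs@gapAsState)
  d <- matrix(0L, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cmp <- !(miss[i, ] | miss[j, ])
    d[i, j] <- d[j, i] <- sum(m[i, cmp] != m[j, cmp])
  }
  d
}

#' Partition haplotypes into independent parsimony networks
#'
#' Builds the graph joining every haplotype pair whose mutational step
#' distance (Hamming distance over comparable sites) is at most the
#' connection limit `jMax`, and returns its connected components: haplotype
#' clusters that cannot be joined within the limit form independent networks.
#' Intra-component edges are annotated with their step counts; `steps - 1` is
#' the number of interlying unsampled intermediate haplotypes. Network
#' topology beyond component membership (which intermediate path) is not
#' resolved, since only independence feeds the evidence engine.
#'
#' @param hs a [HaplotypeSet].
#' @param limit a [ConnectionLimit]; default `connectionLimit(L)` with `L`
#'   taken from the haplotype sequences.
#' @param x a `NetworkPartition` (accessors).
#' @return A [NetworkPartition].
#' @export
buildNetworks <- function(hs, limit = NULL) {
  if (is.null(limit))
    limit <- connectionLimit(nchar(hs@sequences[1L]), marker = hs@marker)
  d <- stepDistances(hs)
  n <- nrow(d)
  adj <- d <= limit@jMax
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  components <- split(seq_len(n), membership)
  names(components) <- NULL
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(hap1 = edges[, 1L], hap2 = edges[, 2L],
                      steps = d[edges],
                      intermediates = pmax(d[edges] - 1L, 0L))
  methods::new("NetworkPartition", marker = hs@marker,
               membership = membership, components = components,
               edges = edges, limit = limit, haplotypes = hs)
}

#' @rdname buildNetworks
#' @export
setMethod("nComponents", "NetworkPartition",
          function(x) length(x@components))

#' @rdname buildNetworks
#' @export
setMethod("componentPopulations", "NetworkPartition", function(x) {
  lapply(x@components, function(idx) {
    ids <- unlist(x@haplotypes@members[idx], use.names = FALSE)
    sort(unique(popOf(x@haplotypes@metadata, ids)))
  })
})

setMethod("show", "NetworkPartition", function(object) {
  cat("NetworkPartition '", object@marker, "': ", nComponents(object),
      " independent network(s) at jMax = ", object@limit@jMax, " steps\n",
      sep = "")
  pops <- componentPopulations(object)
  for (i in seq_along(pops))
    cat("  component ", i, ": ", length(object@components[[i]]),
        " haplotype(s); populations: ", paste(pops[[i]], collapse = ", "),
        "\n", sep = "")
})

#' Export a network partition
#'
#' Writes the intra-component edges (with step annotations) as an edge-list
#' CSV, or the whole partition as GML-style text (nodes carry haplotype
#' index, component and member count; edges carry step counts).
#'
#' @param np a [NetworkPartition].
#' @param path output file.
#' @param format `"edgelist"` (CSV) or `"gml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(np, path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.csv(np@edges, path, row.names = FALSE)
  } else {
    lines <- c("graph [", "  directed 0",
               sprintf("  comment \"marker %s, jMax %d\"", np@marker,
                       np@limit@jMax))
    for (i in seq_along(np@membership))
      lines <- c(lines, "  node [", sprintf("    id %d", i),
                 sprintf("    component %d", np@membership[i]),
                 sprintf("    members %d", length(np@haplotypes@members[[i]])),
                 "  ]")
    for (r in seq_len(nrow(np@edges)))
      lines <- c(lines, "  edge [",
                 sprintf("    source %d", np@edges$hap1[r]),
                 sprintf("    target %d", np@edges$hap2[r]),
                 sprintf("    steps %d", np@edges$steps[r]), "  ]")
    writeLines(c(lines, "]"), path)
  }
  invisible(path)
}

#' Is a candidate represented by independent parsimony networks?
#'
#' `TRUE` iff every haplotype carried by the candidate's samples lies in
#' components containing no other population's samples. The criterion is
#' exclusivity, not connectivity: a candidate split across two components is
#' still independent as long as both components are exclusively its own.
#'
#' @param np a [NetworkPartition].
#' @param candidatePopulations one or more population labels forming the
#'   candidate taxon.
#' @return Logical.
#' @export
isIndependentNetwork <- function(np, candidatePopulations) {
  pops <- componentPopulations(np)
  all_pops <- unique(unlist(pops))
  absent <- setdiff(candidatePopulations, all_pops)
  if (length(absent))
    txStop("taxlines_population_error", "population(s) not in the data: ",
           paste(absent, collapse = ", "))
  carrying <- vapply(pops, function(p) any(candidatePopulations %in% p), NA)
  all(vapply(pops[carrying],
             function(p) all(p %in% candidatePopulations), NA))
}
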