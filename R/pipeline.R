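.stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "taxlines_stage_error")) stop(e)
    txStop("taxlines_stage_error", "[", label, "] ", conditionMessage(e))
  })
}

#' Run the integrated delimitation pipeline
#'
#' Executes the full analysis: read or simulate the per-marker alignments and
#' the morphology matrix; collapse haplotypes; compute p-distance matrices
#' and population- and clade-level summaries; derive the guide clade grouping
#' (UPGMA at `k = 2` on the configured mtDNA marker unless supplied); build
#' statistical-parsimony network partitions for every marker; compare the
#' barcode marker's clade divergence with the configured threshold; run
#' MANOVA/CVA and clade-level diagnostics; evaluate the three lines of
#' evidence at clade and candidate level; and assign species/subspecies
#' ranks. Optionally writes a machine-readable JSON report and a
#' human-readable markdown summary. Any stage failure aborts with a
#' stage-tagged error message.
#'
#' @param scenario a [ScenarioConfig] for a simulated run, or `NULL` to read
#'   files.
#' @param alignmentFiles named list (marker -> FASTA path) for a file-based
#'   run.
#' @param metadataFile CSV path with `sample_id,population,voucher,sex`.
#' @param morphologyFile two-header morphology CSV path (optional).
#' @param config see [evidenceConfig()].
#' @param grouping optional named vector population -> clade; default derived
#'   by [upgmaGrouping()] with `k = 2`.
#' @param seed overrides the scenario's base seed.
#' @param outDir if non-`NULL`, `report.json` and `report.md` are written
#'   there.
#' @return A [RunReport].
#' @examples
#' \donttest{
#' rep <- runPipeline(comoroPreset(seed = 7))
#' rep@ranks
#' }
#' @export
runPipeline <- function(scenario = NULL, alignmentFiles = NULL,
                        metadataFile = NULL, morphologyFile = NULL,
                        config = evidenceConfig(), grouping = NULL,
                        seed = NULL, outDir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  alignments <- .stage("alignments", {
    if (!is.null(scenario)) {
      if (!is.null(seed)) scenario@seed <- as.integer(seed)
      al <- lapply(stats::setNames(names(scenario@markers),
                                   names(scenario@markers)),
                   function(m) simulateSequences(scenario, m))
      note("[alignments] simulated ", length(al), " marker(s), seed ",
           scenario@seed)
      al
    } else {
      if (is.null(alignmentFiles) || is.null(metadataFile))
        txStop("taxlines_input_error",
               "either a scenario or alignmentFiles + metadataFile required")
      al <- lapply(stats::setNames(names(alignmentFiles),
                                   names(alignmentFiles)),
                   function(m) readAlignment(alignmentFiles[[m]],
                                             metadataFile, m))
      note("[alignments] read ", length(al), " marker(s)")
      al
    }
  })

  morph <- .stage("morphology-input", {
    if (!is.null(scenario)) simulateMorphology(scenario)
    else if (!is.null(morphologyFile)) readMorphMatrix(morphologyFile)
    else NULL
  })

  haps <- .stage("haplotypes", lapply(alignments, collapseHaplotypes))

  dms <- .stage("distances", lapply(alignments, distanceMatrix))
  md <- as.data.frame(alignments[[1L]]@metadata)

  grouping <- .stage("grouping", {
    if (is.null(grouping)) {
      gm <- config$groupingMarkers
      if (is.null(gm)) gm <- setdiff(names(dms), config$nuclearMarkers)
      gm <- intersect(gm, names(dms))
      if (!length(gm)) gm <- config$mtdnaMarker
      if (!all(gm %in% names(dms)))
        txStop("taxlines_input_error", "grouping marker(s) absent: ",
               paste(setdiff(gm, names(dms)), collapse = ", "))
      g <- guideGrouping(dms[gm],
                         lapply(alignments[gm], function(a)
                           as.data.frame(a@metadata)),
                         k = 2L,
                         weights = vapply(alignments[gm], alignmentLength,
                                          1L))
      note("[grouping] UPGMA guide grouping (k=2) pooled over ",
           paste(gm, collapse = "+"), ": ",
           paste(names(g), g, sep = "->", collapse = ", "))
      g
    } else grouping
  })

  summaries <- .stage("summaries", {
    s <- lapply(names(dms), function(m) groupDistanceSummary(
      dms[[m]], as.data.frame(alignments[[m]]@metadata)))
    names(s) <- names(dms)
    cl <- lapply(names(dms), function(m) groupDistanceSummary(
      dms[[m]], as.data.frame(alignments[[m]]@metadata), grouping = grouping))
    names(cl) <- names(dms)
    c(s, list(clade = cl))
  })

  thresholds <- .stage("threshold", {
    bm <- config$barcodeMarker
    if (bm %in% names(summaries$clade))
      list(thresholdComparison(summaries$clade[[bm]],
                               config$thresholdPercent))
    else list()
  })

  partitions <- .stage("networks", {
    p <- lapply(haps, buildNetworks)
    for (m in names(p))
      note("[networks] ", m, ": ", nComponents(p[[m]]),
           " component(s) at jMax=", p[[m]]@limit@jMax)
    p
  })

  morphres <- .stage("morphology", {
    if (is.null(morph)) list()
    else {
      clades <- sort(unique(unname(grouping)))
      diag <- list()
      if (length(clades) == 2L) {
        a <- names(grouping)[grouping == clades[1L]]
        b <- names(grouping)[grouping == clades[2L]]
        diag[[paste(clades, collapse = "-vs-")]] <-
          fixedDiagnosticCharacters(morph, a, b,
                                    includeGraded = !config$excludeGraded)
      }
      list(manova = morphManova(morph), cva = morphCva(morph),
           diagnostics = diag)
    }
  })

  profiles <- .stage("evidence", {
    clades <- sort(unique(unname(grouping)))
    cp <- lapply(stats::setNames(clades, clades), function(cl) {
      own <- names(grouping)[grouping == cl]
      evaluateLines(cl, own, setdiff(names(grouping), own), partitions,
                    haps, morph, config)
    })
    cand <- list()
    for (cand_pop in names(grouping)) {
      sibs <- setdiff(names(grouping)[grouping == grouping[[cand_pop]]],
                      cand_pop)
      if (length(sibs))
        cand[[cand_pop]] <- evaluateLines(cand_pop, cand_pop, sibs,
                                          partitions, haps, morph, config,
                                          designate = FALSE)
    }
    for (p in c(cp, cand))
      note("[evidence] ", p@candidate, ": mtDNA=", p@mtdna, " nDNA=",
           p@ndna, " morphology=", p@morphology)
    list(clade = cp, candidate = cand)
  })

  ranks <- .stage("ranks",
                  assignRanks(profiles$clade, profiles$candidate, grouping))
  note("[ranks] ", length(ranks@species), " species; ",
       sum(ranks@table$rank == "subspecies"), " subspecies")

  report <- methods::new("RunReport", summaries = summaries,
                         thresholds = thresholds, partitions = partitions,
                         haplotypes = haps,
                         morphology = morphres, profiles = profiles,
                         ranks = ranks,
                         config = c(config,
                                    list(grouping = as.list(grouping),
                                         seed = if (!is.null(scenario))
                                           scenario@seed else NA)),
                         log = log)
  if (!is.null(outDir)) .stage("report", writeReport(report, outDir))
  report
}

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  cat("  markers:", paste(names(object@partitions), collapse = ", "), "\n")
  show(object@ranks)
})

.profileJson <- function(p) {
  li <- linesOfEvidence(p)
  out <- list(candidate = p@candidate,
              populations = p@populations, comparison = p@comparison,
              mtdna = li[["mtdna"]], ndna = li[["ndna"]],
              morphology = li[["morphology"]],
              n_lines = sum(li, na.rm = TRUE))
  if (!is.na(p@designation)) out$designation <- p@designation
  if (!is.null(p@detail$ndna))
    out$nuclear_substitutions <- p@detail$ndna$substitutions
  out
}

#' Write a RunReport to disk
#'
#' `report.json` is a machine-readable dump (no timestamps, so identical
#' configurations and seeds produce byte-identical files); `report.md` is a
#' human-readable summary. Logs go to the markdown file only.
#'
#' @param report a [RunReport].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    config = report@config,
    summaries = lapply(report@summaries[setdiff(names(report@summaries),
                                                "clade")],
                       function(s) s@table),
    clade_summaries = lapply(report@summaries$clade, function(s) s@table),
    thresholds = lapply(report@thresholds, function(t)
      list(threshold = t@threshold, table = t@table)),
    networks = lapply(report@partitions, function(p)
      list(jMax = p@limit@jMax, alpha = p@limit@alpha, L = p@limit@L,
           probabilities = p@limit@probabilities,
           n_components = nComponents(p),
           component_populations = componentPopulations(p))),
    morphology = if (length(report@morphology)) list(
      manova = list(wilks = report@morphology$manova@wilks,
                    p = report@morphology$manova@pValue,
                    pairwise = report@morphology$manova@pairwise),
      cva = list(eigenvalues = report@morphology$cva@eigenvalues,
                 loadings = as.data.frame(report@morphology$cva@loadings)),
      diagnostics = lapply(report@morphology$diagnostics,
                           function(d) d@table)) else NULL,
    profiles = list(
      clade = lapply(report@profiles$clade, .profileJson),
      candidate = lapply(report@profiles$candidate, .profileJson)),
    ranks = report@ranks@table,
    species = report@ranks@species)
  jsonlite::write_json(js, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  md <- c("# Integrative delimitation report", "",
          "## Ranks", "",
          sprintf("- %d species, %d subspecies", length(report@ranks@species),
                  sum(report@ranks@table$rank == "subspecies")),
          utils::capture.output(print(report@ranks@table, row.names = FALSE)),
          "", "## Lines of evidence (clades)", "",
          unlist(lapply(report@profiles$clade, function(p)
            utils::capture.output(show(p)))),
          "", "## Networks", "",
          unlist(lapply(names(report@partitions), function(m)
            sprintf("- %s: %d component(s), jMax = %d (see probability table in JSON)",
                    m, nComponents(report@partitions[[m]]),
                    report@partitions[[m]]@limit@jMax))),
          "", "## Log", "", report@log)
  writeLines(md, file.path(outDir, "report.md"))
  invisible(outDir)
}
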