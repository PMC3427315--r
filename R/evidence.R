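#' Evidence-engine configuration
#'
#' Defaults encode the judgments of the lines-of-evidence workflow: the mtDNA
#' line is read from the cyt b network partition, the nDNA line from Rag2
#' haplotype exclusivity, and at least `minNuclearSubstitutions = 2`
#' distinguishing nuclear substitutions are required before haplotype
#' exclusivity counts as a line of evidence (a single substitution per marker
#' is treated as too slight to be distinctive). Graded (and sex-limited)
#' characters are excluded from the morphology line by default. Each knob is
#' echoed into the rank rationale strings so a report shows which judgment
#' produced which rank.
#'
#' @param mtdnaMarker marker whose network partition supplies the mtDNA line.
#' @param nuclearMarkers marker(s) whose haplotype sets supply the nDNA line.
#' @param minNuclearSubstitutions minimum total distinguishing substitutions.
#' @param excludeGraded exclude graded/sex-limited characters from the
#'   morphology line?
#' @param morphologyScope `"clade"`: a candidate's standalone morphology line
#'   is judged against the populations outside its clade; `"sister"`: against
#'   its within-clade sibling(s).
#' @param thresholdPercent barcoding threshold (percent) used in reports.
#' @param barcodeMarker marker compared against the threshold.
#' @param groupingMarkers markers pooled (length-weighted) into the default
#'   guide grouping; `NULL` pools every marker not listed in
#'   `nuclearMarkers`. A multilocus pool stands in for the guide tree.
#' @return Named list of settings.
#' @export
evidenceConfig <- function(mtdnaMarker = "cytb", nuclearMarkers = "Rag2",
                           minNuclearSubstitutions = 2L,
                           excludeGraded = TRUE,
                           morphologyScope = c("clade", "sister"),
                           thresholdPercent = 8.3, barcodeMarker = "COI",
                           groupingMarkers = c("cytb", "COI", "ND4", "16S")) {
  list(mtdnaMarker = mtdnaMarker, nuclearMarkers = nuclearMarkers,
       minNuclearSubstitutions = as.integer(minNuclearSubstitutions),
       excludeGraded = excludeGraded,
       morphologyScope = match.arg(morphologyScope),
       thresholdPercent = thresholdPercent, barcodeMarker = barcodeMarker,
       groupingMarkers = groupingMarkers)
}

#' Designate a candidate taxon (UCS / CCS / DCL)
#'
#' Candidate designation: a lineage distinguishable only by molecular
#' characters is an Unconfirmed Candidate Species (UCS); molecular
#' distinction plus a taxonomically relevant character, or sympatric
#' occurrence without admixture, confirms it (CCS); indications of admixture,
#' or explicitly slight expression of the relevant differences, make it a
#' Deep Conspecific Lineage (DCL).
#'
#' @param molecularDistinct detectable genetic differentiation?
#' @param relevantCharacter distinctiveness in a character of taxonomic value?
#' @param sympatricNoAdmixture sympatric occurrence without admixture? Use
#'   `NA` when sympatry does not apply (allopatric/insular candidates).
#' @param admixture indications of admixture with other lineages?
#' @param explicitlySlight are the relevant differences explicitly judged too
#'   slight?
#' @return `"UCS"`, `"CCS"` or `"DCL"` (or `NA` if not molecularly distinct).
#' @export
designateCandidate <- function(molecularDistinct, relevantCharacter,
                               sympatricNoAdmixture = NA, admixture = FALSE,
                               explicitlySlight = FALSE) {
  if (isTRUE(admixture) && isTRUE(sympatricNoAdmixture))
    txStop("taxlines_evidence_error",
           "contradictory flags: admixture and sympatry-without-admixture")
  if (isTRUE(admixture)) return("DCL")
  if (!isTRUE(molecularDistinct)) return(NA_character_)
  if (isTRUE(relevantCharacter) || isTRUE(sympatricNoAdmixture)) return("CCS")
  if (isTRUE(explicitlySlight)) return("DCL")
  "UCS"
}

# Nuclear exclusivity detail for candidate populations vs comparison
# populations on one haplotype set: is any haplotype shared, and how many
# substitutions separate the closest candidate/non-candidate haplotypes?
.nuclearDetail <- function(hs, candPops, otherPops) {
  popsByHap <- lapply(hs@members, function(ids)
    unique(popOf(hs@metadata, ids)))
  inC <- vapply(popsByHap, function(p) any(p %in% candPops), NA)
  inO <- vapply(popsByHap, function(p) any(p %in% otherPops), NA)
  shared <- any(inC & inO)
  subs <- if (shared) 0L else {
    d <- stepDistances(hs)
    if (!any(inC) || !any(inO)) NA_integer_
    else min(d[inC, inO, drop = FALSE])
  }
  list(shared = shared, substitutions = subs)
}

#' Evaluate the three lines of evidence for a candidate
#'
#' Computes, for a candidate taxon (one or more populations) against a
#' comparison set of populations:
#' \describe{
#'   \item{mtDNA line}{representation by independent parsimony network(s) of
#'     the configured mitochondrial marker ([isIndependentNetwork()], judged
#'     against the comparison populations only).}
#'   \item{nDNA line}{no haplotype of the configured nuclear marker(s) shared
#'     with the comparison set, *and* a total of at least
#'     `minNuclearSubstitutions` distinguishing substitutions (summed over
#'     the nuclear markers' closest candidate-vs-comparison haplotype
#'     pairs).}
#'   \item{morphology line}{at least one fixed (or
#'     quantitative-diagnosable) character against the comparison set,
#'     graded/sex-limited characters excluded unless configured otherwise.}
#' }
#' A line is `NA` when the corresponding data are not supplied.
#'
#' @param candidate candidate label.
#' @param candidatePopulations populations forming the candidate.
#' @param comparisonPopulations populations compared against.
#' @param partitions named list of [NetworkPartition] per marker; must
#'   contain `config$mtdnaMarker`.
#' @param nuclearHaplotypes named list of [HaplotypeSet] per nuclear marker;
#'   must contain every `config$nuclearMarkers` entry.
#' @param morphology a [MorphMatrix] or `NULL`.
#' @param config see [evidenceConfig()].
#' @param designate compute the UCS/CCS/DCL designation? (Sympatry is
#'   recorded as not applicable for these allopatric candidates.)
#' @param x an `EvidenceProfile` (accessor).
#' @return An [EvidenceProfile].
#' @export
evaluateLines <- function(candidate, candidatePopulations,
                          comparisonPopulations, partitions,
                          nuclearHaplotypes = list(), morphology = NULL,
                          config = evidenceConfig(), designate = TRUE) {
  detail <- list()
  mk <- config$mtdnaMarker
  if (!mk %in% names(partitions))
    txStop("taxlines_evidence_error",
           "no network partition for configured mtDNA marker '", mk, "'")
  np <- partitions[[mk]]
  # exclusivity judged against the comparison populations only
  pops <- componentPopulations(np)
  carrying <- vapply(pops, function(p) any(candidatePopulations %in% p), NA)
  mtdna <- all(vapply(pops[carrying], function(p)
    !any(p %in% comparisonPopulations), NA))
  detail$mtdna <- list(marker = mk, nComponents = nComponents(np),
                       componentPopulations = pops)

  ndna <- NA
  if (length(config$nuclearMarkers)) {
    missing <- setdiff(config$nuclearMarkers, names(nuclearHaplotypes))
    if (length(missing))
      txStop("taxlines_evidence_error",
             "no haplotype set for configured nuclear marker(s): ",
             paste(missing, collapse = ", "))
    nd <- lapply(nuclearHaplotypes[config$nuclearMarkers], .nuclearDetail,
                 candPops = candidatePopulations,
                 otherPops = comparisonPopulations)
    anyShared <- any(vapply(nd, `[[`, NA, "shared"))
    totalSubs <- sum(vapply(nd, `[[`, 0L, "substitutions"))
    ndna <- !anyShared && totalSubs >= config$minNuclearSubstitutions
    detail$ndna <- list(markers = config$nuclearMarkers, shared = anyShared,
                        substitutions = totalSubs,
                        required = config$minNuclearSubstitutions,
                        perMarker = nd)
  }

  morph <- NA
  if (!is.null(morphology)) {
    rep <- fixedDiagnosticCharacters(morphology, candidatePopulations,
                                     comparisonPopulations,
                                     includeGraded = !config$excludeGraded)
    morph <- hasFixedDiagnostic(rep)
    detail$morphology <- rep
  }

  desig <- NA_character_
  if (designate) {
    # shared mtDNA haplotypes with the comparison set indicate admixture
    # (sharing a network component alone does not)
    admix <- any(vapply(np@haplotypes@members, function(ids) {
      p <- unique(popOf(np@haplotypes@metadata, ids))
      any(p %in% candidatePopulations) && any(p %in% comparisonPopulations)
    }, NA))
    desig <- designateCandidate(molecularDistinct = isTRUE(mtdna) ||
                                  isTRUE(ndna),
                                relevantCharacter = isTRUE(morph),
                                sympatricNoAdmixture = NA,
                                admixture = admix)
    detail$sympatry <- "not-applicable (allopatric, insular distribution)"
  }

  methods::new("EvidenceProfile", candidate = candidate,
               populations = candidatePopulations,
               comparison = comparisonPopulations,
               mtdna = mtdna, ndna = ndna, morphology = morph,
               designation = desig, detail = detail)
}

#' @rdname evaluateLines
#' @export
setMethod("linesOfEvidence", "EvidenceProfile", function(x)
  c(mtdna = x@mtdna, ndna = x@ndna, morphology = x@morphology))

nLines <- function(profile)
  sum(linesOfEvidence(profile), na.rm = TRUE)

setMethod("show", "EvidenceProfile", function(object) {
  li <- linesOfEvidence(object)
  cat("EvidenceProfile '", object@candidate, "' (",
      paste(object@populations, collapse = "+"), " vs ",
      paste(object@comparison, collapse = "+"), ")\n", sep = "")
  cat("  mtDNA:", li[1L], " nDNA:", li[2L], " morphology:", li[3L],
      " -> lines:", sum(li, na.rm = TRUE), "\n")
  if (!is.na(object@designation))
    cat("  designation:", object@designation, "\n")
})

#' Assign species and subspecies ranks under a guide grouping
#'
#' Hierarchical rank assignment: each guide clade is evaluated against the
#' populations outside it; a clade supported by two or more lines of evidence
#' is ranked as a species. Within a species clade, each candidate is
#' evaluated against its sibling(s): exactly one line gives subspecies rank,
#' two or more elevate the candidate to a separate species (the "strict
#' application" outcome), none synonymises it with its sibling(s). Singleton
#' clades take their own rank directly. Clades supported by fewer than two
#' lines are synonymised into their nearest clade (in guide order) and the
#' rationale records it.
#'
#' @param cladeProfiles named list: clade label -> [EvidenceProfile] of the
#'   clade against the other clades.
#' @param candidateProfiles named list: candidate label ->
#'   [EvidenceProfile] of the candidate against its within-clade sibling(s).
#'   Singleton-clade candidates may be omitted.
#' @param grouping named character vector: candidate -> clade label.
#' @param x a `RankAssignment` (accessor).
#' @return A [RankAssignment]. Ranks are a deterministic function of the
#'   profiles and the grouping.
#' @export
assignRanks <- function(cladeProfiles, candidateProfiles, grouping) {
  if (anyDuplicated(names(grouping)))
    txStop("taxlines_evidence_error", "overlapping grouping: duplicated candidates")
  clades <- unique(unname(grouping))
  if (!all(clades %in% names(cladeProfiles)))
    txStop("taxlines_evidence_error", "missing clade profile(s): ",
           paste(setdiff(clades, names(cladeProfiles)), collapse = ", "))
  cladeLines <- vapply(cladeProfiles[clades], nLines, 0)
  speciesOf <- character(0)   # clade -> species label
  speciesClades <- clades[cladeLines >= 2L]
  if (!length(speciesClades)) speciesClades <- clades[1L]  # nothing distinct:
  for (cl in clades) {
    speciesOf[cl] <- if (cl %in% speciesClades) cl else {
      host <- speciesClades[1L]
      host
    }
  }
  rows <- list(); species <- list()
  for (cand in names(grouping)) {
    cl <- grouping[[cand]]
    sibs <- setdiff(names(grouping)[grouping == cl], cand)
    clLines <- cladeLines[[cl]]
    cladeNote <- sprintf("clade %s vs other clades: %d line(s)%s", cl,
                         clLines,
                         if (!cl %in% speciesClades)
                           sprintf(" -> synonymised into %s", speciesOf[[cl]])
                         else "")
    if (!length(sibs)) {
      # singleton clade: takes its own rank directly
      if (clLines >= 2L) { rank <- "species"; sp <- cl }
      else if (clLines == 1L) { rank <- "subspecies"; sp <- speciesOf[[cl]] }
      else { rank <- "not-distinct"; sp <- speciesOf[[cl]] }
      n <- clLines
      note <- cladeNote
    } else {
      pr <- candidateProfiles[[cand]]
      if (is.null(pr))
        txStop("taxlines_evidence_error", "missing candidate profile: ", cand)
      n <- nLines(pr)
      if (n >= 2L) { rank <- "species"; sp <- cand }
      else if (n == 1L) { rank <- "subspecies"; sp <- speciesOf[[cl]] }
      else { rank <- "not-distinct"; sp <- speciesOf[[cl]] }
      note <- sprintf("%s; vs sibling(s) %s: %d line(s) [%s]", cladeNote,
                      paste(sibs, collapse = "+"), n,
                      paste(names(linesOfEvidence(pr))[
                        which(linesOfEvidence(pr))], collapse = ","))
    }
    rows[[cand]] <- data.frame(candidate = cand, clade = cl, species = sp,
                               rank = rank, n_lines = n, rationale = note)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  for (sp in unique(tab$species))
    species[[sp]] <- tab$candidate[tab$species == sp]
  # a species whose only member sits at subspecies rank is lifted to species
  for (sp in names(species)) {
    if (length(species[[sp]]) == 1L) {
      i <- which(tab$candidate == species[[sp]][1L])
      if (tab$rank[i] == "subspecies") tab$rank[i] <- "species"
    }
  }
  methods::new("RankAssignment", table = tab, species = species)
}

#' @rdname assignRanks
#' @export
setMethod("rankTable", "RankAssignment", function(x) x@table)

setMethod("show", "RankAssignment", function(object) {
  nsp <- length(object@species)
  cat("RankAssignment:", nsp, "species\n")
  for (sp in names(object@species)) {
    mem <- object@table[object@table$species == sp, , drop = FALSE]
    cat("  species '", sp, "': ", paste0(mem$candidate, " (", mem$rank, ")",
                                         collapse = ", "), "\n", sep = "")
  }
})
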