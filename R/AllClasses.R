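#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' MarkerAlignment: one aligned locus with sample metadata
#'
#' Container for a single pre-aligned marker: the aligned sequences (all of
#' equal width), the sample metadata (one population per sample, optional
#' voucher and sex), the marker label and a flag stating whether the marker is
#' protein-coding. Build it with [readAlignment()] or [markerAlignment()].
#'
#' @slot marker single character, marker label (e.g. `"cytb"`).
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width aligned sequences,
#'   named by sample ID.
#' @slot metadata a [S4Vectors::DataFrame] with columns `sample_id`,
#'   `population`, `voucher`, `sex`, one row per alignment sample.
#' @slot coding logical flag, `TRUE` for protein-coding markers.
#' @aliases MarkerAlignment
#' @exportClass MarkerAlignment
setClass("MarkerAlignment",
  slots = c(marker = "character", seqs = "DNAStringSet",
            metadata = "DataFrame", coding = "logical"))

setValidity("MarkerAlignment", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || is.na(object@marker))
    msg <- c(msg, "'marker' must be a single non-NA label")
  if (length(object@seqs) == 0L)
    msg <- c(msg, "alignment contains no sequences")
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have the same aligned length")
  if (length(w) && w[1L] < 1L)
    msg <- c(msg, "aligned length must be >= 1")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "sequences must carry unique non-empty sample IDs")
  need <- c("sample_id", "population")
  if (!all(need %in% colnames(object@metadata))) {
    msg <- c(msg, "metadata must have columns 'sample_id' and 'population'")
  } else if (!is.null(ids)) {
    miss <- setdiff(ids, object@metadata$sample_id)
    if (length(miss))
      msg <- c(msg, paste0("samples without metadata: ",
                           paste(miss, collapse = ", ")))
    if (anyDuplicated(object@metadata$sample_id))
      msg <- c(msg, "duplicated sample_id in metadata")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeSet: collapsed haplotypes of one marker
#'
#' Distinct sequence variants after collapsing an alignment under a missing-
#' data policy, with the map from haplotype to member samples. The member sets
#' partition the original samples. Build with [collapseHaplotypes()].
#'
#' @slot marker marker label.
#' @slot sequences character vector of representative sequences, one per
#'   haplotype (uppercase; missing positions may remain where no member
#'   resolves them).
#' @slot members list of character vectors: sample IDs carried by each
#'   haplotype.
#' @slot policy `"strict"` or `"missing-as-wildcard"`.
#' @slot gapAsState logical: was `-` treated as a fifth state?
#' @slot metadata sample metadata inherited from the alignment.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  slots = c(marker = "character", sequences = "character", members = "list",
            policy = "character", gapAsState = "logical",
            metadata = "DataFrame"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@members))
    msg <- c(msg, "'sequences' and 'members' lengths differ")
  ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(ids))
    msg <- c(msg, "member sets must be disjoint (they must partition samples)")
  if (any(!lengths(object@members)))
    msg <- c(msg, "every haplotype must have at least one member")
  if (length(msg)) msg else TRUE
})

#' ConnectionLimit: statistical-parsimony connection limit
#'
#' The maximum number of mutational steps `jMax` that can join two haplotypes
#' of an `L`-site marker such that the estimated probability of a
#' non-homoplastic (parsimonious) connection stays at or above `1 - alpha`,
#' together with the full probability table so the limit can be audited.
#' Build with [connectionLimit()].
#'
#' @slot marker marker label (may be `NA`).
#' @slot L integer, number of sites.
#' @slot alpha significance level; the classical limit of 95% corresponds to
#'   `alpha = 0.05`.
#' @slot jMax largest number of steps justified under the limit.
#' @slot probabilities numeric vector of parsimony probabilities `P_j` for
#'   `j = 1, 2, ...` up to and including the first value below `1 - alpha`.
#' @exportClass ConnectionLimit
setClass("ConnectionLimit",
  slots = c(marker = "character", L = "integer", alpha = "numeric",
            jMax = "integer", probabilities = "numeric"))

setValidity("ConnectionLimit", function(object) {
  msg <- character()
  if (object@L < 1L) msg <- c(msg, "'L' must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must be in (0, 1)")
  p <- object@probabilities
  if (length(p) && any(diff(p) > 1e-12))
    msg <- c(msg, "probabilities must be non-increasing in j")
  if (length(msg)) msg else TRUE
})

#' NetworkPartition: independent statistical-parsimony networks
#'
#' Partition of a [HaplotypeSet] into connected components of the graph whose
#' edges join haplotype pairs separated by at most `jMax` mutational steps.
#' Build with [buildNetworks()].
#'
#' @slot marker marker label.
#' @slot membership integer vector, component index per haplotype.
#' @slot components list of integer vectors of haplotype indices.
#' @slot edges data.frame of intra-component edges with step annotations
#'   (columns `hap1`, `hap2`, `steps`, `intermediates`).
#' @slot limit the [ConnectionLimit] used.
#' @slot haplotypes the underlying [HaplotypeSet].
#' @exportClass NetworkPartition
setClass("NetworkPartition",
  slots = c(marker = "character", membership = "integer", components = "list",
            edges = "data.frame", limit = "ConnectionLimit",
            haplotypes = "HaplotypeSet"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  n <- length(object@haplotypes@sequences)
  if (length(object@membership) != n)
    msg <- c(msg, "'membership' must have one entry per haplotype")
  idx <- sort(unlist(object@components, use.names = FALSE))
  if (n && !identical(idx, seq_len(n)))
    msg <- c(msg, "'components' must partition the haplotype indices")
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise uncorrected p-distances
#'
#' Symmetric matrix of uncorrected p-distances (fractions in \[0, 1\]) between
#' the samples of one marker alignment. Build with [distanceMatrix()].
#'
#' @slot samples ordered sample IDs.
#' @slot d symmetric numeric matrix with zero diagonal.
#' @slot marker marker label.
#' @slot deletion missing-data policy used (`"pairwise"` or
#'   `"complete-against-matrix"`).
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  slots = c(samples = "character", d = "matrix", marker = "character",
            deletion = "character"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (nrow(d) != length(object@samples) || ncol(d) != length(object@samples))
    msg <- c(msg, "matrix dimensions must match 'samples'")
  if (nrow(d)) {
    if (max(abs(d - t(d)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "diagonal must be zero")
    rng <- range(d, na.rm = TRUE)
    if (rng[1L] < -1e-12 || rng[2L] > 1 + 1e-12)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' DistanceSummary: within- and between-group p-distance summaries
#'
#' Per-group and per-group-pair records of minimum, mean and maximum
#' p-distance, expressed as percentages. Build with [groupDistanceSummary()].
#'
#' @slot marker marker label.
#' @slot table data.frame with columns `scope` (`"within"`/`"between"`),
#'   `group1`, `group2`, `n_pairs`, `min`, `mean`, `max` (percent). Singleton
#'   groups yield a within record with `n_pairs = 0` and `NA` statistics.
#' @slot level `"population"` or `"clade"`.
#' @exportClass DistanceSummary
setClass("DistanceSummary",
  slots = c(marker = "character", table = "data.frame", level = "character"))

setValidity("DistanceSummary", function(object) {
  tab <- object@table
  ok <- is.na(tab$min) | (tab$min <= tab$mean + 1e-9 & tab$mean <= tab$max + 1e-9)
  if (!all(ok)) "summary must satisfy min <= mean <= max" else TRUE
})

#' ThresholdReport: barcoding-threshold comparison
#'
#' Comparison of between-group maximum p-distances against a divergence
#' threshold (percent). The relation is inclusive at the boundary: a maximum
#' equal to the threshold "meets-or-exceeds" it. Build with
#' [thresholdComparison()].
#'
#' @slot threshold threshold in percent (e.g. 8.3).
#' @slot table data.frame with columns `group1`, `group2`, `min`, `max`,
#'   `relation` (`"below"` or `"meets-or-exceeds"`).
#' @exportClass ThresholdReport
setClass("ThresholdReport",
  slots = c(threshold = "numeric", table = "data.frame"))

setValidity("ThresholdReport", function(object) {
  tab <- object@table
  exp_rel <- ifelse(tab$max >= object@threshold, "meets-or-exceeds", "below")
  if (nrow(tab) && !identical(as.character(tab$relation), exp_rel))
    "relation inconsistent with numeric comparison" else TRUE
})

#' MorphMatrix: typed specimen-by-character morphology table
#'
#' Specimens with population and sex labels plus typed characters: `metric`
#' (continuous measurements, mm), `meristic` (counts, bilateral ones stored as
#' `*_L`/`*_R` column pairs) and `qualitative` (finite state sets). Characters
#' may carry the flags `graded` (clinal, excluded from diagnosis by default)
#' and `sex-limited:<sex>` (scored only in one sex). Build with
#' [readMorphMatrix()] or [morphMatrix()].
#'
#' @slot data data.frame with columns `specimen`, `population`, `sex` followed
#'   by the characters.
#' @slot types named character vector, one of `"metric"`, `"meristic"`,
#'   `"qualitative"` per character column.
#' @slot graded character vector of flagged character names.
#' @slot sexLimited named character vector: character name -> sex.
#' @exportClass MorphMatrix
setClass("MorphMatrix",
  slots = c(data = "data.frame", types = "character", graded = "character",
            sexLimited = "character"))

setValidity("MorphMatrix", function(object) {
  msg <- character()
  need <- c("specimen", "population", "sex")
  if (!all(need %in% colnames(object@data)))
    msg <- c(msg, "data must have columns specimen, population, sex")
  chars <- setdiff(colnames(object@data), need)
  if (!setequal(chars, names(object@types)))
    msg <- c(msg, "'types' must name exactly the character columns")
  bad <- setdiff(unique(object@types), c("metric", "meristic", "qualitative"))
  if (length(bad))
    msg <- c(msg, paste0("unknown character type(s): ", paste(bad, collapse = ", ")))
  for (ch in names(object@types)) {
    if (object@types[[ch]] %in% c("metric", "meristic") &&
        !is.numeric(object@data[[ch]]))
      msg <- c(msg, paste0("numeric character '", ch, "' has non-numeric values"))
  }
  if (length(msg)) msg else TRUE
})

#' ManovaResult: MANOVA with pairwise Hotelling tests
#'
#' Overall Wilks' lambda with its F approximation, plus two-group Hotelling
#' T-squared tests for every pair of groups. Build with [morphManova()].
#'
#' @slot wilks Wilks' lambda statistic.
#' @slot statistic approximate F value for the overall test.
#' @slot df numeric length-2 vector of F degrees of freedom.
#' @slot pValue overall p-value.
#' @slot pairwise data.frame: `group1`, `group2`, `T2`, `F`, `df1`, `df2`,
#'   `p`, `testable`.
#' @slot characters characters used.
#' @slot nUsed complete cases per group actually analysed (named integer).
#' @slot dropped specimens dropped for missing values.
#' @exportClass ManovaResult
setClass("ManovaResult",
  slots = c(wilks = "numeric", statistic = "numeric", df = "numeric",
            pValue = "numeric", pairwise = "data.frame",
            characters = "character", nUsed = "integer", dropped = "character"))

#' CvaResult: canonical variates analysis
#'
#' Generalized eigen-decomposition of the between-group scatter against the
#' within-group scatter. Axis signs are indeterminate (any axis may be
#' reflected); compare loadings by magnitude only. Build with [morphCva()].
#'
#' @slot scores specimen-by-axis score matrix.
#' @slot loadings character-by-axis coefficient matrix (raw canonical
#'   coefficients).
#' @slot eigenvalues non-negative, sorted decreasingly.
#' @slot grouping factor of group labels for the scored specimens.
#' @slot characters characters used.
#' @slot ridge ridge coefficient applied if the within-scatter was singular
#'   (0 when none was needed).
#' @exportClass CvaResult
setClass("CvaResult",
  slots = c(scores = "matrix", loadings = "matrix", eigenvalues = "numeric",
            grouping = "factor", characters = "character", ridge = "numeric"))

setValidity("CvaResult", function(object) {
  ev <- object@eigenvalues
  msg <- character()
  if (any(ev < -1e-8)) msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted decreasingly")
  if (length(msg)) msg else TRUE
})

#' DiagnosticReport: fixed and quantitative diagnosability per character
#'
#' For one group-vs-group comparison, the per-character status: a qualitative
#' character is `fixed-qualitative` iff the observed state sets are disjoint
#' (and both non-empty); a numeric character is `quantitative-diagnosable` iff
#' the observed ranges are disjoint (or Amadon's 75% rule passes when that
#' mode is enabled); everything else is `overlapping`. Build with
#' [fixedDiagnosticCharacters()].
#'
#' @slot groupA,groupB labels of the compared groups.
#' @slot table data.frame: `character`, `type`, `status`, `detail`.
#' @slot excluded characters excluded by the graded/sex-limited flags.
#' @exportClass DiagnosticReport
setClass("DiagnosticReport",
  slots = c(groupA = "character", groupB = "character", table = "data.frame",
            excluded = "character"))

#' EvidenceProfile: the three lines of evidence for one candidate
#'
#' Booleans for the mtDNA line (independent parsimony network), the nDNA line
#' (haplotype exclusivity with enough distinguishing substitutions) and the
#' morphology line (at least one fixed non-graded diagnostic character), with
#' the supporting detail and the candidate-species designation
#' (UCS/CCS/DCL). Build with [evaluateLines()].
#'
#' @slot candidate candidate label.
#' @slot populations populations forming the candidate.
#' @slot comparison populations compared against.
#' @slot mtdna,ndna,morphology the three lines (logical; `NA` when the
#'   corresponding data were not supplied).
#' @slot designation `"UCS"`, `"CCS"` or `"DCL"` (may be `NA` if not
#'   designated).
#' @slot detail list of supporting objects (network partition reference,
#'   shared-haplotype table, substitution counts, diagnostic reports).
#' @exportClass EvidenceProfile
setClass("EvidenceProfile",
  slots = c(candidate = "character", populations = "character",
            comparison = "character", mtdna = "logical", ndna = "logical",
            morphology = "logical", designation = "character",
            detail = "list"))

#' RankAssignment: hierarchical species/subspecies ranks
#'
#' Mapping of candidate taxa to species and subspecies under a guide clade
#' grouping: a clade supported by two or more lines of evidence is ranked as a
#' species; within it, a candidate supported by exactly one line against its
#' sibling(s) is a subspecies, by two or more a species of its own, and by
#' none is not distinct. Build with [assignRanks()].
#'
#' @slot table data.frame: `candidate`, `clade`, `species`, `rank`
#'   (`"species"`, `"subspecies"`, `"not-distinct"`), `n_lines`, `rationale`.
#' @slot species named list: species label -> member candidates.
#' @exportClass RankAssignment
setClass("RankAssignment",
  slots = c(table = "data.frame", species = "list"))

setValidity("RankAssignment", function(object) {
  msg <- character()
  tab <- object@table
  if (nrow(tab)) {
    one <- vapply(object@species, length, 1L) == 1L
    for (sp in names(object@species)[one]) {
      cand <- object@species[[sp]][1L]
      rk <- tab$rank[tab$candidate == cand]
      if (length(rk) == 1L && rk == "subspecies")
        msg <- c(msg, "a species with a single member cannot hold it at subspecies rank")
    }
    if (any(tab$rank == "subspecies" & is.na(tab$species)))
      msg <- c(msg, "every subspecies must belong to exactly one species")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: parameters of a simulated island scenario
#'
#' Populations with sample sizes and clade assignments; per-marker alignment
#' length and divergence tiers (expected pairwise p-distance in percent within
#' populations, between within-clade sisters and between clades) or, for
#' nuclear markers, exact substitution counts placed on named branches; and
#' per-character morphology distributions. Build with [scenarioConfig()] or
#' use [comoroPreset()].
#'
#' @slot populations population labels.
#' @slot clades named character: population -> clade label.
#' @slot seqN named integer: sequence sample size per population.
#' @slot morphN named integer: morphology sample size per population.
#' @slot markers named list of marker specifications (see [scenarioConfig()]).
#' @slot morphology named list of character specifications.
#' @slot seed base seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  slots = c(populations = "character", clades = "character",
            seqN = "integer", morphN = "integer", markers = "list",
            morphology = "list", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (!setequal(names(object@clades), object@populations))
    msg <- c(msg, "'clades' must map every population to a clade")
  if (!all(object@populations %in% names(object@seqN)) ||
      !all(object@populations %in% names(object@morphN)))
    msg <- c(msg, "sample sizes must be given for every population")
  for (m in object@markers) {
    if (!is.null(m$within_pct)) {
      s <- if (is.null(m$sister_pct)) m$within_pct else min(m$sister_pct)
      cl <- if (is.null(m$clade_pct)) s else m$clade_pct
      if (m$within_pct > s + 1e-9 || max(if (is.null(m$sister_pct)) 0 else m$sister_pct) > cl + 1e-9)
        msg <- c(msg, paste0("marker '", m$name,
                             "': divergence tiers must satisfy within <= sister <= clade"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' RunReport: integrated pipeline output
#'
#' Everything [runPipeline()] computed: per-marker distance summaries and
#' network partitions, the threshold report, morphology results, evidence
#' profiles at clade and candidate level, the rank assignment, the
#' configuration echo and the stage log.
#'
#' @slot summaries named list of [DistanceSummary] (population level), plus a
#'   `clade` sub-list.
#' @slot thresholds [ThresholdReport] or `NULL`-like empty list.
#' @slot partitions named list of [NetworkPartition].
#' @slot haplotypes named list of [HaplotypeSet].
#' @slot morphology list: `manova`, `cva`, `diagnostics`.
#' @slot profiles list: `clade` and `candidate` named lists of
#'   [EvidenceProfile].
#' @slot ranks [RankAssignment].
#' @slot config configuration echo (list).
#' @slot log character vector of stage-prefixed log lines.
#' @exportClass RunReport
setClass("RunReport",
  slots = c(summaries = "list", thresholds = "list", partitions = "list",
            haplotypes = "list", morphology = "list", profiles = "list",
            ranks = "RankAssignment", config = "list", log = "character"))
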