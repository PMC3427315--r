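#' Construct a simulation scenario
#'
#' A scenario fixes the study conditions a simulated dataset emulates:
#' populations with sequence/morphology sample sizes, a clade structure,
#' per-marker divergence tiers (expected pairwise uncorrected p-distance, in
#' percent, within populations / between within-clade sisters / between
#' clades) or exact substitution counts on named branches for nuclear
#' markers, and per-character morphology distributions.
#'
#' Marker specifications are lists with elements `name`, `length_bp`,
#' `coding`, and either the tier set `within_pct`, `sister_pct` (single value
#' or named per clade) and `clade_pct`, or `fixed`, a named list
#' branch -> exact substitution count where a branch is a population or clade
#' label (all other branches are substitution-free). Morphology
#' specifications are lists with `name`, `type`, and either `mean`/`sd`
#' (named per population; `kind = "normal"`, the default, rounded for
#' meristic characters), a `table` of per-population `values`/`probs`
#' (`kind = "discrete"`), or per-population `states` with an optional
#' `overlap` fraction (qualitative); plus optional `bilateral`, `graded` and
#' `sexLimited` flags.
#'
#' @param populations population labels.
#' @param clades named character: population -> clade.
#' @param seqN,morphN named integer sample sizes per population.
#' @param markers list of marker specifications.
#' @param morphology list of morphology character specifications.
#' @param seed base seed for all derived simulations.
#' @return A [ScenarioConfig].
#' @seealso [comoroPreset()], [simulateSequences()], [simulateMorphology()]
#' @export
scenarioConfig <- function(populations, clades, seqN, morphN, markers,
                           morphology = list(), seed = 1L) {
  names(markers) <- vapply(markers, `[[`, "", "name")
  names(morphology) <- vapply(morphology, function(x) x$name, "")
  methods::new("ScenarioConfig", populations = populations, clades = clades,
               seqN = as.integer(seqN[populations]) |>
                 stats::setNames(populations),
               morphN = as.integer(morphN[populations]) |>
                 stats::setNames(populations),
               markers = markers, morphology = morphology,
               seed = as.integer(seed))
}

#' Four-island Comoros-like scenario preset
#'
#' The default study conditions: four island populations (Anjouan, Mayotte,
#' GrandComoro, Moheli) forming two clade pairs (AM, GM); protein-coding
#' mitochondrial markers whose divergence tiers follow the published
#' uncorrected p-distances of the Comoran tree-snake populations (cyt b:
#' within-island pairs around 0.5% with maxima near 1.2%, Anjouan-Mayotte
#' around 5.4%, GrandComoro-Moheli around 7.7%, between clades around 9.5%;
#' COI tiers sized so the clade pair straddles the 8.3% lamprophiid
#' threshold); a slower 16S-like marker whose Anjouan-Mayotte divergence
#' falls below the 95% connection limit; and three nuclear markers each
#' carrying exactly one substitution (613 bp Rag2 separating Anjouan, 468 bp
#' PRLR separating the AM clade, 626 bp c-mos separating GrandComoro).
#' Morphology mirrors the published summary table: broadly overlapping
#' morphometric and meristic distributions, a qualitative loreal-contact
#' character fixed between (but not within) the clades ("2+3" vs "2"),
#' occasional 17 midbody scale rows everywhere except Anjouan, and graded /
#' sex-limited male coloration characters that are excluded from diagnosis by
#' default.
#'
#' @param seed base seed.
#' @return A [ScenarioConfig].
#' @export
comoroPreset <- function(seed = 1L) {
  pops <- c("Anjouan", "Mayotte", "GrandComoro", "Moheli")
  clades <- c(Anjouan = "AM", Mayotte = "AM",
              GrandComoro = "GM", Moheli = "GM")
  mkTier <- function(name, L, within, sister, clade, coding = TRUE)
    list(name = name, length_bp = L, coding = coding, within_pct = within,
         sister_pct = sister, clade_pct = clade)
  markers <- list(
    mkTier("cytb", 700L, 0.5, c(AM = 5.4, GM = 7.7), 9.5),
    mkTier("COI",  658L, 0.5, c(AM = 5.8, GM = 5.65), 8.4),
    mkTier("ND4",  700L, 0.5, c(AM = 5.5, GM = 7.5), 9.0),
    mkTier("16S",  500L, 0.2, c(AM = 0.8, GM = 3.0), 4.0, coding = FALSE),
    list(name = "Rag2", length_bp = 613L, coding = TRUE,
         fixed = list(Anjouan = 1L)),
    list(name = "PRLR", length_bp = 468L, coding = TRUE,
         fixed = list(AM = 1L)),
    list(name = "cmos", length_bp = 626L, coding = TRUE,
         fixed = list(GrandComoro = 1L)))
  nm <- function(a, m, g, h) c(Anjouan = a, Mayotte = m, GrandComoro = g,
                               Moheli = h)
  morph <- list(
    list(name = "SVL", type = "metric",
         mean = nm(653.8, 602.6, 569.7, 682.6),
         sd = nm(130.6, 87.6, 80.0, 126.1)),
    list(name = "V", type = "meristic",
         mean = nm(241.8, 238.3, 244.2, 242.2),
         sd = nm(10.7, 10.9, 7.7, 8.1)),
    list(name = "SC", type = "meristic",
         mean = nm(95.5, 95.5, 97.1, 104.1),
         sd = nm(11.8, 15.6, 9.3, 20.1)),
    list(name = "MD", type = "meristic", kind = "discrete",
         table = list(Anjouan = list(values = 19, probs = 1),
                      Mayotte = list(values = c(19, 17), probs = c(6, 1) / 7),
                      GrandComoro = list(values = c(19, 17),
                                         probs = c(17, 2) / 19),
                      Moheli = list(values = c(19, 17), probs = c(9, 2) / 11))),
    list(name = "SLAB", type = "meristic", bilateral = TRUE,
         mean = nm(8.5, 8.5, 8.5, 8.2), sd = nm(0.5, 0.5, 0.7, 0.4)),
    list(name = "ILAB", type = "meristic", bilateral = TRUE,
         mean = nm(9.4, 9.2, 9.8, 9.7), sd = nm(0.7, 0.5, 0.7, 0.7)),
    list(name = "SLCE", type = "meristic", bilateral = TRUE,
         mean = nm(2.1, 2.1, 2.0, 2.0), sd = nm(0.3, 0.3, 0.3, 0.3)),
    list(name = "loreal", type = "qualitative",
         states = c(Anjouan = "2+3", Mayotte = "2+3",
                    GrandComoro = "2", Moheli = "2")),
    list(name = "dorsal_pattern", type = "qualitative", graded = TRUE,
         sexLimited = "male",
         states = nm("blotched", "spotted", "uniform", "diffuse-spots")),
    list(name = "ventral_line", type = "qualitative", graded = TRUE,
         sexLimited = "male",
         states = nm("absent", "present", "absent", "absent")))
  scenarioConfig(pops, clades,
                 seqN = c(Anjouan = 5L, Mayotte = 6L, GrandComoro = 6L,
                          Moheli = 5L),
                 morphN = c(Anjouan = 6L, Mayotte = 7L, GrandComoro = 19L,
                            Moheli = 11L),
                 markers = markers, morphology = morph, seed = seed)
}

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:", length(object@populations), "populations in",
      length(unique(object@clades)), "clades; seed", object@seed, "\n")
  cat("  markers:", paste(names(object@markers), collapse = ", "), "\n")
  cat("  morphology characters:", length(object@morphology), "\n")
})

# site allocator: substitutions land on previously untouched sites while any
# remain (minimising homoplasy so p-distance ~ step distance); overflow falls
# back to multiple hits and raises a warning flag.
.makeSitePicker <- function(L) {
  unused <- seq_len(L); overflow <- FALSE
  pick <- function(k) {
    if (k == 0L) return(integer())
    take <- integer()
    if (length(unused)) {
      t1 <- sample(unused, min(k, length(unused)))
      unused <<- setdiff(unused, t1)
      take <- t1
    }
    if (length(take) < k) {
      overflow <<- TRUE
      take <- c(take, sample.int(L, k - length(take)))
    }
    take
  }
  list(pick = pick, overflow = function() overflow)
}

.mutate <- function(seqChars, sites) {
  for (s in sites)
    seqChars[s] <- sample(setdiff(c("A", "C", "G", "T"), seqChars[s]), 1L)
  seqChars
}

#' Simulate a calibrated marker alignment
#'
#' Generates an alignment whose expected pairwise p-distances hit the
#' configured divergence tiers: an ancestral random sequence evolves along a
#' fixed population tree (root -> clade branches -> population branches ->
#' tips); each branch receives a Poisson number of substitutions with mean
#' chosen so that expected within-population, within-clade and between-clade
#' pairwise distances equal the configured percentages. Substitutions are
#' placed on previously untouched sites while any remain, so p-distance
#' closely tracks mutational step distance (no model correction is involved
#' because the calibrated quantities are uncorrected p-distances); if the
#' requested divergence exhausts the sites a warning is raised and multiple
#' hits occur. Markers with `fixed` branch substitution counts place exactly
#' those substitutions and none elsewhere. Deterministic given the seed.
#'
#' @param cfg a [ScenarioConfig].
#' @param marker marker name in `cfg`.
#' @param seed seed; defaults to a sub-seed derived from `cfg@seed` and the
#'   marker's position.
#' @return A [MarkerAlignment].
#' @export
simulateSequences <- function(cfg, marker, seed = NULL) {
  if (!marker %in% names(cfg@markers))
    txStop("taxlines_scenario_error", "unknown marker '", marker, "'")
  spec <- cfg@markers[[marker]]
  if (is.null(seed))
    seed <- subSeed(cfg@seed, match(marker, names(cfg@markers)))
  L <- as.integer(spec$length_bp)
  clades <- unique(unname(cfg@clades))
  withSeed(seed, {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    picker <- .makeSitePicker(L)
    if (!is.null(spec$fixed)) {
      cladeE <- stats::setNames(rep(0, length(clades)), clades)
      popE <- stats::setNames(rep(0, length(cfg@populations)),
                              cfg@populations)
      tipE <- 0
      draw <- function(e) as.integer(e)   # exact counts
      for (br in names(spec$fixed)) {
        k <- spec$fixed[[br]]
        if (br %in% clades) cladeE[br] <- k
        else if (br %in% cfg@populations) popE[br] <- k
        else txStop("taxlines_scenario_error", "fixed branch '", br,
                    "' is neither a population nor a clade")
      }
    } else {
      w <- spec$within_pct / 100
      sis <- spec$sister_pct
      if (length(sis) == 1L && is.null(names(sis)))
        sis <- stats::setNames(rep(sis, length(clades)), clades)
      cl <- spec$clade_pct / 100
      sis <- sis[clades] / 100
      cladeE <- (cl - sis) / 2 * L
      popE <- stats::setNames((sis[cfg@clades[cfg@populations]] - w) / 2 * L,
                              cfg@populations)
      tipE <- w / 2 * L
      draw <- function(e) stats::rpois(1L, e)
      total <- sum(cladeE) + sum(popE) +
        tipE * sum(cfg@seqN[cfg@populations])
      if (total > 0.75 * L)
        txStop("taxlines_scenario_error", "requested divergence (expected ",
               round(total), " substitutions) is infeasible for ", L,
               " sites")
    }
    cladeSeq <- lapply(stats::setNames(clades, clades), function(cc)
      .mutate(anc, picker$pick(draw(cladeE[[cc]]))))
    seqs <- character(); ids <- character(); popv <- character()
    for (p in cfg@populations) {
      ps <- .mutate(cladeSeq[[cfg@clades[[p]]]], picker$pick(draw(popE[[p]])))
      for (i in seq_len(cfg@seqN[[p]])) {
        tip <- .mutate(ps, picker$pick(draw(tipE)))
        ids <- c(ids, sprintf("%s_%02d", p, i))
        popv <- c(popv, p)
        seqs <- c(seqs, paste(tip, collapse = ""))
      }
    }
    if (picker$overflow())
      warning("site pool exhausted for marker '", marker,
              "': multiple hits were placed")
    names(seqs) <- ids
    markerAlignment(marker, seqs,
                    data.frame(sample_id = ids, population = popv),
                    coding = isTRUE(spec$coding))
  })
}

#' Simulate a typed morphology matrix
#'
#' Draws numeric characters per population from the configured normal (or
#' discrete) distributions (meristic values rounded to integers, bilateral
#' characters as independent left/right draws), assigns qualitative states
#' per population with the configured overlap fraction, and scores
#' sex-limited characters only in the relevant sex (sexes are assigned
#' 50/50). Deterministic given the seed; the result round-trips through
#' [writeMorphMatrix()]/[readMorphMatrix()].
#'
#' @param cfg a [ScenarioConfig].
#' @param seed seed; defaults to a sub-seed of `cfg@seed`.
#' @return A [MorphMatrix].
#' @export
simulateMorphology <- function(cfg, seed = NULL) {
  if (is.null(seed)) seed <- subSeed(cfg@seed, 1000L)
  withSeed(seed, {
    pops <- rep(cfg@populations, cfg@morphN[cfg@populations])
    n <- length(pops)
    dat <- data.frame(
      specimen = sprintf("%s_M%02d", pops,
                         unlist(lapply(cfg@morphN[cfg@populations], seq_len))),
      population = pops,
      sex = sample(c("male", "female"), n, replace = TRUE))
    types <- character(); graded <- character(); sexLim <- character()
    for (spec in cfg@morphology) {
      drawNum <- function(p, k) {
        if (identical(spec$kind, "discrete")) {
          tb <- spec$table[[p]]
          tb$values[sample.int(length(tb$values), k, replace = TRUE,
                               prob = tb$probs)]
        } else {
          v <- stats::rnorm(k, spec$mean[[p]], spec$sd[[p]])
          if (spec$type == "meristic") round(v) else round(v, 1)
        }
      }
      cols <- if (isTRUE(spec$bilateral))
        paste0(spec$name, c("_L", "_R")) else spec$name
      for (col in cols) {
        if (spec$type == "qualitative") {
          v <- vapply(pops, function(p) {
            st <- spec$states[[p]]
            ov <- if (is.null(spec$overlap)) 0 else spec$overlap
            if (ov > 0 && stats::runif(1) < ov) {
              others <- unique(unlist(spec$states))
              others <- setdiff(others, st)
              if (length(others)) sample(others, 1L) else st
            } else st
          }, "")
        } else {
          v <- unlist(lapply(cfg@populations, function(p)
            drawNum(p, cfg@morphN[[p]])))
        }
        if (!is.null(spec$sexLimited) && !is.na(spec$sexLimited[1L]) &&
            length(spec$sexLimited)) {
          v[dat$sex != spec$sexLimited] <- NA
        }
        dat[[col]] <- unname(v)
        types[col] <- spec$type
        if (isTRUE(spec$graded)) graded <- c(graded, col)
        if (!is.null(spec$sexLimited)) sexLim[col] <- spec$sexLimited
      }
    }
    morphMatrix(dat, types, graded, sexLim)
  })
}

#' Write an alignment to FASTA
#' @param aln a [MarkerAlignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@seqs, path)
  invisible(path)
}

#' Serialise / restore a scenario as YAML
#' @param cfg a [ScenarioConfig].
#' @param path YAML file path.
#' @return `scenarioToYaml` returns `path` invisibly; `scenarioFromYaml`
#'   returns a [ScenarioConfig].
#' @export
scenarioToYaml <- function(cfg, path) {
  # named vectors must become maps, or YAML drops their names
  listify <- function(x, fields) {
    for (f in fields)
      if (!is.null(x[[f]]) && !is.list(x[[f]])) x[[f]] <- as.list(x[[f]])
    x
  }
  obj <- list(populations = as.list(cfg@populations),
              clades = as.list(cfg@clades),
              seqN = as.list(cfg@seqN), morphN = as.list(cfg@morphN),
              markers = lapply(cfg@markers, listify, fields = "sister_pct"),
              morphology = lapply(cfg@morphology, listify,
                                  fields = c("mean", "sd", "states")),
              seed = cfg@seed)
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' @rdname scenarioToYaml
#' @export
scenarioFromYaml <- function(path) {
  obj <- yaml::yaml.load_file(path)
  fixNamed <- function(x) if (is.list(x)) unlist(x) else x
  markers <- lapply(obj$markers, function(m) {
    for (f in c("sister_pct")) if (!is.null(m[[f]])) m[[f]] <- fixNamed(m[[f]])
    m
  })
  morphology <- lapply(obj$morphology, function(m) {
    for (f in c("mean", "sd", "states")) if (!is.null(m[[f]]))
      m[[f]] <- fixNamed(m[[f]])
    if (!is.null(m$table))
      m$table <- lapply(m$table, function(t)
        list(values = unlist(t$values), probs = unlist(t$probs)))
    m
  })
  scenarioConfig(unlist(obj$populations), unlist(obj$clades),
                 unlist(obj$seqN), unlist(obj$morphN), markers, morphology,
                 seed = obj$seed)
}
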