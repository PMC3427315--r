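# Fixtures are built in code; nothing binary ships with the tests.

tinyMeta <- function(ids, pops) {
  data.frame(sample_id = ids, population = pops, stringsAsFactors = FALSE)
}

writeFastaFile <- function(seqs, path = tempfile(fileext = ".fasta"),
                           wrap = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  path
}

writeMetaFile <- function(md, path = tempfile(fileext = ".csv")) {
  if (!"voucher" %in% names(md)) md$voucher <- NA
  if (!"sex" %in% names(md)) md$sex <- NA
  utils::write.csv(md, path, row.names = FALSE)
  path
}

randomSeqs <- function(n, L, missFrac = 0, alphabet = c("A", "C", "G", "T")) {
  out <- vapply(seq_len(n), function(i) {
    s <- sample(alphabet, L, replace = TRUE)
    if (missFrac > 0) {
      k <- rbinom(1L, L, missFrac)
      if (k > 0)
        s[sample.int(L, k)] <- sample(c("N", "-"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  names(out) <- sprintf("s%02d", seq_len(n))
  out
}

randomAlignment <- function(n, L, pops = NULL, missFrac = 0) {
  seqs <- randomSeqs(n, L, missFrac)
  if (is.null(pops)) pops <- rep("P1", n)
  markerAlignment("rand", seqs, tinyMeta(names(seqs), pops))
}

# Independent p-distance oracle: plain double loop over characters, nothing
# shared with the package implementation.
oraclePDist <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- c("A", "C", "G", "T")
  ncmp <- 0L; ndiff <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% ok && cb[i] %in% ok) {
      ncmp <- ncmp + 1L
      if (ca[i] != cb[i]) ndiff <- ndiff + 1L
    }
  }
  if (ncmp == 0L) NA_real_ else ndiff / ncmp
}

# Independent Hamming-step oracle over comparable sites.
oracleSteps <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- c("A", "C", "G", "T")
  sum(ca %in% ok & cb %in% ok & ca != cb)
}

# Independent connected-components oracle: breadth-first search on the
# threshold graph of a step-distance matrix.
oracleComponents <- function(d, jmax) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n); cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(d[v, ] <= jmax & is.na(comp)))
    }
  }
  comp
}

# canonical partition representation for comparisons
canonicalPartition <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))[
    order(vapply(split(seq_along(membership), membership),
                 function(x) min(x), 1L))]
}

# small hand-typed morphology table used across morphology tests
demoMorph <- function() {
  dat <- data.frame(
    specimen = sprintf("sp%02d", 1:8),
    population = rep(c("North", "South"), each = 4),
    sex = rep(c("male", "female"), 4),
    SVL = c(50.1, 52.3, 49.8, 51.0, 60.2, 61.5, 59.9, 62.0),
    V = c(230, 232, 231, 229, 231, 233, 230, 234),
    SLAB_L = c(8, 8, 9, 8, 8, 9, 8, 8),
    SLAB_R = c(8, 9, 9, 8, 8, 9, 9, 8),
    loreal = rep(c("2+3", "2"), each = 4),
    pattern = rep(c("blotched", "uniform"), each = 4))
  morphMatrix(dat,
              c(SVL = "metric", V = "meristic", SLAB_L = "meristic",
                SLAB_R = "meristic", loreal = "qualitative",
                pattern = "qualitative"),
              graded = "pattern")
}

writeDemoMorphCsv <- function(path = tempfile(fileext = ".csv")) {
  writeMorphMatrix(demoMorph(), path)
  path
}

# profile constructor for rank-assignment tests
mkProfile <- function(candidate, pops, comparison, mtdna, ndna, morph) {
  methods::new("EvidenceProfile", candidate = candidate, populations = pops,
               comparison = comparison, mtdna = mtdna, ndna = ndna,
               morphology = morph, designation = NA_character_,
               detail = list())
}
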