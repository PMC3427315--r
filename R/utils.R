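# Internal helpers: typed conditions, alignment character matrices and
# missing-data masks shared by the distance, haplotype and network code.

txStop <- function(class, ...) {
  stop(structure(class = c(class, "taxlines_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# Character matrix (uppercase) from a MarkerAlignment, samples in rows.
alnMatrix <- function(aln) {
  s <- toupper(as.character(aln@seqs))
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
              nrow = length(s), byrow = TRUE)
  rownames(m) <- names(aln@seqs)
  m
}

# TRUE where a character counts as missing data. Ambiguity codes and N are
# always missing; gaps ('-', '.') and '?' are missing unless gaps are treated
# as a fifth state, in which case '-' becomes an ordinary state.
missingMask <- function(m, gapAsState = FALSE) {
  miss <- c("N", "?", IUPAC_AMBIG, if (!gapAsState) c("-", "."))
  matrix(m %in% miss, nrow = nrow(m), dimnames = dimnames(m))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a reproducible sub-seed below 2^31 from a base seed and a stream id.
subSeed <- function(seed, stream) {
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483629
}

popOf <- function(metadata, ids) {
  md <- as.data.frame(metadata)
  md$population[match(ids, md$sample_id)]
}

fmtPct <- function(x) ifelse(is.na(x), NA_real_, round(x, 1))
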