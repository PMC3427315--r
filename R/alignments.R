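#' Construct a MarkerAlignment
#'
#' Low-level constructor used by [readAlignment()] and the simulator. Input is
#' case-insensitive; sequences are stored uppercase.
#'
#' @param marker marker label.
#' @param sequences named character vector (or [Biostrings::DNAStringSet]) of
#'   equal-length aligned sequences; names are sample IDs.
#' @param metadata data.frame (or DataFrame) with columns `sample_id`,
#'   `population` and optionally `voucher`, `sex`.
#' @param coding logical, protein-coding marker?
#' @param x a `MarkerAlignment` (accessors).
#' @return A [MarkerAlignment] object.
#' @examples
#' md <- data.frame(sample_id = c("a", "b"), population = c("P1", "P2"))
#' aln <- markerAlignment("demo", c(a = "ACGT", b = "ACGA"), md)
#' alignmentLength(aln)
#' @export
markerAlignment <- function(marker, sequences, metadata, coding = TRUE) {
  if (!methods::is(sequences, "DNAStringSet")) {
    seqs <- toupper(as.character(sequences))
    names(seqs) <- names(sequences)
    if (length(seqs) && length(unique(nchar(seqs))) > 1L)
      txStop("taxlines_alignment_error",
             "sequences are not aligned: unequal lengths (",
             paste(sort(unique(nchar(seqs))), collapse = ", "), ")")
    sequences <- Biostrings::DNAStringSet(seqs)
  }
  md <- S4Vectors::DataFrame(as.data.frame(metadata))
  for (col in c("voucher", "sex"))
    if (!col %in% colnames(md)) md[[col]] <- NA_character_
  obj <- methods::new("MarkerAlignment", marker = marker, seqs = sequences,
                      metadata = md, coding = coding)
  obj
}

#' Read a per-marker alignment with sample metadata
#'
#' Reads a relaxed-line-wrapping FASTA of pre-aligned sequences and a CSV
#' metadata table with header `sample_id,population,voucher,sex`, and checks
#' that every sequence resolves to exactly one population.
#'
#' @param fastaPath path to the aligned FASTA file.
#' @param metadataPath path to the metadata CSV.
#' @param marker marker label.
#' @param coding logical, protein-coding marker?
#' @return A [MarkerAlignment].
#' @seealso [collapseHaplotypes()], [distanceMatrix()]
#' @export
readAlignment <- function(fastaPath, metadataPath, marker, coding = TRUE) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fastaPath),
                   error = function(e)
                     txStop("taxlines_alignment_error",
                            "cannot parse FASTA '", fastaPath, "': ",
                            conditionMessage(e)))
  if (length(seqs) == 0L)
    txStop("taxlines_alignment_error", "empty FASTA: ", fastaPath)
  # FASTA descriptions may carry comments after the ID
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    txStop("taxlines_alignment_error",
           "records are not aligned: lengths ",
           paste(sort(unique(w)), collapse = ", "))
  md <- utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% colnames(md)))
    txStop("taxlines_metadata_error",
           "metadata must have columns 'sample_id' and 'population'")
  miss <- setdiff(names(seqs), md$sample_id)
  if (length(miss))
    txStop("taxlines_metadata_error",
           "no metadata row for sample(s): ", paste(miss, collapse = ", "))
  markerAlignment(marker, seqs, md[md$sample_id %in% names(seqs), ,
                                   drop = FALSE], coding = coding)
}

#' @rdname markerAlignment
#' @export
setMethod("alignmentLength", "MarkerAlignment",
          function(x) unique(Biostrings::width(x@seqs))[1L])

#' @rdname markerAlignment
#' @export
setMethod("sampleIDs", "MarkerAlignment", function(x) names(x@seqs))

#' @rdname markerAlignment
#' @export
setMethod("populations", "MarkerAlignment",
          function(x) popOf(x@metadata, names(x@seqs)))

#' @rdname markerAlignment
#' @export
setMethod("markerName", "MarkerAlignment", function(x) x@marker)

setMethod("show", "MarkerAlignment", function(object) {
  cat("MarkerAlignment '", object@marker, "': ", length(object@seqs),
      " samples x ", alignmentLength(object), " bp",
      if (object@coding) " (coding)" else "", "\n", sep = "")
  pops <- table(populations(object))
  cat("  populations:",
      paste(names(pops), "(", as.integer(pops), ")", sep = "", collapse = ", "),
      "\n")
})

# Can two sequences (character vectors) belong to one haplotype under the
# wildcard policy? Missing positions match anything.
.compatible <- function(a, b, missA, missB) {
  cmp <- !(missA | missB)
  all(a[cmp] == b[cmp])
}

#' Collapse an alignment into haplotypes
#'
#' Under the `strict` policy, sequences share a haplotype iff they are
#' identical character by character. Under `missing-as-wildcard` (the
#' default), missing data (`N`, IUPAC ambiguity codes, `?`, and gaps unless
#' `gapAsState = TRUE`) match any base, and sequences are merged greedily in
#' input order: each sequence joins the first existing haplotype it is
#' compatible with, otherwise founds a new one. Greedy merging is
#' order-dependent by design (the documented tie-break); the representative
#' sequence of a haplotype has its missing positions filled in from later
#' members where those resolve them.
#'
#' @param aln a [MarkerAlignment].
#' @param policy `"missing-as-wildcard"` (default) or `"strict"`.
#' @param gapAsState treat `-` as a fifth character state instead of missing?
#' @param x a `HaplotypeSet` (accessors).
#' @return A [HaplotypeSet] whose member sets partition the samples.
#' @examples
#' md <- data.frame(sample_id = c("a", "b", "c"),
#'                  population = c("P1", "P1", "P2"))
#' aln <- markerAlignment("demo", c(a = "ACNT", b = "ACGT", c = "ACGA"), md)
#' nHaplotypes(collapseHaplotypes(aln))              # wildcard: 2
#' nHaplotypes(collapseHaplotypes(aln, "strict"))    # strict: 3
#' @export
collapseHaplotypes <- function(aln,
                               policy = c("missing-as-wildcard", "strict"),
                               gapAsState = FALSE) {
  policy <- match.arg(policy)
  m <- alnMatrix(aln)
  miss <- missingMask(m, gapAsState = gapAsState)
  reps <- list(); repMiss <- list(); members <- list()
  for (i in seq_len(nrow(m))) {
    s <- m[i, ]; sm <- miss[i, ]
    hit <- 0L
    if (policy == "strict") {
      for (k in seq_along(reps))
        if (all(reps[[k]] == s)) { hit <- k; break }
    } else {
      for (k in seq_along(reps))
        if (.compatible(reps[[k]], s, repMiss[[k]], sm)) { hit <- k; break }
    }
    if (hit) {
      members[[hit]] <- c(members[[hit]], rownames(m)[i])
      if (policy != "strict") {
        fill <- repMiss[[hit]] & !sm
        reps[[hit]][fill] <- s[fill]
        repMiss[[hit]][fill] <- FALSE
      }
    } else {
      reps <- c(reps, list(s)); repMiss <- c(repMiss, list(sm))
      members <- c(members, list(rownames(m)[i]))
    }
  }
  methods::new("HaplotypeSet", marker = aln@marker,
               sequences = vapply(reps, paste, "", collapse = ""),
               members = members, policy = policy, gapAsState = gapAsState,
               metadata = aln@metadata)
}

#' @rdname collapseHaplotypes
#' @export
setMethod("nHaplotypes", "HaplotypeSet", function(x) length(x@sequences))

#' @rdname collapseHaplotypes
#' @export
setMethod("haplotypeMembers", "HaplotypeSet", function(x) x@members)

#' @rdname collapseHaplotypes
#' @export
setMethod("markerName", "HaplotypeSet", function(x) x@marker)

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet '", object@marker, "': ", nHaplotypes(object),
      " haplotypes from ", length(unlist(object@members)),
      " samples (policy: ", object@policy, ")\n", sep = "")
  sizes <- lengths(object@members)
  cat("  sizes:", paste(sort(sizes, decreasing = TRUE), collapse = ", "), "\n")
})

#' Count variable alignment columns
#'
#' Number of columns showing at least two distinct observed (non-missing)
#' character states. With default settings a single nucleotide substitution
#' segregating in the alignment yields a count of 1.
#'
#' @inheritParams collapseHaplotypes
#' @return Integer in `[0, alignmentLength(aln)]`.
#' @export
countVariableSites <- function(aln, gapAsState = FALSE) {
  m <- alnMatrix(aln)
  miss <- missingMask(m, gapAsState = gapAsState)
  m[miss] <- NA_character_
  sum(apply(m, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}
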