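# In-silico validation of a finished design: rebuild the target from the
# oligomer set and screen non-adjacent overlap pairs for shared repeats
# (mis-annealing risk). Verification is advisory: conflicts do not fail a
# design; only a reconstruction mismatch does (mirrored by the CLI exit
# codes).

#' Reconstruct the target sequence from an oligomer tiling
#'
#' Pure inverse of the tiling: concatenates the oligomers' reference extents
#' with each junction overlap counted once, checking at every junction that
#' the two oligomers spell the same bases over their shared region. Uses only
#' the oligomer table (coordinates, strands, sequences), not the stored
#' reference, so it genuinely validates the tiling.
#'
#' @param design an [AssemblyDesign-class].
#' @param ... unused.
#' @return The reconstructed top-strand sequence as a character string.
#' @examples
#' d <- designOligomers(randomSequence(250, seed = 5))
#' identical(reconstruct(d), as.character(referenceSeq(d)))
#' @rdname reconstruct
#' @export
setMethod("reconstruct", "AssemblyDesign", function(design, ...) {
  ol <- design@oligos
  n <- nrow(ol)
  slices <- ifelse(ol$strand == "top", ol$sequence,
                   vapply(ol$sequence, .revCompStr, character(1)))
  res <- slices[1L]
  end <- ol$end[1L]
  if (ol$start[1L] != 0L)
    stop("structural error: first oligomer does not start at the reference origin")
  for (i in seq_len(n)[-1L]) {
    s <- ol$start[i]
    if (s >= end || ol$end[i] <= end)
      stop("structural error at the junction between oligomers ", i - 1L,
           " and ", i, ": extents do not overlap consistently")
    ovLen <- end - s
    if (substr(res, s + 1L, end) != substr(slices[i], 1L, ovLen))
      stop("structural error at the junction between oligomers ", i - 1L,
           " and ", i, ": overlapping bases disagree")
    res <- paste0(res, substr(slices[i], ovLen + 1L, nchar(slices[i])))
    end <- ol$end[i]
  }
  res
})

#' Screen a design for mis-annealing-prone overlap pairs
#'
#' Reconstructs the target from the tiling and screens every non-adjacent
#' overlap pair for shared canonical k-mers (a k-mer and its reverse
#' complement count as the same key, so complementary-strand cross-talk is
#' caught). Adjacent pairs are excluded by definition: their sharing is the
#' designed junction.
#'
#' @param design an [AssemblyDesign-class].
#' @param k screening k-mer length (bp); defaults to the design's
#'   `repeatLenBetween`.
#' @param ... unused.
#' @return A [VerificationReport-class]; its conflict table is sorted by
#'   severity (shared bp) descending, then pair index.
#' @examples
#' d <- designOligomers(randomSequence(250, seed = 5))
#' crosscheck(d)
#' @rdname crosscheck
#' @export
setMethod("crosscheck", "AssemblyDesign", function(design, k = NULL, ...) {
  if (is.null(k)) k <- design@params@repeatLenBetween
  k <- .checkK(k)
  reconstructed <- reconstruct(design)
  conflicts <- .conflictTable(design@overlaps$sequence, k)
  new("VerificationReport",
      reconstructed = reconstructed,
      matchesReference = identical(reconstructed, design@reference),
      uniqueJunctions = nrow(conflicts) == 0L,
      conflicts = conflicts)
})
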