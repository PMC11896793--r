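# Deterministic synthetic-sequence generation: every module is testable
# without downloads. Base composition is drawn to hit the GC target exactly
# (up to rounding); motifs can be planted verbatim at fixed positions.

#' Deterministic random DNA sequence with a GC target and planted motifs
#'
#' Generates a reproducible random sequence whose base composition realizes
#' `gcTarget` exactly (to rounding): the G+C count is fixed at
#' `round(length * gcTarget / 100)` and bases are then permuted with the
#' seeded RNG. Optional motifs are written verbatim over the background at
#' the stated positions (which may shift the realized GC slightly). The
#' caller's RNG state is left untouched.
#'
#' @param length sequence length (nt), >= 1.
#' @param gcTarget target GC content in percent, strictly between 0 and 100.
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param planted named list: names are motifs, values are integer vectors of
#'   1-based start positions. Planted regions must fit and must not overlap
#'   one another.
#' @param id record identifier (FASTA name).
#' @return A [Biostrings::DNAStringSet] of length 1, named `id`.
#' @examples
#' randomSequence(60, gcTarget = 50, seed = 1)
#' randomSequence(120, seed = 7, planted = list(GGATCCGGATC = c(10, 90)))
#' @export
randomSequence <- function(length, gcTarget = 50, seed = 1L,
                           planted = list(),
                           id = sprintf("synth_s%d_n%d", seed, length)) {
  stopifnot(.isCount(length), length >= 1L)
  if (!(gcTarget > 0 && gcTarget < 100))
    stop("gcTarget must be strictly between 0 and 100")
  # validate plants before spending RNG draws
  occupied <- integer(0)
  for (motif in names(planted)) {
    .checkDNA(toupper(motif), "planted motif")
    for (at in planted[[motif]]) {
      span <- at:(at + nchar(motif) - 1L)
      if (at < 1L || max(span) > length)
        stop("planted motif does not fit at position ", at)
      if (any(span %in% occupied))
        stop("planted regions overlap at position ", at)
      occupied <- c(occupied, span)
    }
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  nGC <- round(length * gcTarget / 100)
  nG <- nGC %/% 2L; nC <- nGC - nG
  nAT <- length - nGC
  nA <- nAT %/% 2L; nT <- nAT - nA
  chars <- sample(c(rep("G", nG), rep("C", nC), rep("A", nA), rep("T", nT)))
  for (motif in names(planted)) {
    m <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    for (at in planted[[motif]])
      chars[at:(at + base::length(m) - 1L)] <- m
  }
  out <- DNAStringSet(paste(chars, collapse = ""))
  names(out) <- id
  out
}
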