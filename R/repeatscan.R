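# Repeat detection on canonical k-mers (a k-mer and its reverse complement
# are the same key, so complementary-strand self-annealing and cross-talk are
# caught) and greedy segregation of oligomers into sub-pool clusters.

# canonical k-mers of a sequence given its precomputed reverse complement
.canonicalKmerArray <- function(seq, rc, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  p <- seq_len(n - k + 1L)
  fw <- substring(seq, p, p + k - 1L)
  rv <- substring(rc, n - p - k + 2L, n - p + 1L)
  pmin(fw, rv)
}

.canonicalKmers <- function(seq, k) {
  .canonicalKmerArray(seq, .revCompStr(seq), k)
}

.checkK <- function(k) {
  if (!.isCount(k) || k < 2L) stop("repeat length k must be an integer >= 2")
  as.integer(k)
}

#' Base pairs covered by repeated k-mers within a sequence
#'
#' Counts the positions of `seq` covered by at least one k-mer whose
#' canonical key (k-mer identified with its reverse complement) occurs two or
#' more times within `seq` - a proxy for self-annealing risk that scales with
#' the length of the dangerous region.
#'
#' @param seq DNA string.
#' @param k repeat k-mer length (bp), >= 2.
#' @return Non-negative integer count of covered positions.
#' @examples
#' repeatsWithin("ACGTACGT", k = 4)    # 8: every position covered
#' repeatsWithin("AAAAATTTTT", k = 5)  # 10: AAAAA and TTTTT share one key
#' @export
repeatsWithin <- function(seq, k = 8L) {
  k <- .checkK(k)
  s <- .asSeqChar(seq)
  .checkDNA(s)
  keys <- .canonicalKmers(s, k)
  if (length(keys) < 2L) return(0L)
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  .coverCount(which(dup), k, nchar(s))
}

#' Base pairs one overlap shares with another at the repeat length
#'
#' Counts the positions of `overlapA` covered by a k-mer whose canonical key
#' also occurs in `overlapB`. Symmetric in the canonical-key sense, though
#' the position count is reported for the first argument.
#'
#' @param overlapA,overlapB DNA strings.
#' @param k repeat k-mer length (bp), >= 2.
#' @return Non-negative integer count of covered positions of `overlapA`.
#' @examples
#' sharedRepeatBp("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT", k = 10)
#' @export
sharedRepeatBp <- function(overlapA, overlapB, k = 10L) {
  k <- .checkK(k)
  a <- .asSeqChar(overlapA); b <- .asSeqChar(overlapB)
  .checkDNA(a, "overlapA"); .checkDNA(b, "overlapB")
  keysA <- .canonicalKmers(a, k)
  keysB <- .canonicalKmers(b, k)
  if (!length(keysA) || !length(keysB)) return(0L)
  .coverCount(which(keysA %in% keysB), k, nchar(a))
}

#' Segregate consecutive oligomers into repeat-free sub-pool clusters
#'
#' Greedy left-to-right segmentation of an ordered oligomer set, driven by
#' its junction overlaps: the current group is extended while no two
#' non-adjacent overlaps inside it share a canonical k-mer; at the first
#' violation a new group is opened at the left oligomer of the offending
#' overlap. Within every resulting group, no two non-adjacent overlaps share
#' a canonical k-mer, so oligomers of one group can be pooled without
#' cross-talk at the repeat length.
#'
#' @param overlapSeqs ordered character vector of junction overlap sequences
#'   (top strand); a design of `n` oligomers has `n - 1` overlaps.
#' @param k repeat k-mer length (bp), >= 2.
#' @param nOligomers number of oligomers; defaults to
#'   `length(overlapSeqs) + 1`.
#' @return Integer vector of cluster ids, one per oligomer, starting at 1;
#'   clusters are consecutive index ranges.
#' @examples
#' ov <- c("ACGTTGCAACGTGCAATGCA", "TTGACCTGAACGGTCATGGA", "ACGTTGCAACGTGCAATGCA")
#' segregateOverlaps(ov, k = 10)  # overlaps 1 and 3 collide -> split
#' @export
segregateOverlaps <- function(overlapSeqs, k = 10L, nOligomers = NULL) {
  k <- .checkK(k)
  m <- length(overlapSeqs)
  if (is.null(nOligomers)) nOligomers <- m + 1L
  if (nOligomers < m + 1L)
    stop("nOligomers must be at least length(overlapSeqs) + 1")
  cl <- rep(1L, nOligomers)
  if (m < 2L) return(cl)
  ksets <- lapply(overlapSeqs, function(s) {
    s <- .asSeqChar(s)
    unique(.canonicalKmers(s, k))
  })
  cur <- 1L
  a <- 1L  # first overlap index of the open group
  for (olig in 2:nOligomers) {
    j <- olig - 1L  # overlap entering the group (both of its oligomers now in)
    if (j >= 1L && j <= m && j - 2L >= a) {
      hit <- any(vapply(a:(j - 2L),
                        function(q) any(ksets[[j]] %in% ksets[[q]]),
                        logical(1)))
      if (hit) {
        cur <- cur + 1L
        a <- j
        cl[j] <- cur      # left oligomer of the offending overlap moves over
        cl[olig] <- cur
        next
      }
    }
    cl[olig] <- cur
  }
  cl
}

# conflict table over a set of overlap windows: non-adjacent pairs sharing
# canonical k-mers, with per-pair shared-bp severity (positions of the first
# overlap covered)
.conflictTable <- function(overlapSeqs, k) {
  m <- length(overlapSeqs)
  empty <- DataFrame(a = integer(0), b = integer(0),
                     kmers = character(0), sharedBp = integer(0))
  if (m < 3L) return(empty)
  ksets <- lapply(overlapSeqs, function(s) unique(.canonicalKmers(s, k)))
  rows <- list()
  for (p in seq_len(max(0L, m - 2L))) {
    for (q in seq(p + 2L, m)) {
      shared <- intersect(ksets[[p]], ksets[[q]])
      if (length(shared)) {
        rows[[length(rows) + 1L]] <- DataFrame(
          a = p, b = q,
          kmers = paste(shared, collapse = ","),
          sharedBp = sharedRepeatBp(overlapSeqs[p], overlapSeqs[q], k))
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$sharedBp, out$a, out$b), , drop = FALSE]
}
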