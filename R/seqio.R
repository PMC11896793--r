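# FASTA in, design CSV out (and back), plus the reverse-complement helper.
# Standard formats go through Biostrings; this layer adds strict A/C/G/T
# validation with positional error messages and the order-sheet CSV dialect.

#' Read and validate FASTA records
#'
#' Reads a (multi-record) FASTA file, uppercases the residues and rejects any
#' record containing a character outside A/C/G/T, naming the offending
#' position. Order of records is preserved.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' readFastaRecords(fa)
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- readDNAStringSet(path)
  if (!length(recs)) stop("no records in FASTA file: ", path)
  out <- DNAStringSet(toupper(as.character(recs)))
  for (i in seq_along(out))
    .checkDNA(as.character(out[[i]]),
              sprintf("record '%s'", names(recs)[i]))
  names(out) <- names(recs)
  out
}

#' Write FASTA records
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFastaRecords <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; an involution. Needed to emit
#' bottom-strand oligomers 5'->3'.
#'
#' @param seq DNA string(s) over A/C/G/T; vectorized.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplementStr("ATGCC")  # "GGCAT"
#' @export
reverseComplementStr <- function(seq) {
  if (is(seq, "DNAStringSet")) seq <- as.character(seq)
  vapply(seq, function(s) {
    s <- .asSeqChar(s)
    .checkDNA(s)
    .revCompStr(s)
  }, character(1), USE.NAMES = FALSE)
}

.CSV_COLUMNS <- c("index", "name", "strand", "ref_start", "ref_end", "length",
                  "sequence", "overlap_with_next", "overlap_tm", "overlap_gc",
                  "tm_dev", "three_prime_t", "gc_clamp", "r_within",
                  "r_between", "score", "cluster")

#' Export a design as an order-sheet CSV
#'
#' One row per oligomer, 5'->3' own-strand sequences, 1-based inclusive
#' reference coordinates, the top-strand sequence / Tm / GC of the overlap
#' with the next oligomer (empty for the last row), the five penalty
#' components with their total, and the sub-pool cluster id. Tm, GC and score
#' columns are rounded to 2 decimals. Round-trips through
#' [readDesignCsv()].
#'
#' @param design an [AssemblyDesign-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDesignCsv <- function(design, path) {
  stopifnot(is(design, "AssemblyDesign"))
  ol <- design@oligos; ov <- design@overlaps; sc <- design@scores
  n <- nrow(ol)
  nxt <- function(col, fill) c(ov[[col]], fill)[seq_len(n)]
  df <- data.frame(
    index = ol$index, name = ol$name, strand = ol$strand,
    ref_start = ol$start + 1L, ref_end = ol$end, length = ol$length,
    sequence = ol$sequence,
    overlap_with_next = if (n > 1L) c(ov$sequence, "") else "",
    overlap_tm = if (n > 1L) round(c(ov$tm, NA), 2) else NA,
    overlap_gc = if (n > 1L) round(c(ov$gc, NA), 2) else NA,
    tm_dev = round(sc$tmDev, 2), three_prime_t = sc$threePrimeT,
    gc_clamp = sc$gcClamp, r_within = sc$rWithin, r_between = sc$rBetween,
    score = round(sc$total, 2), cluster = design@clusters,
    stringsAsFactors = FALSE)
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write design CSV: ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a design back from an order-sheet CSV
#'
#' Rebuilds an [AssemblyDesign-class] from a CSV written by
#' [writeDesignCsv()]: coordinates are converted back to the internal
#' 0-based half-open convention, the reference is reconstructed from the
#' top-strand slices, and the assembly-wide conflict table is recomputed.
#'
#' @param path path to the CSV.
#' @param params the [DesignParams-class] to attach (defaults to package
#'   defaults); stored parameters are not serialized in the CSV.
#' @param refId reference identifier to attach; by default inferred from the
#'   oligomer names.
#' @return An [AssemblyDesign-class].
#' @export
readDesignCsv <- function(path, params = DesignParams(), refId = NULL) {
  if (!file.exists(path)) stop("design CSV not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(.CSV_COLUMNS %in% names(df)))
    stop("malformed design CSV: missing column(s) ",
         paste(setdiff(.CSV_COLUMNS, names(df)), collapse = ", "))
  n <- nrow(df)
  if (n < 1L) stop("malformed design CSV: no oligomer rows")
  if (is.null(refId)) {
    refId <- sub("_oligo_[0-9]+$", "", df$name[1L])
    if (!nzchar(refId) || refId == df$name[1L]) refId <- "design"
  }
  starts <- df$ref_start - 1L
  ends <- df$ref_end
  topSlices <- ifelse(df$strand == "top", df$sequence,
                      vapply(df$sequence, .revCompStr, character(1)))
  for (i in seq_len(n)) .checkDNA(toupper(topSlices[i]),
                                  sprintf("oligomer %d sequence", i))
  # reference from slices
  refChars <- character(max(ends))
  for (i in seq_len(n)) {
    sl <- strsplit(topSlices[i], "", fixed = TRUE)[[1L]]
    refChars[(starts[i] + 1L):ends[i]] <- sl
  }
  reference <- paste(refChars, collapse = "")
  oligos <- DataFrame(index = df$index, name = df$name, strand = df$strand,
                      start = starts, end = ends, length = df$length,
                      sequence = df$sequence)
  if (n > 1L) {
    ovIdx <- seq_len(n - 1L)
    overlaps <- DataFrame(index = ovIdx,
                          start = starts[ovIdx + 1L], end = ends[ovIdx],
                          length = ends[ovIdx] - starts[ovIdx + 1L],
                          sequence = df$overlap_with_next[ovIdx],
                          tm = df$overlap_tm[ovIdx],
                          gc = df$overlap_gc[ovIdx])
  } else {
    overlaps <- DataFrame(index = integer(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          sequence = character(0), tm = numeric(0),
                          gc = numeric(0))
  }
  scores <- DataFrame(tmDev = df$tm_dev, threePrimeT = df$three_prime_t,
                      gcClamp = df$gc_clamp, rWithin = df$r_within,
                      rBetween = df$r_between, total = df$score)
  conflicts <- .conflictTable(overlaps$sequence, params@repeatLenBetween)
  new("AssemblyDesign", refId = refId, reference = reference,
      params = params, oligos = oligos, overlaps = overlaps,
      scores = scores, clusters = as.integer(df$cluster),
      conflicts = conflicts)
}
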