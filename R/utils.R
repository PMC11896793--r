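# Internal sequence helpers. All public entry points validate their input
# with .checkDNA() so downstream arithmetic can assume a clean A/C/G/T string.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Coerce DNAString/DNAStringSet/character to a single uppercase character
# string, without validating the alphabet.
.asSeqChar <- function(x) {
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got ", length(x), " records")
    x <- x[[1L]]
  }
  if (is(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string or DNAString")
  toupper(x)
}

# Validate residues; names the first offending position.
.checkDNA <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L)
    stop(what, " contains non-ACGT residue '", substr(seq, bad, bad),
         "' at position ", bad)
  invisible(seq)
}

.revCompStr <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

.revStr <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Number of positions of a length-`len` sequence covered by k-mers starting
# at `idx` (1-based k-mer start offsets).
.coverCount <- function(idx, k, len) {
  if (!length(idx)) return(0L)
  cov <- logical(len)
  for (j in idx) cov[j:(j + k - 1L)] <- TRUE
  sum(cov)
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}
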