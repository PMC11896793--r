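# Nearest-neighbor duplex thermodynamics (unified SantaLucia parameter set),
# melting temperature, GC content, GC-clamp excess and the 3'-thymine
# indicator.

.GAS_CONSTANT <- 1.987  # cal/(mol*K)

#' Nearest-neighbor thermodynamic parameter table
#'
#' Loads the unified nearest-neighbor duplex parameters (SantaLucia) from the
#' plain-text table shipped with the package (or from a user-supplied TSV with
#' columns `key`, `dH`, `dS`). The ten unique dinucleotide stacks are expanded
#' to all sixteen dimers via reverse-complement equivalence; `init_GC` and
#' `init_AT` are the duplex initiation terms applied once per terminal base
#' pair.
#'
#' @param path optional path to a TSV parameter file; defaults to the table
#'   shipped in `inst/extdata`.
#' @return A list with named numeric vectors `dH` and `dS` (kcal/mol and
#'   cal/(mol K), one entry per dimer), and length-2 vectors `initGC`,
#'   `initAT` giving the (dH, dS) initiation terms.
#' @examples
#' tab <- nnParameterTable()
#' tab$dH[["AA"]]   # identical to tab$dH[["TT"]]
#' @export
nnParameterTable <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("nn", envir = .oligotiler_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "nn_santalucia_unified.tsv",
                        package = "oligotiler", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("key", "dH", "dS") %in% names(raw)))
  dimers <- raw[!startsWith(raw$key, "init"), ]
  dH <- structure(dimers$dH, names = dimers$key)
  dS <- structure(dimers$dS, names = dimers$key)
  # reverse-complement dimers share parameters
  rc <- vapply(names(dH), .revCompStr, character(1))
  missing <- setdiff(rc, names(dH))
  dH[missing] <- dH[names(dH)[match(missing, rc)]]
  dS[missing] <- dS[names(dS)[match(missing, rc)]]
  if (length(dH) != 16L)
    stop("nearest-neighbor table does not expand to 16 dimers")
  tab <- list(
    dH = dH, dS = dS,
    initGC = c(raw$dH[raw$key == "init_GC"], raw$dS[raw$key == "init_GC"]),
    initAT = c(raw$dH[raw$key == "init_AT"], raw$dS[raw$key == "init_AT"])
  )
  if (cache) assign("nn", tab, envir = .oligotiler_cache)
  tab
}

#' Duplex enthalpy and entropy by nearest-neighbor summation
#'
#' Sums the tabulated stacking terms over consecutive dimers of `seq` plus
#' one initiation term per terminal base pair.
#'
#' @param seq DNA string (character or `DNAString`), length >= 2.
#' @param table parameter table from [nnParameterTable()].
#' @return Named numeric vector `c(dH = , dS = )` in kcal/mol and
#'   cal/(mol K).
#' @examples
#' duplexEnthalpyEntropy("AA")  # two A.T initiations plus one AA/TT stack
#' @export
duplexEnthalpyEntropy <- function(seq, table = nnParameterTable()) {
  seq <- .asSeqChar(seq)
  .checkDNA(seq)
  n <- nchar(seq)
  if (n < 2L)
    stop("sequence must have length >= 2 (no stacked pair exists)")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  dimers <- paste0(chars[-n], chars[-1L])
  init <- function(base) if (base %in% c("G", "C")) table$initGC else table$initAT
  i1 <- init(chars[1L]); i2 <- init(chars[n])
  c(dH = i1[1L] + i2[1L] + sum(table$dH[dimers]),
    dS = i1[2L] + i2[2L] + sum(table$dS[dimers]))
}

#' Nearest-neighbor melting temperature
#'
#' Two-state duplex melting temperature with the classic monovalent-salt
#' correction:
#' `Tm = 1000 dH / (dS + R ln(C_T / x)) - 273.15 + 16.6 log10([Na+])`,
#' with `R = 1.987` cal/(mol K) and `x = 4` for non-self-complementary
#' duplexes (`x = 1` when `seq` equals its reverse complement).
#'
#' @param seq DNA string(s); vectorized.
#' @param oligoConc total strand concentration `C_T` (M).
#' @param naConc monovalent cation concentration (M).
#' @param table parameter table from [nnParameterTable()].
#' @return Melting temperature(s) in degrees C.
#' @examples
#' meltingTemp("ATGCAATGGCTACTGACTGA")
#' @export
meltingTemp <- function(seq, oligoConc = 2.5e-7, naConc = 0.05,
                        table = nnParameterTable()) {
  stopifnot(oligoConc > 0, naConc > 0)
  if (is(seq, "DNAStringSet")) seq <- as.character(seq)
  vapply(seq, function(s) {
    s <- .asSeqChar(s)
    hs <- duplexEnthalpyEntropy(s, table)
    x <- if (identical(s, .revCompStr(s))) 1 else 4
    1000 * hs[["dH"]] / (hs[["dS"]] + .GAS_CONSTANT * log(oligoConc / x)) -
      273.15 + 16.6 * log10(naConc)
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content in percent
#'
#' @param seq DNA string(s); vectorized.
#' @return `100 * (#G + #C) / length` for each input.
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(seq) {
  if (is(seq, "DNAStringSet")) seq <- as.character(seq)
  vapply(seq, function(s) {
    s <- .asSeqChar(s)
    .checkDNA(s)
    n <- nchar(s)
    if (n < 1L) stop("sequence must be non-empty")
    100 * (n - nchar(gsub("[GC]", "", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC-clamp excess of an overlap
#'
#' Counts G/C among the five 3'-terminal bases of an overlap (passed 5'->3'
#' in the orientation of the oligomer being scored) and returns the count
#' above the standard allowance of 3. A faultless overlap scores 0.
#'
#' @param overlapSeq overlap sequence, length >= 5.
#' @return Non-negative integer excess.
#' @examples
#' gcClampExcess("AAAAAGGCGC")  # 5 G/C in the last 5 -> excess 2
#' @export
gcClampExcess <- function(overlapSeq) {
  s <- .asSeqChar(overlapSeq)
  .checkDNA(s, "overlap")
  n <- nchar(s)
  if (n < 5L) stop("overlap must have length >= 5")
  tail5 <- substr(s, n - 4L, n)
  cnt <- 5L - nchar(gsub("[GC]", "", tail5))
  max(0L, cnt - 3L)
}

#' 3'-terminal thymine indicator
#'
#' Indicator that an oligomer (own-strand, 5'->3') ends in thymine; a
#' 3'-terminal T is penalized because it extends less faithfully.
#'
#' @param oligoSeq oligomer sequence, 5'->3' on its own strand.
#' @return `1L` if the final base is `T`, else `0L`.
#' @examples
#' threePrimeThymine("ACGT")  # 1
#' @export
threePrimeThymine <- function(oligoSeq) {
  s <- .asSeqChar(oligoSeq)
  .checkDNA(s, "oligomer")
  if (nchar(s) < 1L) stop("oligomer must be non-empty")
  as.integer(substr(s, nchar(s), nchar(s)) == "T")
}
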