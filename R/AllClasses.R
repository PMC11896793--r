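#' Design parameters for oligomer tiling
#'
#' Holds every user-tunable knob of the tiling designer: oligomer and overlap
#' length windows, the target overlap melting temperature and its tolerance,
#' overlap GC-content bounds, repeat-detection k-mer lengths, and the
#' hybridization conditions used by the nearest-neighbor Tm model.
#'
#' @slot maxOligoLen maximum oligomer length (nt).
#' @slot minOligoLen minimum oligomer length (nt); the final oligomer of a
#'   design may be shorter, but never shorter than `minOverlapLen + 5`.
#' @slot maxOverlapLen,minOverlapLen overlap length window (bp).
#' @slot targetTm target overlap melting temperature (degrees C).
#' @slot tmTolerance half-width of the acceptable Tm window (degrees C); used
#'   only to flag error-prone oligomers, never to reject candidates.
#' @slot gcLow,gcHigh preferred overlap GC-content bounds (percent).
#' @slot repeatLenBetween k-mer length (bp) for between-overlap repeat
#'   detection and cluster segregation.
#' @slot repeatLenWithin k-mer length (bp) for within-oligomer repeat
#'   detection.
#' @slot scoreEquiv penalty-equivalence margin (score units) of the greedy
#'   selection: candidates whose totals are within this margin of the best
#'   are treated as tied and the longer oligomer wins, keeping designs from
#'   fragmenting into needlessly many oligomers over score differences
#'   smaller than the Tm model's real accuracy. `0` recovers strict
#'   minimum-score selection.
#' @slot oligoConc total strand concentration (M) for the Tm model.
#' @slot naConc monovalent cation concentration (M) for the salt correction.
#' @seealso [DesignParams()] for the user constructor.
#' @exportClass DesignParams
setClass("DesignParams",
  representation(
    maxOligoLen = "integer", minOligoLen = "integer",
    maxOverlapLen = "integer", minOverlapLen = "integer",
    targetTm = "numeric", tmTolerance = "numeric",
    gcLow = "numeric", gcHigh = "numeric",
    repeatLenBetween = "integer", repeatLenWithin = "integer",
    scoreEquiv = "numeric", oligoConc = "numeric", naConc = "numeric"
  )
)

setValidity("DesignParams", function(object) {
  p <- object
  msg <- character(0)
  if (p@minOverlapLen < 5L)
    msg <- c(msg, "minOverlapLen must be >= 5")
  if (p@maxOverlapLen < p@minOverlapLen)
    msg <- c(msg, "maxOverlapLen must be >= minOverlapLen")
  if (p@maxOverlapLen >= p@maxOligoLen)
    msg <- c(msg, "maxOverlapLen must be < maxOligoLen")
  if (p@minOligoLen < p@minOverlapLen + 5L)
    msg <- c(msg, "minOligoLen must be >= minOverlapLen + 5")
  if (p@maxOligoLen < p@minOligoLen)
    msg <- c(msg, "maxOligoLen must be >= minOligoLen")
  if (!(p@gcLow < p@gcHigh))
    msg <- c(msg, "gcLow must be < gcHigh")
  if (!(p@tmTolerance > 0))
    msg <- c(msg, "tmTolerance must be > 0")
  if (p@repeatLenBetween < 2L || p@repeatLenWithin < 2L)
    msg <- c(msg, "repeat k-mer lengths must be >= 2")
  if (p@scoreEquiv < 0)
    msg <- c(msg, "scoreEquiv must be >= 0")
  if (!(p@oligoConc > 0) || !(p@naConc > 0))
    msg <- c(msg, "oligoConc and naConc must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignParams object
#'
#' @param maxOligoLen,minOligoLen oligomer length window (nt). By default
#'   `minOligoLen` is `max(30, minOverlapLen + 10)`.
#' @param maxOverlapLen,minOverlapLen overlap length window (bp).
#' @param targetTm target overlap melting temperature (degrees C).
#' @param tmTolerance half-width of the acceptable Tm window (degrees C).
#' @param gcLow,gcHigh preferred overlap GC-content bounds (percent).
#' @param repeatLenBetween,repeatLenWithin repeat-detection k-mer lengths (bp).
#' @param scoreEquiv penalty-equivalence margin (score units) of the greedy
#'   selection; near-ties are resolved toward the longer oligomer. The
#'   default of 3.5 is calibrated so that assembly-scale designs (hundreds of
#'   bp at typical genomic GC) reach the oligomer counts published for
#'   tools of this class; set to 0 for strict minimum-score selection.
#' @param oligoConc total strand concentration (M).
#' @param naConc monovalent salt concentration (M).
#' @return A validated [DesignParams-class] object.
#' @examples
#' DesignParams(maxOligoLen = 50, maxOverlapLen = 20, targetTm = 56)
#' @export
DesignParams <- function(maxOligoLen = 50L, minOligoLen = NULL,
                         maxOverlapLen = 20L, minOverlapLen = 15L,
                         targetTm = 56, tmTolerance = 2.5,
                         gcLow = 40, gcHigh = 60,
                         repeatLenBetween = 10L, repeatLenWithin = 8L,
                         scoreEquiv = 3.5, oligoConc = 2.5e-7, naConc = 0.05) {
  if (is.null(minOligoLen))
    minOligoLen <- max(30L, as.integer(minOverlapLen) + 10L)
  new("DesignParams",
      maxOligoLen = as.integer(maxOligoLen),
      minOligoLen = as.integer(minOligoLen),
      maxOverlapLen = as.integer(maxOverlapLen),
      minOverlapLen = as.integer(minOverlapLen),
      targetTm = as.numeric(targetTm),
      tmTolerance = as.numeric(tmTolerance),
      gcLow = as.numeric(gcLow), gcHigh = as.numeric(gcHigh),
      repeatLenBetween = as.integer(repeatLenBetween),
      repeatLenWithin = as.integer(repeatLenWithin),
      scoreEquiv = as.numeric(scoreEquiv),
      oligoConc = as.numeric(oligoConc), naConc = as.numeric(naConc))
}

setMethod("show", "DesignParams", function(object) {
  cat("DesignParams\n")
  cat(sprintf("  oligomer length : %d-%d nt\n",
              object@minOligoLen, object@maxOligoLen))
  cat(sprintf("  overlap length  : %d-%d bp\n",
              object@minOverlapLen, object@maxOverlapLen))
  cat(sprintf("  target Tm       : %.1f +/- %.1f C\n",
              object@targetTm, object@tmTolerance))
  cat(sprintf("  overlap GC      : %.0f-%.0f %%\n",
              object@gcLow, object@gcHigh))
  cat(sprintf("  repeat k-mers   : between %d bp, within %d bp\n",
              object@repeatLenBetween, object@repeatLenWithin))
  cat(sprintf("  score equiv.    : %.1f\n", object@scoreEquiv))
  cat(sprintf("  Tm conditions   : C_T = %.3g M, [Na+] = %.3g M\n",
              object@oligoConc, object@naConc))
})

#' Assembly design: an ordered, scored oligomer tiling
#'
#' The result of [designOligomers()]: the reference sequence, the parameters
#' used, the ordered oligomer and overlap tables, per-oligomer penalty scores,
#' the sub-pool cluster partition, and the assembly-wide table of
#' repeat-sharing overlap pairs.
#'
#' Coordinates in the `oligos` and `overlaps` tables are 0-based, half-open on
#' the top strand; sequences are each element's own-strand 5'->3' string
#' (bottom-strand oligomers are the reverse complement of their reference
#' slice). Use [writeDesignCsv()] to export 1-based inclusive order sheets.
#'
#' @slot refId identifier of the reference record.
#' @slot reference the reference (top-strand) sequence as a character string.
#' @slot params the [DesignParams-class] used.
#' @slot oligos `DataFrame` with columns `index`, `name`, `strand`
#'   (`"top"`/`"bottom"`), `start`, `end`, `length`, `sequence`.
#' @slot overlaps `DataFrame` (one row per junction, `n - 1` rows) with
#'   columns `index`, `start`, `end`, `length`, `sequence` (top strand),
#'   `tm`, `gc`.
#' @slot scores `DataFrame` with the five penalty components `tmDev`,
#'   `threePrimeT`, `gcClamp`, `rWithin`, `rBetween` and their sum `total`.
#' @slot clusters integer vector assigning each oligomer to a sub-pool
#'   cluster.
#' @slot conflicts `DataFrame` of non-adjacent overlap pairs sharing a
#'   canonical k-mer (`a`, `b`, `kmers`, `sharedBp`), computed assembly-wide.
#' @seealso [oligomers()], [overlaps()], [designScores()], [clusters()],
#'   [conflictPairs()], [reconstruct()], [crosscheck()], [reoptimize()].
#' @exportClass AssemblyDesign
setClass("AssemblyDesign",
  representation(
    refId = "character", reference = "character", params = "DesignParams",
    oligos = "DataFrame", overlaps = "DataFrame", scores = "DataFrame",
    clusters = "integer", conflicts = "DataFrame"
  )
)

setValidity("AssemblyDesign", function(object) {
  n <- nrow(object@oligos)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "design must contain at least one oligomer")
  if (nrow(object@overlaps) != max(0L, n - 1L))
    msg <- c(msg, "design must have exactly n - 1 overlaps")
  if (nrow(object@scores) != n)
    msg <- c(msg, "scores must have one row per oligomer")
  if (length(object@clusters) != n)
    msg <- c(msg, "clusters must assign every oligomer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblyDesign", function(object) {
  n <- nrow(object@oligos)
  cat(sprintf("AssemblyDesign of '%s' (%d nt)\n",
              object@refId, nchar(object@reference)))
  cat(sprintf("  %d oligomers (%d top / %d bottom), %d overlaps, %d cluster%s\n",
              n, sum(object@oligos$strand == "top"),
              sum(object@oligos$strand == "bottom"),
              nrow(object@overlaps), max(object@clusters),
              if (max(object@clusters) == 1L) "" else "s"))
  cat(sprintf("  penalty total : %.2f (per-oligomer mean %.2f, max %.2f)\n",
              sum(object@scores$total), mean(object@scores$total),
              max(object@scores$total)))
  if (nrow(object@overlaps))
    cat(sprintf("  overlap Tm    : %.1f-%.1f C (target %.1f), GC %.0f-%.0f %%\n",
                min(object@overlaps$tm), max(object@overlaps$tm),
                object@params@targetTm,
                min(object@overlaps$gc), max(object@overlaps$gc)))
  if (nrow(object@conflicts))
    cat(sprintf("  %d non-adjacent overlap pair(s) share %d bp repeats (see conflictPairs())\n",
                nrow(object@conflicts), object@params@repeatLenBetween))
})

#' Verification report for an assembly design
#'
#' Produced by [crosscheck()]: the sequence reconstructed from the oligomer
#' tiling, whether it matches the reference, whether every overlap is a
#' unique junction at the screening k-mer length, and the table of
#' mis-annealing-prone (repeat-sharing) overlap pairs sorted by severity.
#'
#' @slot reconstructed the reconstructed top-strand sequence.
#' @slot matchesReference `TRUE` if `reconstructed` equals the reference.
#' @slot uniqueJunctions `TRUE` if no non-adjacent overlap pair shares a
#'   canonical k-mer at the screening length.
#' @slot conflicts `DataFrame` (`a`, `b`, `kmers`, `sharedBp`) sorted by
#'   severity (shared bp) descending, then pair index.
#' @exportClass VerificationReport
setClass("VerificationReport",
  representation(
    reconstructed = "character", matchesReference = "logical",
    uniqueJunctions = "logical", conflicts = "DataFrame"
  )
)

setMethod("show", "VerificationReport", function(object) {
  cat("VerificationReport\n")
  cat(sprintf("  reconstructed length : %d nt\n", nchar(object@reconstructed)))
  cat(sprintf("  matches reference    : %s\n", object@matchesReference))
  cat(sprintf("  unique junctions     : %s\n", object@uniqueJunctions))
  if (nrow(object@conflicts)) {
    cat(sprintf("  %d repeat-sharing overlap pair(s):\n", nrow(object@conflicts)))
    df <- as.data.frame(object@conflicts)
    print(utils::head(df, 10L))
  } else {
    cat("  no repeat-sharing overlap pairs\n")
  }
})
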