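# Independent brute-force oracles, written before (and kept independent of)
# the implementation paths they check. Constants are re-typed here on
# purpose: the oracle must not share code with the package.

ORACLE_NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
ORACLE_NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
ORACLE_INIT_GC <- c(0.1, -2.8)
ORACLE_INIT_AT <- c(2.3, 4.1)

oracleRevComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# dimer-by-dimer exhaustive summation
oracleDuplexHS <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (end in c(ch[1], ch[n])) {
    init <- if (end %in% c("G", "C")) ORACLE_INIT_GC else ORACLE_INIT_AT
    dH <- dH + init[1]; dS <- dS + init[2]
  }
  for (i in seq_len(n - 1)) {
    d <- paste0(ch[i], ch[i + 1])
    dH <- dH + ORACLE_NN_DH[[d]]
    dS <- dS + ORACLE_NN_DS[[d]]
  }
  c(dH, dS)
}

oracleTm <- function(seq, ct = 2.5e-7, na = 0.05) {
  hs <- oracleDuplexHS(seq)
  x <- if (identical(seq, oracleRevComp(seq))) 1 else 4
  1000 * hs[1] / (hs[2] + 1.987 * log(ct / x)) - 273.15 + 16.6 * log10(na)
}

oracleKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
         character(1))
}

# O(n^2) substring comparison: positions covered by a k-mer seen (directly or
# as a reverse complement) elsewhere in the same sequence
oracleRepeatsWithin <- function(seq, k) {
  km <- oracleKmers(seq, k)
  m <- length(km)
  if (m < 2) return(0L)
  cov <- logical(nchar(seq))
  for (i in seq_len(m)) {
    rci <- oracleRevComp(km[i])
    hit <- FALSE
    for (j in seq_len(m)) {
      if (j == i) next
      if (km[j] == km[i] || km[j] == rci) { hit <- TRUE; break }
    }
    if (hit) cov[i:(i + k - 1)] <- TRUE
  }
  sum(cov)
}

oracleSharedBp <- function(a, b, k) {
  kmA <- oracleKmers(a, k)
  kmB <- oracleKmers(b, k)
  if (!length(kmA) || !length(kmB)) return(0L)
  cov <- logical(nchar(a))
  for (i in seq_along(kmA)) {
    rci <- oracleRevComp(kmA[i])
    if (any(kmB == kmA[i]) || any(kmB == rci))
      cov[i:(i + k - 1)] <- TRUE
  }
  sum(cov)
}

# plain random sequence for oracle-agreement loops (independent of the
# fixtures module)
oracleRandSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hand-built tiling -> AssemblyDesign, for tests that need full control over
# overlap content. Scores are filled with zeros; only structure matters.
makeTilingDesign <- function(ref, starts, ends,
                             params = DesignParams()) {
  n <- length(starts)
  strand <- ifelse(seq_len(n) %% 2 == 1, "top", "bottom")
  topSlices <- substring(ref, starts + 1, ends)
  seqs <- ifelse(strand == "top", topSlices,
                 vapply(topSlices, oracleRevComp, character(1)))
  ovStart <- starts[-1]; ovEnd <- ends[-n]
  ovSeq <- substring(ref, ovStart + 1, ovEnd)
  oligos <- S4Vectors::DataFrame(
    index = seq_len(n), name = sprintf("t_oligo_%02d", seq_len(n)),
    strand = strand, start = starts, end = ends,
    length = ends - starts, sequence = unname(seqs))
  overlaps <- S4Vectors::DataFrame(
    index = seq_len(n - 1), start = ovStart, end = ovEnd,
    length = ovEnd - ovStart, sequence = ovSeq,
    tm = meltingTemp(ovSeq, params@oligoConc, params@naConc),
    gc = gcContent(ovSeq))
  zeros <- rep(0L, n)
  scores <- S4Vectors::DataFrame(
    tmDev = rep(0, n), threePrimeT = zeros, gcClamp = zeros,
    rWithin = zeros, rBetween = zeros, total = rep(0, n))
  new("AssemblyDesign", refId = "handmade", reference = ref, params = params,
      oligos = oligos, overlaps = overlaps, scores = scores,
      clusters = segregateOverlaps(ovSeq, params@repeatLenBetween, n),
      conflicts = S4Vectors::DataFrame(a = integer(0), b = integer(0),
                                       kmers = character(0),
                                       sharedBp = integer(0)))
}

# structural checks every produced design must satisfy
expectTilingInvariants <- function(d, refLen = nchar(d@reference)) {
  ol <- oligomers(d)
  n <- nrow(ol)
  expect_identical(ol$start[1], 0L)
  expect_identical(ol$end[n], as.integer(refLen))
  expect_identical(ol$strand, ifelse(seq_len(n) %% 2 == 1, "top", "bottom"))
  if (n > 1) {
    ov <- overlaps(d)
    expect_identical(ov$start, ol$start[-1])
    expect_identical(ov$end, ol$end[-n])
    expect_true(all(ov$length >= 1))
    expect_true(all(ol$start[-1] > ol$start[-n]))  # strictly advancing
    expect_true(all(ol$end[-1] > ol$end[-n]))
  }
  sc <- designScores(d)
  expect_equal(sc$total,
               sc$tmDev + sc$threePrimeT + sc$gcClamp + sc$rWithin +
                 sc$rBetween)
  invisible(d)
}
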