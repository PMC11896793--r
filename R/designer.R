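# The tiling designer: enumerate candidate (oligomer length, next-overlap
# length) splits at each cursor, score each candidate with the five-component
# penalty, and grow the alternating-strand tiling greedily. Odd ordinals are
# top-strand, even ordinals bottom-strand; coordinates are 0-based half-open
# on the top strand throughout.

# ---- per-reference precomputation ------------------------------------------
# Cumulative dimer dH/dS and GC arrays make every window's Tm / GC an O(1)
# lookup; canonical k-mer arrays make repeat checks a slice + membership test.
.pcEnv <- function(ref, params, table = nnParameterTable()) {
  N <- nchar(ref)
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  rc <- .revCompStr(ref)
  isGC <- chars == "G" | chars == "C"
  gcCum <- c(0L, cumsum(isGC))
  if (N >= 2L) {
    dimers <- paste0(chars[-N], chars[-1L])
    dHc <- c(0, cumsum(unname(table$dH[dimers])))
    dSc <- c(0, cumsum(unname(table$dS[dimers])))
  } else {
    dHc <- dSc <- 0
  }
  list(ref = ref, rc = rc, N = N, chars = chars,
       gcCum = gcCum, dHc = dHc, dSc = dSc,
       initH = ifelse(isGC, table$initGC[1L], table$initAT[1L]),
       initS = ifelse(isGC, table$initGC[2L], table$initAT[2L]),
       canB = .canonicalKmerArray(ref, rc, params@repeatLenBetween),
       canW = .canonicalKmerArray(ref, rc, params@repeatLenWithin))
}

# Tm of reference windows [a0, b0) (0-based half-open; vectorized)
.tmWindows <- function(pc, a0, b0, oligoConc, naConc) {
  a <- a0 + 1L; b <- b0
  dH <- pc$initH[a] + pc$initH[b] + (pc$dHc[b] - pc$dHc[a])
  dS <- pc$initS[a] + pc$initS[b] + (pc$dSc[b] - pc$dSc[a])
  div <- rep(4, length(a))
  even <- (b0 - a0) %% 2L == 0L
  if (any(even)) {
    fw <- substring(pc$ref, a[even], b[even])
    rv <- substring(pc$rc, pc$N - b[even] + 1L, pc$N - a[even] + 1L)
    div[even][fw == rv] <- 1
  }
  1000 * dH / (dS + .GAS_CONSTANT * log(oligoConc / div)) - 273.15 +
    16.6 * log10(naConc)
}

.gcCountWin <- function(pc, p1, p2) pc$gcCum[p2 + 1L] - pc$gcCum[p1]  # 1-based incl.

# GC-clamp excess of overlap window [a0, b0), oriented in the strand of the
# oligomer being scored: top -> 3'-terminal 5 bases are the window's last 5;
# bottom -> the reverse complement's last 5 are the window's first 5.
.gcClampWin <- function(pc, a0, b0, top) {
  cnt <- if (top) .gcCountWin(pc, b0 - 4L, b0)
         else .gcCountWin(pc, a0 + 1L, a0 + 5L)
  max(0L, cnt - 3L)
}

# within-oligomer repeat bp for window [a0, a0+L)
.rWithinWin <- function(pc, a0, L, k) {
  if (L < k) return(0L)
  keys <- pc$canW[(a0 + 1L):(a0 + L - k + 1L)]
  if (length(keys) < 2L) return(0L)
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  .coverCount(which(dup), k, L)
}

# between-overlap repeat bp of window [a0, b0) against a context key set
.rBetweenWin <- function(pc, a0, b0, k, ctx) {
  len <- b0 - a0
  if (len < k || !length(ctx)) return(0L)
  keys <- pc$canB[(a0 + 1L):(b0 - k + 1L)]
  .coverCount(which(keys %in% ctx), k, len)
}

# Reachability of a remainder r (bases left from the next cursor to the end):
# r is finishable if a final oligomer fits (minOverlapLen + 5 <= r <=
# maxOligoLen) or some admissible stride d = L - V leads to a finishable
# remainder. Used as the terminal-feasibility guard; it is what lets the
# greedy "shorten the penultimate step" instead of stranding a tail shorter
# than the smallest legal final oligomer.
.canFinish <- function(N, params) {
  f <- logical(N)
  lo <- params@minOverlapLen + 5L
  hi <- params@maxOligoLen
  f[lo:min(hi, N)] <- TRUE
  if (N > hi) {
    dmin <- max(1L, params@minOligoLen - params@maxOverlapLen)
    dmax <- params@maxOligoLen - params@minOverlapLen
    strides <- dmin:dmax
    for (r in (hi + 1L):N) {
      prev <- r - strides
      f[r] <- any(f[prev[prev >= 1L]])
    }
  }
  f
}

# ---- candidate enumeration --------------------------------------------------
# All candidates at a cursor: the full (L, V) grid of continuing splits plus
# the terminal candidate when the remainder is itself a legal final oligomer.
# `prevEnd` is the 0-based exclusive end of the previous oligomer (NA for the
# first); the preceding overlap is [cursor, prevEnd). `ctx` is the canonical
# k-mer set of committed non-adjacent overlaps. `feasible` is the
# reachability vector from .canFinish() (NULL to skip the guard).
.candidateTable <- function(pc, params, cursor, top, prevEnd, ctx,
                            feasible = NULL) {
  N <- pc$N
  Tt <- params@targetTm
  kB <- params@repeatLenBetween
  kW <- params@repeatLenWithin
  rows <- list()

  remainder <- N - cursor
  minFinal <- params@minOverlapLen + 5L
  if (remainder <= params@maxOligoLen &&
      (remainder >= minFinal || is.na(prevEnd))) {
    L <- remainder
    if (is.na(prevEnd)) {            # single-oligomer design: no overlap at all
      tmDev <- 0; clamp <- 0L
    } else {
      ovTm <- .tmWindows(pc, cursor, prevEnd, params@oligoConc, params@naConc)
      tmDev <- abs(Tt - ovTm)
      clamp <- .gcClampWin(pc, cursor, prevEnd, top)
    }
    t3 <- if (top) as.integer(pc$chars[N] == "T")
          else as.integer(pc$chars[cursor + 1L] == "A")
    rW <- .rWithinWin(pc, cursor, L, kW)
    rows[["terminal"]] <- data.frame(
      start = cursor, end = N, len = L, terminal = TRUE,
      ovStart = NA_integer_, ovEnd = NA_integer_, ovLen = NA_integer_,
      ovTm = NA_real_, ovGC = NA_real_,
      tmDev = tmDev, threePrimeT = t3, gcClamp = as.integer(clamp),
      rWithin = rW, rBetween = 0L)
  }

  maxL <- min(params@maxOligoLen, N - cursor - 1L)
  if (maxL >= params@minOligoLen) {
    Ls <- params@minOligoLen:maxL
    if (!is.na(prevEnd)) Ls <- Ls[cursor + Ls > prevEnd]
    grid <- do.call(rbind, lapply(Ls, function(L) {
      Vhi <- min(params@maxOverlapLen, L - 1L)
      if (Vhi < params@minOverlapLen) return(NULL)
      data.frame(L = L, V = params@minOverlapLen:Vhi)
    }))
    if (!is.null(grid) && nrow(grid)) {
      b0 <- cursor + grid$L
      a0 <- b0 - grid$V
      keep <- rep(TRUE, nrow(grid))
      if (!is.null(feasible)) keep <- feasible[N - a0]
      if (any(keep)) {
        grid <- grid[keep, , drop = FALSE]
        a0 <- a0[keep]; b0 <- b0[keep]
        ovTm <- .tmWindows(pc, a0, b0, params@oligoConc, params@naConc)
        ovGC <- 100 * (.gcCountWin(pc, a0 + 1L, b0)) / grid$V
        t3 <- if (top) as.integer(pc$chars[b0] == "T")
              else rep(as.integer(pc$chars[cursor + 1L] == "A"), length(b0))
        clamp <- if (top) pmax(0L, .gcCountWin(pc, b0 - 4L, b0) - 3L)
                 else pmax(0L, .gcCountWin(pc, a0 + 1L, a0 + 5L) - 3L)
        rWByL <- vapply(unique(grid$L),
                        function(L) .rWithinWin(pc, cursor, L, kW), integer(1))
        rW <- rWByL[match(grid$L, unique(grid$L))]
        rB <- vapply(seq_along(a0), function(i)
          .rBetweenWin(pc, a0[i], b0[i], kB, ctx), integer(1))
        rows[["grid"]] <- data.frame(
          start = cursor, end = b0, len = grid$L, terminal = FALSE,
          ovStart = a0, ovEnd = b0, ovLen = grid$V,
          ovTm = ovTm, ovGC = ovGC,
          tmDev = abs(Tt - ovTm), threePrimeT = t3, gcClamp = clamp,
          rWithin = rW, rBetween = rB)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0), len = integer(0),
                      terminal = logical(0), ovStart = integer(0),
                      ovEnd = integer(0), ovLen = integer(0),
                      ovTm = numeric(0), ovGC = numeric(0), tmDev = numeric(0),
                      threePrimeT = integer(0), gcClamp = integer(0),
                      rWithin = integer(0), rBetween = integer(0),
                      total = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$total <- out$tmDev + out$threePrimeT + out$gcClamp + out$rWithin +
    out$rBetween
  out
}

# Greedy selection: GC-in-window candidates are preferred over out-of-window
# ones (next-best-fit rule: never empty-handed); candidates within the
# scoreEquiv margin of the best total count as tied and the longer oligomer
# wins, then lower total, then Tm closer to target, then smaller overlap
# start. With scoreEquiv = 0 this is strict minimum-total selection.
.pickBest <- function(cand, params) {
  pref <- cand$terminal |
    (cand$ovGC >= params@gcLow & cand$ovGC <= params@gcHigh)
  pool <- if (any(pref)) cand[pref, , drop = FALSE] else cand
  near <- pool$total <= min(pool$total) + params@scoreEquiv
  pool <- pool[near, , drop = FALSE]
  ovs <- ifelse(is.na(pool$ovStart), .Machine$integer.max, pool$ovStart)
  pool[order(-pool$len, pool$total, pool$tmDev, ovs)[1L], , drop = FALSE]
}

#' Enumerate scored candidate splits at a cursor
#'
#' Returns the exhaustive grid of candidate oligomers starting at `cursor`:
#' one row per admissible (oligomer length, next-overlap length) pair, plus a
#' terminal candidate (no next overlap) when the remainder itself is a legal
#' final oligomer. Every row carries the five penalty components and their
#' total. The terminal-feasibility guard used by [designOligomers()] is *not*
#' applied here; the grid is purely geometric.
#'
#' @param reference reference sequence (character, `DNAString`, or
#'   `DNAStringSet` of length 1).
#' @param cursor 0-based start position of the candidate oligomer.
#' @param params a [DesignParams-class].
#' @param prevOverlapEnd 0-based exclusive end of the previous oligomer (the
#'   preceding overlap is `[cursor, prevOverlapEnd)`); `NA` for the first
#'   oligomer.
#' @param strand `"top"` or `"bottom"`: the strand of the candidate oligomer.
#' @param contextOverlaps character vector of committed non-adjacent overlap
#'   sequences used for the between-overlap repeat component.
#' @return A `data.frame` with columns `start`, `end`, `len`, `terminal`,
#'   `ovStart`, `ovEnd`, `ovLen`, `ovTm`, `ovGC`, `tmDev`, `threePrimeT`,
#'   `gcClamp`, `rWithin`, `rBetween`, `total`.
#' @examples
#' ref <- randomSequence(200, seed = 1)
#' p <- DesignParams(maxOligoLen = 50, minOligoLen = 40,
#'                   maxOverlapLen = 20, minOverlapLen = 15)
#' nrow(enumerateCandidates(ref, 0, p))  # 11 lengths x 6 overlaps = 66
#' @export
enumerateCandidates <- function(reference, cursor, params = DesignParams(),
                                prevOverlapEnd = NA, strand = c("top", "bottom"),
                                contextOverlaps = character()) {
  strand <- match.arg(strand)
  ref <- .asSeqChar(reference)
  .checkDNA(ref, "reference")
  if (cursor < 0L || cursor >= nchar(ref))
    stop("cursor beyond reference (cursor = ", cursor, ")")
  pc <- .pcEnv(ref, params)
  ctx <- unique(unlist(lapply(contextOverlaps, function(s)
    .canonicalKmers(.asSeqChar(s), params@repeatLenBetween))))
  if (is.null(ctx)) ctx <- character(0)
  .candidateTable(pc, params, as.integer(cursor), strand == "top",
                  if (is.na(prevOverlapEnd)) NA_integer_
                  else as.integer(prevOverlapEnd),
                  ctx, feasible = NULL)
}

# ---- the engine -------------------------------------------------------------
# `fixed`: optional committed prefix (from reoptimize): list(starts, ends,
# ovStarts, ovEnds) of oligomers/overlaps 1..i0-1 with the cursor implied by
# overlap i0-1's start.
.designEngine <- function(ref, params, fixed = NULL) {
  N <- nchar(ref)
  pc <- .pcEnv(ref, params)
  feasible <- .canFinish(N, params)
  starts <- integer(0); ends <- integer(0)
  ovStarts <- integer(0); ovEnds <- integer(0)
  ctxKeys <- list()  # canonical k-mer sets of committed overlaps
  if (!is.null(fixed)) {
    starts <- fixed$starts; ends <- fixed$ends
    ovStarts <- fixed$ovStarts; ovEnds <- fixed$ovEnds
    ctxKeys <- lapply(seq_along(ovStarts), function(j) {
      lo <- ovStarts[j] + 1L
      hi <- ovEnds[j] - params@repeatLenBetween + 1L
      if (hi < lo) character(0) else unique(pc$canB[lo:hi])
    })
    cursor <- ovStarts[length(ovStarts)]
    prevEnd <- ends[length(ends)]
    i <- length(starts) + 1L
  } else {
    cursor <- 0L; prevEnd <- NA_integer_; i <- 1L
  }
  repeat {
    ctx <- unique(unlist(ctxKeys[seq_len(max(0L, i - 2L))]))
    if (is.null(ctx)) ctx <- character(0)
    cand <- .candidateTable(pc, params, cursor, top = (i %% 2L) == 1L,
                            prevEnd, ctx, feasible)
    if (!nrow(cand))
      stop("design error: no admissible candidate at cursor ", cursor)
    best <- .pickBest(cand, params)
    starts[i] <- cursor; ends[i] <- best$end
    if (best$terminal) break
    ovStarts[i] <- best$ovStart; ovEnds[i] <- best$ovEnd
    lo <- best$ovStart + 1L
    hi <- best$ovEnd - params@repeatLenBetween + 1L
    ctxKeys[[i]] <- if (hi < lo) character(0) else unique(pc$canB[lo:hi])
    cursor <- best$ovStart
    prevEnd <- best$end
    i <- i + 1L
  }
  list(pc = pc, starts = starts, ends = ends,
       ovStarts = ovStarts, ovEnds = ovEnds)
}

# score the final tiling: overlaps get Tm/GC; every oligomer gets the
# five-component breakdown with rBetween scoped to its final cluster
.finalizeDesign <- function(refId, engine, params) {
  pc <- engine$pc
  starts <- engine$starts; ends <- engine$ends
  ovStarts <- engine$ovStarts; ovEnds <- engine$ovEnds
  n <- length(starts)
  m <- length(ovStarts)
  kB <- params@repeatLenBetween
  strand <- ifelse(seq_len(n) %% 2L == 1L, "top", "bottom")
  topSlices <- substring(pc$ref, starts + 1L, ends)
  seqs <- ifelse(strand == "top", topSlices,
                 vapply(topSlices, .revCompStr, character(1)))
  oligos <- DataFrame(
    index = seq_len(n),
    name = sprintf("%s_oligo_%02d", refId, seq_len(n)),
    strand = strand, start = starts, end = ends,
    length = ends - starts, sequence = unname(seqs))
  if (m) {
    ovSeqs <- substring(pc$ref, ovStarts + 1L, ovEnds)
    overlaps <- DataFrame(
      index = seq_len(m), start = ovStarts, end = ovEnds,
      length = ovEnds - ovStarts, sequence = ovSeqs,
      tm = .tmWindows(pc, ovStarts, ovEnds, params@oligoConc, params@naConc),
      gc = 100 * .gcCountWin(pc, ovStarts + 1L, ovEnds) / (ovEnds - ovStarts))
  } else {
    overlaps <- DataFrame(index = integer(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          sequence = character(0), tm = numeric(0),
                          gc = numeric(0))
  }
  cl <- segregateOverlaps(overlaps$sequence, kB, nOligomers = n)
  conflicts <- .conflictTable(overlaps$sequence, kB)
  ovKeys <- lapply(seq_len(m), function(j) {
    lo <- ovStarts[j] + 1L
    hi <- ovEnds[j] - kB + 1L
    if (hi < lo) character(0) else unique(pc$canB[lo:hi])
  })
  inCluster <- function(j, c) cl[j] == c && cl[j + 1L] == c  # overlap j fully in cluster c
  scoreRow <- function(i) {
    top <- strand[i] == "top"
    ovIdx <- if (m == 0L) NA_integer_ else if (i < n) i else n - 1L
    if (is.na(ovIdx)) {
      tmDev <- 0; clamp <- 0L
    } else {
      tmDev <- abs(params@targetTm - overlaps$tm[ovIdx])
      clamp <- .gcClampWin(pc, ovStarts[ovIdx], ovEnds[ovIdx], top)
    }
    t3 <- threePrimeThymine(seqs[i])
    rW <- .rWithinWin(pc, starts[i], ends[i] - starts[i],
                      params@repeatLenWithin)
    rB <- 0L
    for (p in intersect(c(i - 1L, i), seq_len(m))) {
      if (!inCluster(p, cl[i])) next
      for (q in seq_len(m)) {
        if (abs(q - p) < 2L || !inCluster(q, cl[i])) next
        if (any(ovKeys[[p]] %in% ovKeys[[q]]))
          rB <- rB + .coverCount(
            which(pc$canB[(ovStarts[p] + 1L):(ovEnds[p] - kB + 1L)] %in%
                    ovKeys[[q]]), kB, ovEnds[p] - ovStarts[p])
      }
    }
    c(tmDev, t3, clamp, rW, rB)
  }
  sc <- vapply(seq_len(n), scoreRow, numeric(5))
  scores <- DataFrame(tmDev = sc[1L, ], threePrimeT = as.integer(sc[2L, ]),
                      gcClamp = as.integer(sc[3L, ]),
                      rWithin = as.integer(sc[4L, ]),
                      rBetween = as.integer(sc[5L, ]))
  scores$total <- scores$tmDev + scores$threePrimeT + scores$gcClamp +
    scores$rWithin + scores$rBetween
  new("AssemblyDesign", refId = refId, reference = pc$ref, params = params,
      oligos = oligos, overlaps = overlaps, scores = scores,
      clusters = cl, conflicts = conflicts)
}

#' Design an alternating-strand oligomer tiling
#'
#' The core operation: tiles the reference left-to-right with
#' alternating-strand, overlapping oligomers. At each cursor the full grid of
#' admissible (oligomer length, overlap length) candidates is scored with the
#' five-component penalty and the minimum-score candidate is taken, with ties
#' broken by longer oligomer, then overlap Tm closer to the target, then
#' smaller overlap start. Candidates whose overlap GC content falls inside
#' the preferred window are chosen ahead of out-of-window ones; when no
#' candidate is ideal the next-best fit is still returned rather than
#' failing. A reachability guard rejects candidates that would strand a final
#' remainder shorter than the smallest legal final oligomer. After tiling,
#' oligomers are segregated into sub-pool clusters and re-scored with the
#' between-overlap repeat component scoped to their final cluster.
#'
#' @param reference the target sequence (character, `DNAString`, or a
#'   `DNAStringSet` whose first record is used).
#' @param params a [DesignParams-class].
#' @param id reference identifier; defaults to the record name or `"seq"`.
#' @return An [AssemblyDesign-class].
#' @examples
#' ref <- randomSequence(300, gcTarget = 50, seed = 1)
#' d <- designOligomers(ref)
#' d
#' oligomers(d)
#' @export
designOligomers <- function(reference, params = DesignParams(), id = NULL) {
  if (is.null(id)) {
    id <- if (is(reference, "DNAStringSet") && !is.null(names(reference)))
      sub("\\s.*$", "", names(reference)[1L]) else "seq"
  }
  if (is(reference, "DNAStringSet")) reference <- reference[1L]
  ref <- .asSeqChar(reference)
  .checkDNA(ref, "reference")
  validObject(params)
  if (nchar(ref) < params@minOligoLen)
    stop("reference (", nchar(ref), " nt) is shorter than minOligoLen (",
         params@minOligoLen, ")")
  engine <- .designEngine(ref, params)
  .finalizeDesign(id, engine, params)
}

#' Score one oligomer with the five-component penalty
#'
#' Evaluates the penalty `tmDev + threePrimeT + gcClamp + rWithin + rBetween`
#' for a single oligomer: the absolute deviation of its annealing overlap's
#' Tm from the target, the 3'-terminal thymine indicator on its own strand,
#' the GC-clamp excess of the overlap (pass the overlap 5'->3' in the
#' oligomer's own orientation), the base pairs covered by internal repeats,
#' and the base pairs its overlap shares with the other overlaps of its
#' cluster. A theoretically faultless oligomer scores exactly 0.
#'
#' @param oligoSeq oligomer sequence, 5'->3' on its own strand.
#' @param overlapSeq the oligomer's scoring (annealing) overlap, oriented in
#'   the oligomer's own strand; `NULL` for a single-oligomer design (Tm and
#'   clamp components are then 0).
#' @param params a [DesignParams-class] (supplies the target Tm, k-mer
#'   lengths and Tm conditions).
#' @param contextOverlaps other overlap sequences of the oligomer's cluster.
#' @return A one-row `DataFrame` with `tmDev`, `threePrimeT`, `gcClamp`,
#'   `rWithin`, `rBetween`, `total`.
#' @examples
#' p <- DesignParams(targetTm = 56)
#' scoreOligomer("ATGGCTAGCTAAGGTCCGATCGATTGCAGCTAGCTAAGG",
#'               "TTGCAGCTAGCTAAGG", p)
#' @export
scoreOligomer <- function(oligoSeq, overlapSeq = NULL,
                          params = DesignParams(),
                          contextOverlaps = character()) {
  oligoSeq <- .asSeqChar(oligoSeq)
  .checkDNA(oligoSeq, "oligomer")
  if (!is.null(overlapSeq)) {
    overlapSeq <- .asSeqChar(overlapSeq)
    .checkDNA(overlapSeq, "overlap")
    tmDev <- abs(params@targetTm -
                   meltingTemp(overlapSeq, params@oligoConc, params@naConc))
    clamp <- gcClampExcess(overlapSeq)
    rB <- sum(vapply(contextOverlaps, function(o)
      sharedRepeatBp(overlapSeq, o, params@repeatLenBetween), integer(1)))
  } else {
    tmDev <- 0; clamp <- 0L; rB <- 0L
  }
  t3 <- threePrimeThymine(oligoSeq)
  rW <- repeatsWithin(oligoSeq, params@repeatLenWithin)
  DataFrame(tmDev = tmDev, threePrimeT = t3, gcClamp = clamp,
            rWithin = rW, rBetween = as.integer(rB),
            total = tmDev + t3 + clamp + rW + rB)
}

#' Re-design a tiling from a chosen oligomer onward
#'
#' The programmatic counterpart of a manual optimizer: oligomers
#' `1..index-1` (and their junction overlaps) are kept byte-identical, and
#' the tiling from `index` to the end is re-designed with optionally
#' overridden length / Tm parameters. Scores and clusters are recomputed for
#' the whole design; the input object is not modified. With no overrides the
#' operation is idempotent.
#'
#' @param design an [AssemblyDesign-class].
#' @param index 1-based ordinal of the first oligomer to re-design.
#' @param overrides named list of parameter overrides; only `maxOligoLen`,
#'   `minOligoLen`, `maxOverlapLen`, `minOverlapLen`, `targetTm` and
#'   `tmTolerance` may be overridden.
#' @param ... unused.
#' @return A new [AssemblyDesign-class].
#' @examples
#' d <- designOligomers(randomSequence(400, seed = 3))
#' d2 <- reoptimize(d, 3, list(maxOverlapLen = 25))
#' @rdname reoptimize
#' @export
setMethod("reoptimize", "AssemblyDesign",
  function(design, index, overrides = list(), ...) {
    n <- nrow(design@oligos)
    if (!.isCount(index) || index < 1L || index > n)
      stop("index must be an oligomer ordinal in 1..", n)
    allowed <- c("maxOligoLen", "minOligoLen", "maxOverlapLen",
                 "minOverlapLen", "targetTm", "tmTolerance")
    bad <- setdiff(names(overrides), allowed)
    if (length(bad) || (length(overrides) && is.null(names(overrides))))
      stop("overrides may only touch: ", paste(allowed, collapse = ", "))
    params <- design@params
    for (nm in names(overrides)) {
      value <- overrides[[nm]]
      slot(params, nm) <- if (nm %in% c("targetTm", "tmTolerance"))
        as.numeric(value) else as.integer(value)
    }
    validObject(params)
    if (index == 1L) {
      engine <- .designEngine(design@reference, params)
    } else {
      fixed <- list(starts = design@oligos$start[seq_len(index - 1L)],
                    ends = design@oligos$end[seq_len(index - 1L)],
                    ovStarts = design@overlaps$start[seq_len(index - 1L)],
                    ovEnds = design@overlaps$end[seq_len(index - 1L)])
      engine <- .designEngine(design@reference, params, fixed = fixed)
    }
    .finalizeDesign(design@refId, engine, params)
  })
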