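narrowParams <- function(...) {
  DesignParams(maxOligoLen = 50, minOligoLen = 40,
               maxOverlapLen = 20, minOverlapLen = 15, ...)
}

test_that("candidate enumeration is exhaustive over the parameter grid", {
  ref <- randomSequence(200, seed = 1)
  cand <- enumerateCandidates(ref, 0, narrowParams())
  expect_identical(nrow(cand), 11L * 6L)   # 11 lengths x 6 overlap lengths
  expect_false(any(cand$terminal))
  expect_true(all(is.finite(cand$total)))
  expect_true(all(cand$ovLen < cand$len))
  expect_true(all(cand$ovEnd == cand$end))

  # near the end only terminal candidates remain
  tailCand <- enumerateCandidates(ref, 155, narrowParams(),
                                  prevOverlapEnd = 170)
  expect_true(any(tailCand$terminal))
  expect_true(all(is.na(tailCand$ovStart[tailCand$terminal])))
  expect_error(enumerateCandidates(ref, 500, narrowParams()), "cursor beyond")
})

test_that("a 60 nt reference under a narrow grid yields exactly 2 oligomers", {
  d <- designOligomers(randomSequence(60, seed = 2), narrowParams())
  expect_identical(nrow(oligomers(d)), 2L)
  expectTilingInvariants(d)
  expect_identical(reconstruct(d), d@reference)
})

test_that("designs satisfy the tiling invariants and are deterministic", {
  for (s in c(3, 4, 5)) {
    ref <- randomSequence(100 * s, gcTarget = 35 + 10 * s, seed = s)
    d1 <- designOligomers(ref)
    d2 <- designOligomers(ref)
    expectTilingInvariants(d1)
    expect_identical(oligomers(d1), oligomers(d2))
    expect_identical(designScores(d1), designScores(d2))
    ov <- overlaps(d1)
    p <- designParams(d1)
    expect_true(all(ov$length >= p@minOverlapLen &
                      ov$length <= p@maxOverlapLen))
    ol <- oligomers(d1)
    n <- nrow(ol)
    expect_true(all(ol$length[-n] >= p@minOligoLen))
    expect_true(all(ol$length <= p@maxOligoLen))
    expect_gte(ol$length[n], p@minOverlapLen + 5L)
  }
})

test_that("a reference shorter than the minimum oligomer length is rejected", {
  expect_error(designOligomers(randomSequence(20, seed = 1)), "shorter than")
})

test_that("a short reference collapses to a single-oligomer design", {
  d <- designOligomers(randomSequence(45, seed = 6))
  expect_identical(nrow(oligomers(d)), 1L)
  expect_identical(nrow(overlaps(d)), 0L)
  expect_identical(designScores(d)$tmDev, 0)
  expect_identical(reconstruct(d), d@reference)
})

test_that("overlap Tm and GC stored in designs match the public calculators", {
  d <- designOligomers(randomSequence(350, seed = 7))
  ov <- overlaps(d)
  p <- designParams(d)
  expect_equal(ov$tm, meltingTemp(ov$sequence, p@oligoConc, p@naConc),
               tolerance = 1e-12)
  expect_equal(ov$gc, gcContent(ov$sequence), tolerance = 1e-12)
})

test_that("the penalty equation substitutes component-wise", {
  # overlap Tm 2 C below target plus a 3'-terminal T -> total exactly 3
  overlap <- "ATGGCATTACGATCAA"    # 2 G/C in terminal 5, no clamp excess
  oligo <- paste0("GATTACCAGT", overlap, "GAGGATCCAT")
  oligo <- paste0(substr(oligo, 1, nchar(oligo) - 1), "T")
  p <- DesignParams(targetTm = meltingTemp(overlap) + 2)
  sc <- scoreOligomer(oligo, overlap, p)
  expect_equal(sc$tmDev, 2)
  expect_identical(sc$threePrimeT, 1L)
  expect_identical(sc$gcClamp, 0L)
  expect_equal(sc$total, 3)
})

test_that("a faultless oligomer scores exactly zero", {
  ref <- randomSequence(300, seed = 8)
  d <- designOligomers(ref)
  sc <- designScores(d)
  ok <- which(sc$threePrimeT == 0 & sc$gcClamp == 0 & sc$rWithin == 0 &
                sc$rBetween == 0)
  ok <- ok[ok < nrow(oligomers(d))]
  expect_gt(length(ok), 0)
  i <- ok[1]
  ov <- overlaps(d)
  p0 <- designParams(d)
  p <- DesignParams(targetTm = ov$tm[i],
                    oligoConc = p0@oligoConc, naConc = p0@naConc)
  ovOriented <- if (oligomers(d)$strand[i] == "top") ov$sequence[i]
                else oracleRevComp(ov$sequence[i])
  sc0 <- scoreOligomer(oligomers(d)$sequence[i], ovOriented, p)
  expect_identical(sc0$total, 0)
})

test_that("an oligomer with a duplicated 8-mer is penalized by covered positions", {
  eightmer <- "GGATCCGA"
  oligo <- as.character(randomSequence(
    50, seed = 9, planted = setNames(list(c(5, 40)), eightmer))[[1]])
  rw <- repeatsWithin(oligo, 8)
  expect_gte(rw, 16L)
  expect_identical(rw, oracleRepeatsWithin(oligo, 8))
  sc <- scoreOligomer(oligo, NULL, DesignParams())
  expect_identical(sc$rWithin, rw)
})

test_that("stored design scores match independent re-scoring of each oligomer", {
  d <- designOligomers(randomSequence(400, gcTarget = 45, seed = 10))
  ol <- oligomers(d); ov <- overlaps(d); sc <- designScores(d)
  cl <- clusters(d)
  n <- nrow(ol)
  p <- designParams(d)
  for (i in seq_len(n)) {
    ovIdx <- if (i < n) i else n - 1L
    oriented <- if (ol$strand[i] == "top") ov$sequence[ovIdx]
                else oracleRevComp(ov$sequence[ovIdx])
    # context: the oligomer's flanking overlaps' non-adjacent cluster mates
    ctx <- character(0)
    for (pIdx in intersect(c(i - 1L, i), seq_len(n - 1L))) {
      if (!(cl[pIdx] == cl[i] && cl[pIdx + 1L] == cl[i])) next
      for (q in seq_len(n - 1L)) {
        if (abs(q - pIdx) < 2 || !(cl[q] == cl[i] && cl[q + 1L] == cl[i])) next
        ctx <- c(ctx, ov$sequence[q])
      }
    }
    indep <- scoreOligomer(ol$sequence[i], oriented, p, ctx)
    expect_equal(sc$tmDev[i], indep$tmDev, tolerance = 1e-9)
    expect_identical(sc$threePrimeT[i], indep$threePrimeT)
    expect_identical(sc$rWithin[i], indep$rWithin)
    expect_identical(sc$rBetween[i], indep$rBetween)
  }
})

test_that("the first greedy choice matches a brute-force reimplementation of the policy", {
  ref <- randomSequence(120, seed = 14)
  p <- narrowParams()
  refStr <- as.character(ref[[1]])
  rows <- list()
  for (L in p@minOligoLen:p@maxOligoLen) {
    if (L >= nchar(refStr)) next
    for (V in p@minOverlapLen:min(p@maxOverlapLen, L - 1)) {
      ovSeq <- substr(refStr, L - V + 1, L)
      sc <- scoreOligomer(substr(refStr, 1, L), ovSeq, p)
      rows[[length(rows) + 1]] <- data.frame(
        L = L, V = V, total = sc$total, tmDev = sc$tmDev,
        gc = gcContent(ovSeq))
    }
  }
  grid <- do.call(rbind, rows)
  pool <- grid[grid$gc >= p@gcLow & grid$gc <= p@gcHigh, ]
  if (!nrow(pool)) pool <- grid
  pool <- pool[pool$total <= min(pool$total) + p@scoreEquiv, ]
  pool <- pool[order(-pool$L, pool$total, pool$tmDev, pool$L - pool$V), ]
  d <- designOligomers(ref, p)
  expect_identical(oligomers(d)$length[1], as.integer(pool$L[1]))
  expect_identical(overlaps(d)$length[1], as.integer(pool$V[1]))
})

test_that("widening parameter windows never raises the minimum candidate score", {
  ref <- randomSequence(400, seed = 15)
  narrow <- narrowParams()
  wideV <- DesignParams(maxOligoLen = 50, minOligoLen = 40,
                        maxOverlapLen = 25, minOverlapLen = 15)
  wideL <- DesignParams(maxOligoLen = 60, minOligoLen = 35,
                        maxOverlapLen = 20, minOverlapLen = 15)
  for (cursor in c(0, 57, 213)) {
    mn <- min(enumerateCandidates(ref, cursor, narrow)$total)
    expect_lte(min(enumerateCandidates(ref, cursor, wideV)$total), mn)
    expect_lte(min(enumerateCandidates(ref, cursor, wideL)$total), mn)
  }
  # tmTolerance is a flag threshold only: scores are unchanged
  relaxed <- narrowParams(tmTolerance = 10)
  expect_equal(enumerateCandidates(ref, 0, relaxed)$total,
               enumerateCandidates(ref, 0, narrow)$total)
})

test_that("reoptimize is idempotent, local, and validates its inputs", {
  d <- designOligomers(randomSequence(500, seed = 16))
  n <- nrow(oligomers(d))

  same <- reoptimize(d, 3)
  expect_identical(oligomers(same), oligomers(d))
  expect_identical(designScores(same)$total, designScores(d)$total)

  # locality: prefix untouched, junction overlap preserved
  d2 <- reoptimize(d, 4, list(maxOverlapLen = 25))
  expect_identical(oligomers(d2)[1:3, ], oligomers(d)[1:3, ])
  expect_identical(overlaps(d2)[1:3, c("start", "end")],
                   overlaps(d)[1:3, c("start", "end")])
  expectTilingInvariants(d2)
  expect_identical(reconstruct(d2), d@reference)

  # last-oligomer reoptimization with unchanged params changes nothing
  dLast <- reoptimize(d, n)
  expect_identical(oligomers(dLast), oligomers(d))

  expect_error(reoptimize(d, 0), "ordinal")
  expect_error(reoptimize(d, n + 1), "ordinal")
  expect_error(reoptimize(d, 2, list(gcLow = 10)), "overrides")
  expect_error(reoptimize(d, 2, list(maxOverlapLen = 60)), "maxOligoLen")
})

test_that("widening the overlap window at a junction cannot worsen its per-step score", {
  d <- designOligomers(randomSequence(500, gcTarget = 40, seed = 17))
  sc <- designScores(d)
  j <- which.max(sc$tmDev[-nrow(oligomers(d))])  # highest-deviation junction
  cursor <- oligomers(d)$start[j]
  p <- designParams(d)
  wide <- DesignParams(maxOligoLen = p@maxOligoLen, minOligoLen = p@minOligoLen,
                       maxOverlapLen = p@maxOverlapLen + 10,
                       minOverlapLen = p@minOverlapLen,
                       targetTm = p@targetTm, scoreEquiv = p@scoreEquiv)
  prevEnd <- if (j > 1) oligomers(d)$end[j - 1] else NA
  strand <- oligomers(d)$strand[j]
  mnOld <- min(enumerateCandidates(d@reference, cursor, p,
                                   prevOverlapEnd = prevEnd, strand = strand)$total)
  mnNew <- min(enumerateCandidates(d@reference, cursor, wide,
                                   prevOverlapEnd = prevEnd, strand = strand)$total)
  expect_lte(mnNew, mnOld)
})
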