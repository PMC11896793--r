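test_that("within-sequence repeat coverage matches hand-derived cases", {
  expect_identical(repeatsWithin("ACGTACGT", k = 4), 8L)
  expect_identical(repeatsWithin("AAAAATTTTT", k = 5), 10L)   # rc-aware key
  expect_identical(repeatsWithin("ACGT", k = 8), 0L)          # shorter than k
  expect_error(repeatsWithin("ACGTACGT", k = 1), ">= 2")
})

test_that("shared-overlap repeat coverage matches hand-derived cases", {
  a <- "ACGTTGCAACGTGCAATGCA"
  expect_identical(sharedRepeatBp(a, a, k = 10), 20L)
  motif <- "GGATCCGGATC"  # 11 bp -> two 10-mers, 11 covered positions
  left <- as.character(randomSequence(50, seed = 601,
                                      planted = setNames(list(10), motif))[[1]])
  right <- as.character(randomSequence(50, seed = 602,
                                       planted = setNames(list(30), motif))[[1]])
  expect_identical(sharedRepeatBp(left, right, k = 10), 11L)
  # reverse-complement sharing counts
  expect_identical(sharedRepeatBp(left, oracleRevComp(right), k = 10), 11L)
  expect_error(sharedRepeatBp(a, a, k = 0), ">= 2")
})

test_that("repeat counts agree with the exhaustive O(n^2) oracle", {
  for (s in 1:60) {
    k <- sample(c(4, 6, 8, 10), 1)
    seq <- oracleRandSeq(sample(20:100, 1), seed = 400 + s)
    expect_identical(repeatsWithin(seq, k), oracleRepeatsWithin(seq, k))
  }
  for (s in 1:60) {
    k <- sample(c(6, 8, 10), 1)
    a <- oracleRandSeq(sample(15:60, 1), seed = 500 + s)
    b <- oracleRandSeq(sample(15:60, 1), seed = 700 + s)
    expect_identical(sharedRepeatBp(a, b, k), oracleSharedBp(a, b, k))
  }
})

test_that("segregation groups consecutively and splits at the first violation", {
  distinct <- vapply(1:5, function(s)
    as.character(randomSequence(20, seed = 800 + s)[[1]]), character(1))
  expect_identical(segregateOverlaps(distinct, k = 10), rep(1L, 6))
  expect_identical(segregateOverlaps(character(0), k = 10), 1L)

  # overlaps 1 and 3 share a planted 10-mer -> boundary before oligomer 3
  motif <- "GGATCCGGAT"
  ov <- distinct[1:3]
  ov[1] <- paste0(motif, substr(ov[1], 11, 20))
  ov[3] <- paste0(substr(ov[3], 1, 10), motif)
  cl <- segregateOverlaps(ov, k = 10)
  expect_identical(cl, c(1L, 1L, 2L, 2L))
})

test_that("after segregation no non-adjacent overlap pair within a group shares a k-mer", {
  for (s in 1:10) {
    # plant the same motif several times to force conflicts
    motif <- "CCGGTTAACCGG"
    ref <- randomSequence(700, gcTarget = 45, seed = 900 + s,
                          planted = setNames(list(c(60, 320, 580)), motif))
    d <- designOligomers(ref)
    cl <- clusters(d)
    ov <- overlaps(d)$sequence
    for (p in seq_along(ov)) {
      for (q in seq_along(ov)) {
        if (q - p < 2) next
        sameGroup <- cl[p] == cl[p + 1] && cl[q] == cl[q + 1] &&
          cl[p] == cl[q]
        if (sameGroup)
          expect_identical(sharedRepeatBp(ov[p], ov[q],
                                          designParams(d)@repeatLenBetween), 0L)
      }
    }
  }
})

test_that("segregation never splits without a conflict against the open group", {
  # a split implies the left overlap of the new group conflicts with some
  # earlier overlap of the previous group
  motif <- "GGATCCGGAT"
  base <- vapply(1:6, function(s)
    as.character(randomSequence(20, seed = 820 + s)[[1]]), character(1))
  ov <- base
  ov[2] <- paste0(motif, substr(ov[2], 11, 20))
  ov[5] <- paste0(substr(ov[5], 1, 10), motif)
  cl <- segregateOverlaps(ov, k = 10)
  expect_identical(cl, c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
})
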