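mk_matrix <- function(scores, counts, origin = 0L) {
  sc <- matrix(0, 4, length(scores), dimnames = list(c("A","C","G","T"), NULL))
  cn <- matrix(0L, 4, length(scores), dimnames = list(c("A","C","G","T"), NULL))
  for (i in seq_along(scores)) {
    sc[names(scores[[i]]), i] <- scores[[i]]
    cn[names(counts[[i]]), i] <- counts[[i]]
  }
  new("ScoreMatrix", origin = as.integer(origin), scores = sc, counts = cn)
}

test_that("buildScoreMatrix sums squared qualities and counts per base", {
  ov <- data.frame(
    readId = c("a", "b"), orientedSeq = c("A", "A"), offset = c(5L, 5L),
    overhang = c(1L, 1L), quality = c(3L, 2L), stringsAsFactors = FALSE
  )
  sm <- buildScoreMatrix(ov, 5L)
  expect_equal(matrixOrigin(sm), 5L)
  expect_equal(unname(voteScores(sm)["A", 1]), 13) # 3^2 + 2^2
  expect_equal(unname(voteCounts(sm)["A", 1]), 2L)

  ov <- data.frame(readId = "a", orientedSeq = "G", offset = 0L,
                   overhang = 1L, quality = 4L, stringsAsFactors = FALSE)
  sm <- buildScoreMatrix(ov, 0L)
  expect_equal(voteScores(sm)[, 1], c(A = 0, C = 0, G = 16, T = 0))

  empty <- buildScoreMatrix(ov[0, ], 10L)
  expect_equal(ncol(voteScores(empty)), 0L)
})

test_that("buildScoreMatrix matches the brute-force double loop", {
  for (s in 1:5) {
    ov <- random_overlaps(20L, 50L, seed = s)
    sm <- buildScoreMatrix(ov, 50L)
    lens <- nchar(ov$orientedSeq)
    lo <- min(ov$offset)
    hi <- max(ov$offset + lens - 1L)
    want <- oracle_score_matrix(ov, lo, hi)
    expect_equal(matrixOrigin(sm), lo)
    expect_equal(unname(voteScores(sm)), unname(want$Q))
    expect_equal(unname(voteCounts(sm)), unname(want$C))
  }
})

test_that("extensionThreshold evaluates 10^-t * l^2 * c", {
  expect_equal(extensionThreshold(toleranceConfig(0, 1L, 1)), 1)
  expect_equal(extensionThreshold(toleranceConfig(2.5, 100L, 10)),
               316.227766, tolerance = 1e-8)
  t1 <- extensionThreshold(toleranceConfig(1.5, 80L, 4))
  t2 <- extensionThreshold(toleranceConfig(1.5, 80L, 8))
  expect_equal(t2, 2 * t1)
})

test_that("callConsensus applies threshold, truncation and ambiguity rules", {
  cfg <- toleranceConfig(2.5, 100L, 10, minBranchSupport = 2L) # thr 316.2

  # argmax above threshold, second best far below: clean call
  cc <- callConsensus(
    mk_matrix(list(c(A = 400, C = 10)), list(c(A = 3L, C = 1L))), 0L, cfg
  )
  expect_equal(consensusSequence(cc), "A")
  expect_length(ambiguousPositions(cc), 0L)

  # below threshold: undefined, extension truncated
  cc <- callConsensus(mk_matrix(list(c(A = 200)), list(c(A = 2L))), 0L, cfg)
  expect_equal(extendedBases(cc), 0L)

  # both best and second-best above threshold with enough support: ambiguous
  cc <- callConsensus(
    mk_matrix(list(c(A = 900, G = 625)), list(c(A = 3L, G = 2L))), 0L, cfg
  )
  expect_equal(consensusSequence(cc), "A")
  expect_equal(ambiguousPositions(cc), 1L)

  # same scores but second-best support below minBranchSupport: not ambiguous
  cc <- callConsensus(
    mk_matrix(list(c(A = 900, G = 625)), list(c(A = 3L, G = 1L))), 0L, cfg
  )
  expect_length(ambiguousPositions(cc), 0L)

  # truncation stops at the first undefined column even if later ones pass
  cc <- callConsensus(
    mk_matrix(
      list(c(A = 500), c(C = 100), c(G = 800)),
      list(c(A = 3L), c(C = 1L), c(G = 3L))
    ), 0L, cfg
  )
  expect_equal(consensusSequence(cc), "A")

  # argmax ties break in A<C<G<T order
  cc <- callConsensus(
    mk_matrix(list(c(C = 400, G = 400)), list(c(C = 2L, G = 2L))), 0L,
    toleranceConfig(2.5, 100L, 10, minBranchSupport = 5L)
  )
  expect_equal(consensusSequence(cc), "C")

  # in-contig columns (coordinates before contigEnd) are never re-called
  cc <- callConsensus(
    mk_matrix(list(c(T = 900), c(A = 900)), list(c(T = 3L), c(A = 3L))),
    1L, cfg
  )
  expect_equal(consensusSequence(cc), "A")
})

test_that("score matrix + caller equal the brute-force pipeline on fixtures", {
  for (s in 1:8) {
    W <- 40L
    ov <- random_overlaps(30L, W, seed = 100 + s)
    cfg <- toleranceConfig(
      tolerance = sample(c(1.5, 2.5, 3.5), 1), readLength = 60L,
      coverageEstimate = sample(1:5, 1), minBranchSupport = 2L
    )
    sm <- buildScoreMatrix(ov, W)
    got <- callConsensus(sm, W, cfg)
    lens <- nchar(ov$orientedSeq)
    lo <- min(ov$offset)
    hi <- max(ov$offset + lens - 1L)
    orc <- oracle_score_matrix(ov, lo, hi)
    want <- oracle_consensus(orc$Q, orc$C, lo, W,
                             extensionThreshold(cfg), 2L)
    expect_equal(consensusSequence(got), want$sequence)
    expect_equal(ambiguousPositions(got), as.integer(want$ambiguous))
  }
})

test_that("raising the tolerance never shortens the called extension", {
  for (s in 1:4) {
    ov <- random_overlaps(25L, 40L, seed = 200 + s)
    sm <- buildScoreMatrix(ov, 40L)
    lens <- vapply(c(1, 2, 3, 4), function(t) {
      extendedBases(callConsensus(sm, 40L, toleranceConfig(t, 60L, 2)))
    }, integer(1))
    expect_true(all(diff(lens) >= 0))
  }
})

test_that("enumerateGenotypes counts, ranks, filters and caps genotypes", {
  cfg <- toleranceConfig(minBranchSupport = 2L, maxAlternates = 2L)
  mkov <- function(seqs) {
    data.frame(
      readId = paste0("r", seq_along(seqs)), orientedSeq = seqs,
      offset = 0L, overhang = 1L, quality = 10L, stringsAsFactors = FALSE
    )
  }
  # 6 covering reads: 4 vote AT, 2 vote GC at positions 1 and 3
  ov <- mkov(c("ACTG", "ACTG", "ATTG", "ATTG", "GCCG", "GCCG"))
  gt <- enumerateGenotypes(ov, c(0L, 2L), cfg)
  expect_equal(gt$bases, c("AT", "GC"))
  expect_equal(gt$support, c(4L, 2L))

  # single unanimous genotype
  gt <- enumerateGenotypes(mkov(rep("AAA", 5)), 1L, cfg)
  expect_equal(gt$bases, "A")
  expect_equal(gt$support, 5L)

  # support below the threshold is dropped
  ov <- mkov(c("A", "A", "A", "G"))
  gt <- enumerateGenotypes(ov, 0L, cfg)
  expect_equal(gt$bases, "A")

  # reads not covering every listed position do not contribute
  ov <- mkov(c("AAAA", "AAAA", "AA", "AA"))
  gt <- enumerateGenotypes(ov, c(0L, 3L), cfg)
  expect_equal(gt$support, 2L)

  # no read covers all positions -> empty
  gt <- enumerateGenotypes(mkov(c("AA", "AA")), c(0L, 5L), cfg)
  expect_equal(nrow(gt), 0L)

  # at most 1 + maxAlternates genotypes, ranked by support then bases
  ov <- mkov(c(rep("A", 5), rep("C", 4), rep("G", 3), rep("T", 2)))
  gt <- enumerateGenotypes(ov, 0L, cfg)
  expect_equal(gt$bases, c("A", "C", "G"))
})

test_that("applyGenotype rewrites exactly the ambiguous positions", {
  cc <- new("ConsensusCall", sequence = "AACAG", extendedBases = 5L,
            ambiguousPositions = c(2L, 4L))
  expect_equal(applyGenotype(cc, "TT"), "ATCTG")
  expect_equal(applyGenotype(cc, "AA"), "AACAG") # main genotype: unchanged
  two <- c(applyGenotype(cc, "TA"), applyGenotype(cc, "TG"))
  expect_equal(substr(two[1], 2, 2), "T")
  expect_equal(substr(two[2], 4, 4), "G")
  expect_error(applyGenotype(cc, "TTT"), "length")
})
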