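# Driver behaviour: stepping, branching, cycle/circular detection, budgets.

test_that("extendStep grows a clean single-strain terminus by one consensus", {
  fx <- sim_fixture(genomeLength = 2000L, depth = 10, errorRate = 0, rng = 2L)
  idx <- buildReadIndex(fx$reads)
  seedChr <- as.character(fx$seed)[[1]]
  b <- ContigStretch:::.newBranch(seedChr, "s1")
  kids <- extendStep(b, "right", idx, extenderConfig())
  expect_length(kids, 1L)
  expect_gt(nchar(finalContig(kids[[1]])), nchar(seedChr))
  # the grown contig is still an exact substring of the genome
  expect_true(grepl(finalContig(kids[[1]]), fx$genome_chr, fixed = TRUE))
})

test_that("a terminus with no overhanging reads deactivates that side", {
  fx <- sim_fixture(genomeLength = 1200L, depth = 10, errorRate = 0, rng = 4L)
  idx <- buildReadIndex(fx$reads)
  b <- ContigStretch:::.newBranch(fx$genome_chr, "whole")
  kids <- extendStep(b, "right", idx, extenderConfig())
  expect_length(kids, 1L)
  expect_equal(nchar(finalContig(kids[[1]])), nchar(fx$genome_chr))
  expect_false(kids[[1]]@rightActive)
})

test_that("two diverged strains beyond the seed end spawn both branches", {
  set.seed(55)
  core <- random_seq(1200)
  # strains differ at one site ~60 bp beyond the seed end
  strainA <- core
  strainB <- core
  substr(strainB, 860, 860) <-
    setdiff(c("A", "C", "G", "T"), substr(strainB, 860, 860))[1]
  mkreads <- function(g, prefix) {
    starts <- seq(1, nchar(g) - 99, by = 10) # 10x tiling
    r <- substring(g, starts, starts + 99)
    names(r) <- paste0(prefix, seq_along(r))
    r
  }
  reads <- Biostrings::DNAStringSet(c(mkreads(strainA, "a"), mkreads(strainB, "b")))
  seed <- stats::setNames(substr(core, 301, 800), "seed")
  res <- runExtension(seed, reads, extenderConfig())
  contigs <- vapply(res, finalContig, character(1))
  matchesA <- vapply(contigs, function(x) grepl(x, strainA, fixed = TRUE), logical(1))
  matchesB <- vapply(contigs, function(x) grepl(x, strainB, fixed = TRUE), logical(1))
  expect_true(any(matchesA & nchar(contigs) > 900))
  expect_true(any(matchesB & nchar(contigs) > 900))
  expect_true(all(matchesA | matchesB))
  # branch budget 1 keeps only the main (higher-support) path
  res1 <- runExtension(seed, reads, extenderConfig(branchBudget = 1L))
  expect_length(res1, 1L)
})

test_that("detectCycle distinguishes none, cycle and circular", {
  b <- ContigStretch:::.newBranch(paste0(random_seq(300, 8)), "s")
  cfg <- extenderConfig(cycleWindow = 50L)
  # first iteration, empty history
  expect_equal(detectCycle(b, "right", cfg), "none")
  # same-side history repeat -> cycle
  term <- substr(b@contig, 251, 300)
  b2 <- b
  b2@historyRight <- term
  expect_equal(detectCycle(b2, "right", cfg), "cycle")
  # opposite-side history repeat -> circular
  b3 <- b
  b3@historyLeft <- term
  expect_equal(detectCycle(b3, "right", cfg), "circular")
  # terminal window recurring inside the contig (wrap) -> circular
  b4 <- ContigStretch:::.newBranch(
    paste0(b@contig, substr(b@contig, 1, 80)), "s"
  )
  expect_equal(detectCycle(b4, "right", cfg), "circular")
})

test_that("a circular genome is detected and not over-extended", {
  fx <- sim_fixture(genomeLength = 1000L, depth = 20, readLength = 100L,
                    errorRate = 0, seedLen = 300L, rng = 12L, circular = TRUE)
  res <- runExtension(fx$seed, fx$reads, extenderConfig())
  top <- res[[1]]
  expect_true(isCircular(top))
  expect_equal(stopReason(top), "circular")
  expect_lte(nchar(finalContig(top)), 1000L + 100L)
  expect_gte(nchar(finalContig(top)), 900L)
  # the contig maps to the circular reference in one piece
  al <- largestAlignedSegment(finalContig(top), fx$genome, circular = TRUE)
  expect_equal(al$alignedPct, 100)
})

test_that("runExtension reconstructs a known genome from a centred seed", {
  set.seed(91)
  genome <- random_seq(500)
  starts <- seq(1, 451, by = 5) # exact 50-mers at 10x
  reads <- substring(genome, starts, starts + 49)
  names(reads) <- paste0("r", seq_along(reads))
  seed <- stats::setNames(substr(genome, 201, 300), "mid")
  res <- runExtension(seed, Biostrings::DNAStringSet(reads),
                      extenderConfig(minQuality = 15L))
  expect_length(res, 1L)
  expect_equal(finalContig(res[[1]]), genome)
})

test_that("degenerate inputs are handled: empty reads, seed = genome", {
  seed <- stats::setNames(random_seq(200, 13), "s")
  res <- runExtension(seed, Biostrings::DNAStringSet())
  expect_length(res, 1L)
  expect_equal(finalContig(res[[1]]), unname(seed))
  expect_equal(stopReason(res[[1]]), "no_overlaps")
})

test_that("extension never shrinks a contig and is deterministic", {
  fx <- sim_fixture(genomeLength = 3000L, depth = 20, errorRate = 0.01,
                    seedLen = 600L, rng = 6L)
  cfg <- extenderConfig()
  res1 <- runExtension(fx$seed, fx$reads, cfg)
  res2 <- runExtension(fx$seed, fx$reads, cfg)
  for (b in res1) expect_gte(nchar(finalContig(b)), 600L)
  expect_equal(
    vapply(res1, finalContig, character(1)),
    vapply(res2, finalContig, character(1))
  )
  expect_equal(
    vapply(res1, lineage, character(1)),
    vapply(res2, lineage, character(1))
  )
})

test_that("extending the reverse-complemented seed mirrors the outputs", {
  fx <- sim_fixture(genomeLength = 2500L, depth = 15, errorRate = 0,
                    seedLen = 500L, rng = 17L)
  cfg <- extenderConfig()
  fwd <- runExtension(fx$seed, fx$reads, cfg)
  rcseed <- Biostrings::reverseComplement(fx$seed)
  names(rcseed) <- "seed"
  rev <- runExtension(rcseed, fx$reads, cfg)
  expect_equal(length(fwd), length(rev))
  expect_setequal(
    vapply(fwd, finalContig, character(1)),
    rc_chr(vapply(rev, finalContig, character(1)))
  )
})

test_that("extendAll is per-seed independent and validates ids", {
  set.seed(33)
  genomes <- vapply(1:3, function(i) random_seq(1500), character(1))
  reads <- character()
  for (i in 1:3) {
    starts <- seq(1, 1401, by = 10)
    r <- substring(genomes[i], starts, starts + 99)
    names(r) <- paste0("g", i, "_", seq_along(r))
    reads <- c(reads, r)
  }
  seeds <- Biostrings::DNAStringSet(stats::setNames(
    substr(genomes, 501, 1000), paste0("seed", 1:3)
  ))
  res <- extendAll(seeds, Biostrings::DNAStringSet(reads), extenderConfig())
  expect_named(res, paste0("seed", 1:3))
  for (i in 1:3) {
    expect_true(grepl(finalContig(res[[i]][[1]]), genomes[i], fixed = TRUE))
    expect_gt(nchar(finalContig(res[[i]][[1]])), 1300L)
  }
  dup <- Biostrings::DNAStringSet(stats::setNames(
    substr(genomes[1:2], 1, 600), c("x", "x")
  ))
  expect_error(extendAll(dup, Biostrings::DNAStringSet(reads)), "duplicate")
  expect_equal(length(extendAll(seeds[0], Biostrings::DNAStringSet(reads))), 0L)
})

test_that("the run log and FASTA writer carry the lineage header convention", {
  fx <- sim_fixture(genomeLength = 1500L, depth = 15, errorRate = 0,
                    seedLen = 400L, rng = 19L)
  seeds <- fx$seed
  names(seeds) <- "s1"
  res <- extendAll(seeds, fx$reads)
  log <- extensionSummary(res)
  expect_true(all(log$gained >= 0))
  expect_true(all(log$length == log$gained + 400L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeExtensionFasta(res, fa)
  back <- readFasta(fa)
  expect_true(all(grepl("^s1\\|branch=root.*\\|len=\\d+\\|circular=(true|false)\\|stop=", names(back))))
})
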