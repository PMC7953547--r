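# Shotgun read simulator emulating the in-silico benchmarking protocol:
# uniform random genomes, uniform read sampling (binomial per-position
# coverage), substitution-only errors, optional 50x/250bp spike-in peaks
# every 1 kb, optional circularity and two-strain mixtures.

#' Simulate a uniformly random genome
#'
#' Bases are i.i.d. with the requested GC content. Deterministic under the
#' spec's RNG seed; the simulator never touches the session RNG state.
#'
#' @param spec a [SimulationSpec-class].
#' @return a single-sequence [Biostrings::DNAStringSet] named `"simgenome"`.
#' @export
simulateGenome <- function(spec) {
  stopifnot(methods::is(spec, "SimulationSpec"))
  g <- withr::with_seed(spec@seed, {
    p <- c((1 - spec@gcContent) / 2, spec@gcContent / 2,
           spec@gcContent / 2, (1 - spec@gcContent) / 2)
    paste(sample(.BASES, spec@genomeLength, replace = TRUE, prob = p),
          collapse = "")
  })
  Biostrings::DNAStringSet(c(simgenome = g))
}

# Apply i.i.d. substitutions at the given per-base rate to one sequence.
# Each hit base becomes a uniformly random *different* base. Consumes the
# current RNG stream (callers wrap in with_seed).
.substitute <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(s)
  cur <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in hit) {
    cur[i] <- sample(setdiff(.BASES, cur[i]), 1L)
  }
  paste(cur, collapse = "")
}

# Vectorized substitution over a character vector of equal-ish length reads.
.substituteReads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  hit <- which(runif(total) < rate)
  if (!length(hit)) return(reads)
  ends <- cumsum(lens)
  ridx <- findInterval(hit - 1L, ends) + 1L # read containing each hit base
  pos <- hit - c(0L, ends)[ridx]
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 3L, dimnames = list(NULL, .BASES))
  pick <- sample.int(3L, length(hit), replace = TRUE)
  for (j in seq_along(hit)) {
    b <- substr(reads[ridx[j]], pos[j], pos[j])
    if (!b %in% .BASES) next
    substr(reads[ridx[j]], pos[j], pos[j]) <- alt[pick[j], b]
  }
  reads
}

# Draw single-end reads of length l from genome (character), starts given.
.cutReads <- function(genome, starts, l, circular) {
  if (circular) {
    G <- nchar(genome)
    starts <- ((starts - 1L) %% G) + 1L
    doubled <- paste0(genome, substr(genome, 1L, l))
    substring(doubled, starts, starts + l - 1L)
  } else {
    substring(genome, starts, starts + l - 1L)
  }
}

#' Simulate a shotgun read set
#'
#' Read count is `round(depth * genomeLength / readLength)` (counted per
#' mate for paired layouts). Start positions are uniform - wrapping the
#' origin for circular genomes, truncated at the end for linear ones - which
#' yields the binomial per-position coverage of ideal shotgun sequencing:
#' at 10x mean depth some positions drop to ~1x by chance. Each base is
#' substituted independently at `errorRate` (to a uniformly random different
#' base); reads land on the reverse strand with probability 1/2. With
#' `spikePeaks`, extra reads are drawn from 250 bp intervals anchored every
#' 1 kb to raise those intervals to 50x coverage. With
#' `strain2Divergence > 0`, half the reads derive from a mutated copy of the
#' genome with that per-base divergence.
#'
#' @param genome the genome (single-sequence `DNAStringSet` or character).
#' @param spec a [SimulationSpec-class].
#' @return a named [Biostrings::DNAStringSet] of reads (paired reads are
#'   interleaved, named `frag<i>/1`, `frag<i>/2`).
#' @export
simulateReads <- function(genome, spec) {
  stopifnot(methods::is(spec, "SimulationSpec"))
  g <- unname(.asSeqChr(genome, "genome"))
  G <- nchar(g)
  l <- spec@readLength
  if (!spec@circular && l > G)
    stop("readLength exceeds the (linear) genome length")
  withr::with_seed(spec@seed + 1L, {
    g2 <- if (spec@strain2Divergence > 0)
      .substitute(g, spec@strain2Divergence) else NULL

    drawFrom <- function(startMin, startMax, count) {
      # returns character reads (genome-forward), before error/strand
      starts <- sample.int(startMax - startMin + 1L, count, replace = TRUE) +
        startMin - 1L
      src <- rep.int(1L, count)
      if (!is.null(g2)) {
        src[sample.int(count, floor(count / 2))] <- 2L
      }
      out <- character(count)
      if (any(src == 1L))
        out[src == 1L] <- .cutReads(g, starts[src == 1L], l, spec@circular)
      if (any(src == 2L))
        out[src == 2L] <- .cutReads(g2, starts[src == 2L], l, spec@circular)
      out
    }

    if (spec@paired) {
      npairs <- max(1L, round(spec@depth * G / (2 * l)))
      ins <- pmax(l, round(rnorm(npairs, spec@insertMean, spec@insertSd)))
      ins <- pmin(ins, G)
      maxStart <- if (spec@circular) G else G - ins + 1L
      starts <- floor(runif(npairs) * maxStart) + 1L
      doubled <- if (spec@circular) paste0(g, substr(g, 1L, max(ins))) else g
      r1 <- substring(doubled, starts, starts + l - 1L)
      r2 <- .rc(substring(doubled, starts + ins - l, starts + ins - 1L))
      reads <- as.vector(rbind(r1, r2))
      nms <- as.vector(rbind(
        paste0("frag", seq_len(npairs), "/1"),
        paste0("frag", seq_len(npairs), "/2")
      ))
      reads <- .substituteReads(reads, spec@errorRate)
    } else {
      n <- max(1L, round(spec@depth * G / l))
      maxStart <- if (spec@circular) G else G - l + 1L
      reads <- drawFrom(1L, maxStart, n)
      if (spec@spikePeaks) {
        anchors <- seq.int(1L, G, by = 1000L)
        extraDepth <- max(0, 50 - spec@depth)
        for (a in anchors) {
          iend <- min(a + 249L, if (spec@circular) a + 249L else G)
          ilen <- iend - a + 1L
          if (ilen < l && !spec@circular) next
          cnt <- round(extraDepth * ilen / l)
          if (cnt < 1L) next
          smax <- if (spec@circular) a + ilen - 1L else iend - l + 1L
          reads <- c(reads, drawFrom(a, max(a, smax), cnt))
        }
      }
      nms <- paste0("read", seq_along(reads))
      reads <- .substituteReads(reads, spec@errorRate)
      flip <- runif(length(reads)) < 0.5
      if (any(flip)) reads[flip] <- .rc(reads[flip])
    }
    Biostrings::DNAStringSet(stats::setNames(reads, nms))
  })
}

#' Sample a random seed contig from a genome
#'
#' Uniformly random substring of the requested length, as in the simulated
#' benchmarks where randomly selected 1 kb sequences serve as seed contigs.
#'
#' @param genome the genome (single-sequence `DNAStringSet` or character).
#' @param length seed length, bp.
#' @param seed RNG seed.
#' @return a single-sequence [Biostrings::DNAStringSet] named `"seed"`.
#' @export
sampleSeed <- function(genome, length, seed = 1L) {
  g <- unname(.asSeqChr(genome, "genome"))
  G <- nchar(g)
  length <- as.integer(length)
  if (length > G) stop("seed length exceeds the genome length")
  s <- withr::with_seed(as.integer(seed), {
    start <- sample.int(G - length + 1L, 1L)
    substr(g, start, start + length - 1L)
  })
  Biostrings::DNAStringSet(c(seed = s))
}

# Serialize a SimulationSpec to a plain list (JSON sidecar for provenance).
.specAsList <- function(spec) {
  list(
    genomeLength = spec@genomeLength, gcContent = spec@gcContent,
    circular = spec@circular, depth = spec@depth,
    readLength = spec@readLength, errorRate = spec@errorRate,
    paired = spec@paired, insertMean = spec@insertMean,
    insertSd = spec@insertSd, spikePeaks = spec@spikePeaks,
    strain2Divergence = spec@strain2Divergence, seed = spec@seed
  )
}
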