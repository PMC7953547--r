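# Shared simulation fixtures used across test files.

sim_fixture <- function(genomeLength = 2000L, depth = 20, readLength = 100L,
                        errorRate = 0, seedLen = 500L, rng = 11L, ...) {
  spec <- simulationSpec(
    genomeLength = genomeLength, depth = depth, readLength = readLength,
    errorRate = errorRate, seed = rng, ...
  )
  genome <- simulateGenome(spec)
  list(
    spec = spec,
    genome = genome,
    genome_chr = as.character(genome)[[1]],
    reads = simulateReads(genome, spec),
    seed = sampleSeed(genome, seedLen, rng)
  )
}

# A set of reads exactly tiling the right end of a contig with fixed
# overhangs into `beyond` (the sequence continuing past the contig).
tiling_reads <- function(contig, beyond, read_len = 30L, overhang = 10L,
                         step = 5L) {
  full <- paste0(contig, beyond)
  W <- nchar(contig)
  starts <- seq(1L, W - (read_len - overhang) + 1L, by = step)
  starts <- starts[starts + read_len - 1L <= nchar(full) &
                   starts + read_len - 1L > W]
  reads <- substring(full, starts, starts + read_len - 1L)
  names(reads) <- paste0("tile", seq_along(reads))
  reads
}

# Write a minimal SAM file for placements against a window reference.
write_sam_fixture <- function(path, refname, reflen, rows) {
  # rows: data.frame(qname, flag, pos, cigar, seq)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refname, reflen))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$qname[i], rows$flag[i], refname, rows$pos[i], 60L,
          rows$cigar[i], "*", 0L, 0L, rows$seq[i],
          strrep("I", nchar(rows$seq[i])), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
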