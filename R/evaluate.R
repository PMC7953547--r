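# Reference-based scoring of final contigs: gained length, largest
# contiguous aligned segment, chimera flagging.

#' Gained-length arithmetic for one extended contig
#'
#' @param seedLength seed contig length, bp.
#' @param finalLength final contig length, bp (must be >= `seedLength`).
#' @param genomeLength reference genome length, bp.
#' @return one-row data.frame: `seedLength`, `finalLength`, `gainedLength`
#'   (final minus seed), `gainedPct` (percent of seed), `gainedGenomePct`
#'   (percent of reference genome).
#' @examples
#' gainedMetrics(4251, 10059, 15646) # gained 5808 bp, 137% of the seed
#' @export
gainedMetrics <- function(seedLength, finalLength, genomeLength) {
  stopifnot(seedLength >= 1, genomeLength >= 1)
  if (finalLength < seedLength)
    stop("finalLength must be >= seedLength")
  gained <- finalLength - seedLength
  data.frame(
    seedLength = seedLength, finalLength = finalLength, gainedLength = gained,
    gainedPct = 100 * gained / seedLength,
    gainedGenomePct = 100 * gained / genomeLength
  )
}

# Exact k-mer matches between a query and a reference string:
# data.table(qpos, rpos, diag), 1-based positions.
.kmerMatches <- function(query, ref, k) {
  nq <- nchar(query) - k + 1L
  if (nq < 1L) {
    return(data.table(qpos = integer(), rpos = integer(), diag = integer()))
  }
  qp <- seq_len(nq)
  qk <- data.table(kmer = substring(query, qp, qp + k - 1L), qpos = qp)
  rp <- seq_len(max(0L, nchar(ref) - k + 1L))
  rk <- data.table(kmer = substring(ref, rp, rp + k - 1L), rpos = rp)
  m <- rk[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  m[, diag := rpos - qpos]
  m[, list(qpos, rpos, diag)]
}

#' Largest contiguous aligned segment of a contig against a reference
#'
#' A self-contained stand-in for a BLAST-style search: exact k-mer matches
#' between the contig (both strands) and the reference (doubled when
#' circular, so origin-spanning contigs align in one piece) are grouped into
#' near-diagonal clusters (diagonal drift at most `maxGap`, so indels longer
#' than `maxGap` split segments), chained along the contig, and each chained
#' segment is verified base-by-base at its dominant diagonal; segments below
#' `minIdentity` ungapped identity are rejected. The longest surviving
#' contig span is reported.
#'
#' @param contig contig sequence (character or `DNAStringSet` of 1).
#' @param reference reference genome (character or `DNAStringSet` of 1).
#' @param circular is the reference circular?
#' @param k seed k-mer size (default 15).
#' @param minIdentity minimum identity of a verified segment (default 0.95).
#' @param maxGap maximum diagonal drift (indel tolerance) within one
#'   segment, bp (default 10).
#' @param maxSeedGap maximum distance between consecutive seed matches
#'   within one segment, bp (default 100).
#' @return list with `alignedLength` (bp of the largest segment, 0 when
#'   nothing aligns) and `alignedPct` (percent of the contig).
#' @export
largestAlignedSegment <- function(contig, reference, circular = FALSE,
                                  k = 15L, minIdentity = 0.95, maxGap = 10L,
                                  maxSeedGap = 100L) {
  qseq <- unname(.asSeqChr(contig, "contig"))
  rseq <- unname(.asSeqChr(reference, "reference"))
  stopifnot(nchar(qseq) > 0L, nchar(rseq) > 0L)
  if (circular) rseq <- paste0(rseq, rseq)
  best <- 0L
  for (q in c(qseq, .rc(qseq))) {
    m <- .kmerMatches(q, rseq, k)
    if (nrow(m) == 0L) next
    setorder(m, diag, qpos)
    # cluster by diagonal: a new cluster starts when the diagonal jumps
    dj <- c(0L, diff(m$diag))
    cl <- cumsum(dj > maxGap)
    for (cid in unique(cl)) {
      mm <- m[cl == cid]
      setorder(mm, qpos)
      mm <- unique(mm, by = "qpos")
      # chain: split where consecutive seed starts are too far apart
      br <- c(0L, cumsum(diff(mm$qpos) > maxSeedGap))
      for (g in unique(br)) {
        seg <- mm[br == g]
        a <- min(seg$qpos)
        b <- max(seg$qpos) + k - 1L
        d <- as.integer(stats::median(seg$diag))
        ra <- a + d
        rb <- b + d
        if (ra < 1L || rb > nchar(rseq)) next
        qr <- charToRaw(substr(q, a, b))
        rr <- charToRaw(substr(rseq, ra, rb))
        ident <- sum(qr == rr & qr != .RAW_N) / length(qr)
        if (ident >= minIdentity && (b - a + 1L) > best)
          best <- b - a + 1L
      }
    }
  }
  list(alignedLength = best, alignedPct = 100 * best / nchar(qseq))
}

#' Full evaluation report for one extended contig
#'
#' Combines [gainedMetrics()] and [largestAlignedSegment()] and flags the
#' contig as chimeric when less than `chimeraPct` of it lies in a single
#' aligned segment - the signature of sequence mis-joined from a different
#' region.
#'
#' @param contig final contig sequence.
#' @param seedLength seed contig length, bp.
#' @param reference reference genome.
#' @param circular is the reference circular?
#' @param chimeraPct single-segment alignment percentage below which the
#'   contig is flagged chimeric (default 98).
#' @param contigId id recorded in the report row.
#' @return one-row data.frame: `contigId`, `seedLength`, `finalLength`,
#'   `gainedLength`, `gainedPct`, `alignedLength`, `alignedPct`,
#'   `genomeLength`, `gainedGenomePct`, `chimeric`.
#' @export
evaluateContig <- function(contig, seedLength, reference, circular = FALSE,
                           chimeraPct = 98, contigId = "contig") {
  qseq <- unname(.asSeqChr(contig, "contig"))
  rseq <- unname(.asSeqChr(reference, "reference"))
  gm <- gainedMetrics(seedLength, nchar(qseq), nchar(rseq))
  al <- largestAlignedSegment(qseq, rseq, circular = circular)
  data.frame(
    contigId = contigId,
    seedLength = gm$seedLength, finalLength = gm$finalLength,
    gainedLength = gm$gainedLength, gainedPct = gm$gainedPct,
    alignedLength = al$alignedLength, alignedPct = al$alignedPct,
    genomeLength = nchar(rseq), gainedGenomePct = gm$gainedGenomePct,
    chimeric = al$alignedPct < chimeraPct,
    stringsAsFactors = FALSE
  )
}

#' Write (and round-trip) an evaluation report table
#'
#' TSV with the benchmark-table column layout; percent columns are rounded
#' to integers for display while bp columns stay exact. The file re-reads
#' losslessly with [readReportTable()].
#'
#' @param reports data.frame of rows from [evaluateContig()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
reportTable <- function(reports, path) {
  cols <- c("contigId", "seedLength", "finalLength", "gainedLength",
            "gainedPct", "alignedLength", "alignedPct", "genomeLength",
            "gainedGenomePct", "chimeric")
  if (nrow(reports) == 0L) {
    reports <- as.data.frame(stats::setNames(
      replicate(length(cols), logical(0), simplify = FALSE), cols
    ))
  }
  out <- reports[, cols, drop = FALSE]
  for (p in c("gainedPct", "alignedPct", "gainedGenomePct"))
    out[[p]] <- round(as.numeric(out[[p]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname reportTable
#' @param path TSV path written by [reportTable()].
#' @export
readReportTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
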