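#' @import data.table
NULL

.RAW_N <- charToRaw("N")

# Coerce a single sequence argument (character, DNAString(Set)) to a plain
# string, carrying an id when one is available.
.asSeqChr <- function(x, default_id = "contig") {
  if (methods::is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    id <- if (!is.null(names(x))) names(x)[[1L]] else default_id
    return(stats::setNames(as.character(x)[[1L]], id))
  }
  if (methods::is(x, "XString"))
    return(stats::setNames(as.character(x), default_id))
  stopifnot(is.character(x), length(x) == 1L)
  id <- if (!is.null(names(x)) && nzchar(names(x)[[1L]])) names(x)[[1L]] else default_id
  stats::setNames(unname(x), id)
}

#' Cut the two terminus windows of a contig
#'
#' Only reads overlapping a contig end can extend it, so alignment is
#' restricted to the prefix and suffix of the contig whose length equals the
#' longest read length (clamped to the contig length for short contigs).
#'
#' @param contig the contig: a single-sequence `DNAStringSet`, `DNAString`,
#'   or (optionally named) character string.
#' @param maxReadLength the longest read length in the read set, bp.
#' @param contigId id used when `contig` carries no name.
#' @return a list with elements `left` and `right`, each a
#'   [TerminusWindow-class].
#' @examples
#' makeWindows("AAAACCCCGGGG", 5)
#' @export
makeWindows <- function(contig, maxReadLength, contigId = "contig") {
  s <- .asSeqChr(contig, contigId)
  stopifnot(nchar(s) >= 1L, maxReadLength >= 1L)
  w <- min(nchar(s), as.integer(maxReadLength))
  list(
    left = new("TerminusWindow",
      contigId = names(s), side = "left",
      sequence = unname(substr(s, 1L, w)), windowLength = w
    ),
    right = new("TerminusWindow",
      contigId = names(s), side = "right",
      sequence = unname(substr(s, nchar(s) - w + 1L, nchar(s))),
      windowLength = w
    )
  )
}

#' Overlap quality: count of agreeing in-contig bases
#'
#' The quality q_k of a candidate read placement is the number of positions,
#' over the part of the read that lies inside the contig, where the read base
#' equals the contig base. Bases hanging beyond the contig are excluded, and
#' `N` never counts as agreeing (on either side).
#'
#' @param orientedRead read sequence, already oriented to the contig strand.
#' @param contig contig (or terminus window) sequence.
#' @param offset 0-based position of the read's first base relative to the
#'   contig's first base; may be negative (read hangs off the start).
#' @return integer agreement count.
#' @examples
#' overlapQuality("CGTTTT", "ACGTACGT", 5) # only "CGT" lies inside -> 3
#' @export
overlapQuality <- function(orientedRead, contig, offset) {
  offset <- as.integer(offset)
  rl <- nchar(orientedRead)
  cl <- nchar(contig)
  a <- max(0L, offset)
  b <- min(cl - 1L, offset + rl - 1L)
  if (b < a)
    stop("placement does not overlap the contig (offset ", offset, ")")
  rr <- charToRaw(substr(orientedRead, a - offset + 1L, b - offset + 1L))
  cc <- charToRaw(substr(contig, a + 1L, b + 1L))
  sum(rr == cc & rr != .RAW_N)
}

#' Build the k-mer index of a read set
#'
#' The built-in overlap scanner anchors candidate placements on exact k-mer
#' matches between a terminus window and any read (both orientations), then
#' scores the implied ungapped placement base by base. The index is built
#' once per read set and reused across all windows, iterations and seeds.
#'
#' @param reads a `DNAStringSet` (or named character vector) of reads.
#' @param k anchor k-mer size (default 12).
#' @return an opaque list used by [findTerminusOverlaps()] and
#'   [runExtension()]; notable elements are `maxLen` (longest read length)
#'   and `n` (number of reads).
#' @export
buildReadIndex <- function(reads, k = 12L) {
  k <- as.integer(k)
  stopifnot(k >= 4L)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  seqs <- toupper(as.character(reads))
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  if (n == 0L) {
    return(list(
      ids = character(), seq = character(), rcseq = character(),
      raw = list(), rcraw = list(), len = integer(), maxLen = 0L, k = k, n = 0L,
      kmers = data.table(
        kmer = character(), read = integer(), pos0 = integer(),
        strand = character()
      )
    ))
  }
  rcs <- .rc(seqs)
  len <- nchar(seqs)

  kmerTab <- function(ss, strand) {
    nk <- pmax(len - k + 1L, 0L)
    idx <- rep.int(seq_len(n), nk)
    p1 <- sequence(nk)
    data.table(
      kmer = substring(ss[idx], p1, p1 + k - 1L),
      read = idx, pos0 = p1 - 1L, strand = strand
    )
  }
  km <- rbind(kmerTab(seqs, "+"), kmerTab(rcs, "-"))
  setkey(km, kmer)
  list(
    ids = ids, seq = seqs, rcseq = rcs,
    raw = lapply(seqs, charToRaw), rcraw = lapply(rcs, charToRaw),
    len = len, maxLen = max(len), k = k, n = n, kmers = km
  )
}

# Agreement count between a read (raw bytes, oriented) and window (raw bytes)
# at a 0-based offset; in-window span only, N never agrees.
.agree <- function(rraw, wraw, offset) {
  rl <- length(rraw)
  W <- length(wraw)
  a <- max(0L, offset)
  b <- min(W - 1L, offset + rl - 1L)
  if (b < a) return(0L)
  rr <- rraw[(a - offset + 1L):(b - offset + 1L)]
  ww <- wraw[(a + 1L):(b + 1L)]
  sum(rr == ww & rr != .RAW_N)
}

#' Find reads overlapping a terminus window
#'
#' Tests every read in both orientations against the window via exact k-mer
#' anchoring, scores each distinct implied placement with [overlapQuality()]
#' semantics, and returns the placements that (a) overhang the contig end by
#' at least one base, (b) have quality `>= minQuality`, and (c) agree on at
#' least `minIdentity` of their in-window span (the scanner's stand-in for an
#' end-to-end aligner's acceptance criterion). A read may yield several
#' placements (genomic repeats); all passing placements are kept and later
#' disambiguated by consensus branching.
#'
#' @param window a [TerminusWindow-class].
#' @param readIndex index from [buildReadIndex()].
#' @param minQuality minimum agreement count q_k (default 20).
#' @param minIdentity minimum agreeing fraction of the in-window span
#'   (default 0.8).
#' @param pairConstraint optional [PairConstraint-class]; when enabled, reads
#'   whose mates place discordantly on the same window are discarded. Mates
#'   are recognized by `/1`/`/2` id suffixes.
#' @return a data.frame with one row per placement: `readId`, `orientedSeq`
#'   (reverse-complemented when placed on the reverse strand), `offset`
#'   (0-based, window coordinates), `overhang` (bases beyond the contig end),
#'   `quality` (q_k).
#' @export
findTerminusOverlaps <- function(window, readIndex, minQuality = 20L,
                                 minIdentity = 0.8, pairConstraint = NULL) {
  stopifnot(methods::is(window, "TerminusWindow"))
  empty <- data.frame(
    readId = character(), orientedSeq = character(), offset = integer(),
    overhang = integer(), quality = integer(), stringsAsFactors = FALSE
  )
  W <- window@windowLength
  k <- readIndex$k
  if (readIndex$n == 0L || W < k) return(empty)
  wseq <- window@sequence
  p1 <- seq_len(W - k + 1L)
  wk <- data.table(kmer = substring(wseq, p1, p1 + k - 1L), wpos0 = p1 - 1L)
  hits <- readIndex$kmers[wk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits[, offset := wpos0 - pos0]
  cand <- unique(hits[, list(read, strand, offset)])
  cand[, len := readIndex$len[read]]
  # overhang beyond the contig end this window represents
  if (window@side == "right") {
    cand[, overhang := offset + len - W]
  } else {
    cand[, overhang := -offset]
  }
  cand <- cand[overhang >= 1L]
  if (nrow(cand) == 0L) return(empty)
  wraw <- charToRaw(wseq)
  q <- integer(nrow(cand))
  span <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rraw <- if (cand$strand[i] == "+") readIndex$raw[[cand$read[i]]] else
      readIndex$rcraw[[cand$read[i]]]
    a <- max(0L, cand$offset[i])
    b <- min(W - 1L, cand$offset[i] + cand$len[i] - 1L)
    span[i] <- b - a + 1L
    q[i] <- .agree(rraw, wraw, cand$offset[i])
  }
  cand[, quality := q]
  cand[, inspan := span]
  cand <- cand[quality >= minQuality & quality / inspan >= minIdentity]
  if (nrow(cand) == 0L) return(empty)
  cand[, readId := readIndex$ids[read]]
  cand[, orientedSeq := ifelse(strand == "+", readIndex$seq[read],
                               readIndex$rcseq[read])]
  if (!is.null(pairConstraint) && methods::is(pairConstraint, "PairConstraint") &&
      pairConstraint@enabled) {
    cand <- .applyPairConstraint(cand, pairConstraint)
  }
  setorder(cand, readId, offset, strand)
  data.frame(
    readId = cand$readId, orientedSeq = cand$orientedSeq,
    offset = as.integer(cand$offset), overhang = as.integer(cand$overhang),
    quality = as.integer(cand$quality), stringsAsFactors = FALSE
  )
}

# Drop placements whose mate placed discordantly (wrong orientation or insert
# outside the allowed range). Mate ids differ only in a /1 vs /2 suffix.
.applyPairConstraint <- function(cand, pc) {
  frag <- sub("/[12]$", "", cand$readId)
  hasMateTag <- grepl("/[12]$", cand$readId)
  keep <- rep(TRUE, nrow(cand))
  for (i in which(hasMateTag)) {
    mrows <- which(frag == frag[i] & cand$readId != cand$readId[i])
    if (length(mrows) == 0L) next # mate unplaced: keep
    concordant <- FALSE
    s1 <- cand$offset[i]
    e1 <- cand$offset[i] + cand$len[i] - 1L
    for (j in mrows) {
      if (cand$strand[i] == cand$strand[j]) next # FF/RR: discordant
      s2 <- cand$offset[j]
      e2 <- cand$offset[j] + cand$len[j] - 1L
      fwdFirst <- if (cand$strand[i] == "+") s1 <= s2 else s2 <= s1
      insert <- max(e1, e2) - min(s1, s2) + 1L
      if (fwdFirst && insert >= pc@minInsert && insert <= pc@maxInsert) {
        concordant <- TRUE
        break
      }
    }
    if (!concordant) keep[i] <- FALSE
  }
  cand[keep]
}

#' Ingest SAM alignments against a terminus window
#'
#' External-aligner backend: converts mapped SAM records (aligned with the
#' window sequence as reference, named `"<contigId>:<side>"`) into the same
#' placement records [findTerminusOverlaps()] produces. Placements are
#' re-scored with [overlapQuality()] rather than trusting aligner scores;
#' soft-clipped bases shift the implied start and typically form the
#' overhang. Unmapped records and records without overhang are dropped, and
#' the same quality/identity filters apply.
#'
#' @param path path to a SAM (text) file.
#' @param window the [TerminusWindow-class] the alignments refer to.
#' @param minQuality,minIdentity as in [findTerminusOverlaps()].
#' @return a data.frame with columns `readId`, `orientedSeq`, `offset`,
#'   `overhang`, `quality`.
#' @export
ingestSam <- function(path, window, minQuality = 20L, minIdentity = 0.8) {
  stopifnot(methods::is(window, "TerminusWindow"))
  expected <- paste0(window@contigId, ":", window@side)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  if (!any(mapped)) {
    return(data.frame(
      readId = character(), orientedSeq = character(), offset = integer(),
      overhang = integer(), quality = integer(), stringsAsFactors = FALSE
    ))
  }
  rnames <- as.character(rec$rname)[mapped]
  if (any(rnames != expected))
    stop("SAM reference name(s) ", paste(unique(setdiff(rnames, expected)),
         collapse = ", "), " do not match window naming convention ", expected)
  qname <- rec$qname[mapped]
  pos <- rec$pos[mapped]
  cig <- rec$cigar[mapped]
  seqs <- .normalizeSeq(as.character(rec$seq)[mapped])
  leadS <- ifelse(grepl("^[0-9]+S", cig),
                  as.integer(sub("^([0-9]+)S.*$", "\\1", cig)), 0L)
  offset <- pos - 1L - leadS
  len <- nchar(seqs)
  W <- window@windowLength
  overhang <- if (window@side == "right") offset + len - W else -offset
  out <- data.frame(
    readId = qname, orientedSeq = seqs, offset = as.integer(offset),
    overhang = as.integer(overhang), quality = 0L, stringsAsFactors = FALSE
  )
  out <- out[out$overhang >= 1L, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  wraw <- charToRaw(window@sequence)
  q <- integer(nrow(out))
  span <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    a <- max(0L, out$offset[i])
    b <- min(W - 1L, out$offset[i] + nchar(out$orientedSeq[i]) - 1L)
    span[i] <- b - a + 1L
    q[i] <- .agree(charToRaw(out$orientedSeq[i]), wraw, out$offset[i])
  }
  out$quality <- q
  out <- out[out$quality >= minQuality & q / span >= minIdentity, , drop = FALSE]
  out <- out[order(out$readId, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
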