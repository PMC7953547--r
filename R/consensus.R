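#' Extension threshold
#'
#' The evidence bar a base must clear to be written into the consensus:
#' `10^(-t) * l^2 * c`, with tolerance `t` (dimensionless), longest read
#' length `l` (bp) and local coverage estimate `c`. The `l^2` term matches
#' the scale of squared overlap qualities, so at any coverage the surviving
#' extension demands terminal overlaps of length about `l * 10^(-t/3)`:
#' low-coverage regions are extended on fewer, but proportionally longer,
#' agreeing overlaps rather than being cut off by a hard depth threshold.
#'
#' @param config a [ToleranceConfig-class].
#' @return the threshold (numeric scalar).
#' @examples
#' extensionThreshold(toleranceConfig(2.5, 100L, 10)) # 316.2278
#' @export
extensionThreshold <- function(config) {
  stopifnot(methods::is(config, "ToleranceConfig"))
  10^(-config@tolerance) * as.numeric(config@readLength)^2 * config@coverageEstimate
}

#' Aggregate overlaps into the per-position score matrix
#'
#' For every covered position i and base j, sums the squared qualities q_k^2
#' of the overlaps whose read carries j at i, and counts those reads. The
#' matrix spans from the leftmost covered position to the rightmost
#' overhanging position; `N` bases contribute nothing.
#'
#' @param overlaps data.frame of placements from [findTerminusOverlaps()] /
#'   [ingestSam()] (columns `orientedSeq`, `offset`, `quality`).
#' @param contigLength length of the contig (window) the offsets refer to;
#'   recorded so callers know where "beyond the end" starts.
#' @return a [ScoreMatrix-class] (0 columns for an empty overlap list).
#' @export
buildScoreMatrix <- function(overlaps, contigLength) {
  contigLength <- as.integer(contigLength)
  if (is.null(overlaps) || nrow(overlaps) == 0L) {
    m <- matrix(numeric(0), nrow = 4L, ncol = 0L,
                dimnames = list(.BASES, NULL))
    cm <- matrix(integer(0), nrow = 4L, ncol = 0L,
                 dimnames = list(.BASES, NULL))
    return(new("ScoreMatrix", origin = 0L, scores = m, counts = cm))
  }
  lens <- nchar(overlaps$orientedSeq)
  # one row per (overlap, base position)
  colCoord <- unlist(lapply(seq_len(nrow(overlaps)), function(i) {
    overlaps$offset[i] + 0L:(lens[i] - 1L)
  }), use.names = FALSE)
  baseChr <- unlist(strsplit(overlaps$orientedSeq, "", fixed = TRUE),
                    use.names = FALSE)
  w2 <- rep.int(as.numeric(overlaps$quality)^2, lens)
  keep <- baseChr != "N"
  colCoord <- colCoord[keep]
  baseChr <- baseChr[keep]
  w2 <- w2[keep]
  origin <- min(colCoord)
  ncols <- max(colCoord) - origin + 1L
  ci <- colCoord - origin + 1L
  bi <- match(baseChr, .BASES)
  idx <- (ci - 1L) * 4L + bi # column-major cell index into a 4 x ncols matrix
  sc <- numeric(4L * ncols)
  cn <- integer(4L * ncols)
  agg <- rowsum(cbind(w2, 1L), group = idx)
  cells <- as.integer(rownames(agg))
  sc[cells] <- agg[, 1L]
  cn[cells] <- as.integer(agg[, 2L])
  new("ScoreMatrix",
    origin = as.integer(origin),
    scores = matrix(sc, nrow = 4L, dimnames = list(.BASES, NULL)),
    counts = matrix(cn, nrow = 4L, dimnames = list(.BASES, NULL))
  )
}

#' Call the consensus extension beyond the contig end
#'
#' Walks the score-matrix columns beyond the contig end in increasing order.
#' At each column the winning base (ties broken A<C<G<T) is written when its
#' score exceeds the extension threshold; the walk stops at the first column
#' where no base clears it (truncation, not N-filling: later columns will be
#' re-voted on the next iteration after re-alignment). A written column is
#' flagged ambiguous when the second-best base also clears the threshold and
#' is supported by at least `minBranchSupport` reads - the signature of a
#' strain mixture or repeat, and the seed of an alternate consensus.
#'
#' @param matrix a [ScoreMatrix-class].
#' @param contigEnd 0-based coordinate of the first position beyond the
#'   contig end (i.e. the contig/window length).
#' @param config a [ToleranceConfig-class].
#' @return a [ConsensusCall-class].
#' @export
callConsensus <- function(matrix, contigEnd, config) {
  stopifnot(methods::is(matrix, "ScoreMatrix"),
            methods::is(config, "ToleranceConfig"))
  contigEnd <- as.integer(contigEnd)
  thr <- extensionThreshold(config)
  sc <- matrix@scores
  cn <- matrix@counts
  nc <- ncol(sc)
  out <- character()
  ambig <- integer()
  if (nc > 0L && matrix@origin <= contigEnd) {
    firstCol <- contigEnd - matrix@origin + 1L
    if (firstCol < 1L) firstCol <- 1L
    for (ci in seq.int(firstCol, length.out = max(0L, nc - firstCol + 1L))) {
      col <- sc[, ci]
      bi <- which.max(col) # first max: A<C<G<T tie-break
      if (col[bi] <= thr) break
      out[length(out) + 1L] <- .BASES[bi]
      second <- col
      second[bi] <- -Inf
      si <- which.max(second)
      if (second[si] > thr && cn[si, ci] >= config@minBranchSupport)
        ambig[length(ambig) + 1L] <- length(out)
    }
  }
  new("ConsensusCall",
    sequence = paste(out, collapse = ""),
    extendedBases = length(out),
    ambiguousPositions = ambig
  )
}

#' Enumerate genotypes over the ambiguous positions
#'
#' Restricts every read that covers all the ambiguous positions to exactly
#' those positions; the resulting strings are each read's vote on how the
#' ambiguity should be resolved jointly. Genotypes are ranked by supporting
#' read count (ties broken lexicographically), those below
#' `minBranchSupport` are dropped, and at most `maxAlternates` beyond the
#' first are returned.
#'
#' @param overlaps placement data.frame (columns `orientedSeq`, `offset`).
#' @param positions 0-based window coordinates of the ambiguous positions.
#' @param config a [ToleranceConfig-class].
#' @return data.frame with columns `bases` (one character per ambiguous
#'   position) and `support` (read count), ranked; zero rows when no read
#'   covers all positions or none reaches the support threshold.
#' @export
enumerateGenotypes <- function(overlaps, positions, config) {
  stopifnot(methods::is(config, "ToleranceConfig"), length(positions) >= 1L)
  positions <- as.integer(positions)
  empty <- data.frame(bases = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(overlaps) || nrow(overlaps) == 0L) return(empty)
  lens <- nchar(overlaps$orientedSeq)
  covers <- overlaps$offset <= min(positions) &
    overlaps$offset + lens - 1L >= max(positions)
  if (!any(covers)) return(empty)
  sub <- overlaps[covers, , drop = FALSE]
  g <- vapply(seq_len(nrow(sub)), function(i) {
    paste(vapply(positions, function(p) {
      substr(sub$orientedSeq[i], p - sub$offset[i] + 1L,
             p - sub$offset[i] + 1L)
    }, character(1)), collapse = "")
  }, character(1))
  g <- g[!grepl("N", g, fixed = TRUE)]
  if (length(g) == 0L) return(empty)
  tab <- table(g)
  df <- data.frame(bases = names(tab), support = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[df$support >= config@minBranchSupport, , drop = FALSE]
  df <- df[order(-df$support, df$bases), , drop = FALSE]
  rownames(df) <- NULL
  head(df, 1L + config@maxAlternates)
}

#' Overwrite ambiguous positions of a consensus call with a genotype
#'
#' @param call a [ConsensusCall-class].
#' @param genotype a genotype string, one base per ambiguous position of the
#'   call, in position order.
#' @return the call's sequence with the ambiguous positions replaced.
#' @export
applyGenotype <- function(call, genotype) {
  stopifnot(methods::is(call, "ConsensusCall"))
  if (nchar(genotype) != length(call@ambiguousPositions))
    stop("genotype length (", nchar(genotype),
         ") does not match the number of ambiguous positions (",
         length(call@ambiguousPositions), ")")
  s <- call@sequence
  for (i in seq_along(call@ambiguousPositions)) {
    substr(s, call@ambiguousPositions[i], call@ambiguousPositions[i]) <-
      substr(genotype, i, i)
  }
  s
}
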