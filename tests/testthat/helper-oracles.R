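# Independent brute-force oracles, written directly from the definitions,
# used to cross-check the vectorized implementations.

BASES <- c("A", "C", "G", "T")

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Brute-force agreement count: per-base loop over the in-contig span.
oracle_quality <- function(read, contig, offset) {
  q <- 0L
  for (i in seq_len(nchar(read))) {
    cpos <- offset + i # 1-based contig position of read base i
    if (cpos < 1L || cpos > nchar(contig)) next
    rb <- substr(read, i, i)
    cb <- substr(contig, cpos, cpos)
    if (rb == cb && rb != "N") q <- q + 1L
  }
  q
}

# Brute-force score matrix: double loop over (overlap, read position),
# accumulating q_k^2 and read counts per base, per column.
oracle_score_matrix <- function(overlaps, span_lo, span_hi) {
  ncols <- span_hi - span_lo + 1L
  Q <- matrix(0, 4, ncols, dimnames = list(BASES, NULL))
  C <- matrix(0L, 4, ncols, dimnames = list(BASES, NULL))
  for (k in seq_len(nrow(overlaps))) {
    s <- overlaps$orientedSeq[k]
    for (i in seq_len(nchar(s))) {
      coord <- overlaps$offset[k] + i - 1L # 0-based column coordinate
      b <- substr(s, i, i)
      if (b == "N") next
      ci <- coord - span_lo + 1L
      if (ci < 1L || ci > ncols) next
      Q[b, ci] <- Q[b, ci] + overlaps$quality[k]^2
      C[b, ci] <- C[b, ci] + 1L
    }
  }
  list(Q = Q, C = C)
}

# Brute-force consensus caller over columns beyond the contig end.
oracle_consensus <- function(Q, C, span_lo, contig_end, threshold, min_support) {
  out <- character()
  ambig <- integer()
  for (ci in seq_len(ncol(Q))) {
    coord <- span_lo + ci - 1L
    if (coord < contig_end) next
    best <- NA_character_
    best_s <- -Inf
    for (b in BASES) { # fixed A<C<G<T order: first strict max wins
      if (Q[b, ci] > best_s) {
        best_s <- Q[b, ci]
        best <- b
      }
    }
    if (best_s <= threshold) break
    out <- c(out, best)
    second_s <- -Inf
    second <- NA_character_
    for (b in setdiff(BASES, best)) {
      if (Q[b, ci] > second_s) {
        second_s <- Q[b, ci]
        second <- b
      }
    }
    if (second_s > threshold && C[second, ci] >= min_support)
      ambig <- c(ambig, length(out))
  }
  list(sequence = paste(out, collapse = ""), ambiguous = ambig)
}

# Brute-force overlap scan: try every read, both orientations, at every
# offset, keeping placements that overhang the right end of the window by
# >= 1 base with quality >= min_quality and identity >= min_identity.
oracle_scan_right <- function(window, reads, min_quality, min_identity = 0.8) {
  W <- nchar(window)
  rows <- list()
  for (ri in seq_along(reads)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") reads[[ri]] else rc_chr(reads[[ri]])
      l <- nchar(s)
      for (offset in (-l + 1L):(W - 1L)) {
        overhang <- offset + l - W
        if (overhang < 1L) next
        a <- max(0L, offset)
        b <- min(W - 1L, offset + l - 1L)
        if (b < a) next
        q <- oracle_quality(s, window, offset)
        if (q < min_quality || q / (b - a + 1L) < min_identity) next
        rows[[length(rows) + 1L]] <- data.frame(
          readId = names(reads)[ri], orientedSeq = s, offset = offset,
          overhang = overhang, quality = q, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      readId = character(), orientedSeq = character(), offset = integer(),
      overhang = integer(), quality = integer(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$readId, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random placement fixture for score-matrix tests: arbitrary offsets and
# qualities, not necessarily consistent with any genome.
random_overlaps <- function(n, window_len, seed) {
  set.seed(seed)
  lens <- sample(20:60, n, replace = TRUE)
  offs <- sample((-10L):(window_len - 5L), n, replace = TRUE)
  data.frame(
    readId = paste0("r", seq_len(n)),
    orientedSeq = vapply(lens, function(l) {
      paste(sample(c(BASES, "N"), l, replace = TRUE,
                   prob = c(rep(0.24, 4), 0.04)), collapse = "")
    }, character(1)),
    offset = offs,
    overhang = pmax(1L, offs + lens - window_len),
    quality = sample(5:50, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
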