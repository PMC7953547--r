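# The recursive extension driver: iterate align -> consensus -> branch per
# contig end, depth-first over alternate consensuses.

.sideActive <- function(b, side) {
  if (side == "left") b@leftActive else b@rightActive
}

# Deactivate one side; when both sides are down, settle the branch-level stop
# reason (cycle outranks plain exhaustion).
.deactivateSide <- function(b, side, reason) {
  b@sideReasons[[side]] <- reason
  if (side == "left") b@leftActive <- FALSE else b@rightActive <- FALSE
  if (!b@leftActive && !b@rightActive && b@stopReason == "active") {
    rs <- b@sideReasons[nzchar(b@sideReasons)]
    b@stopReason <- if ("cycle" %in% rs) "cycle" else "no_overlaps"
  }
  b
}

.stopBranch <- function(b, reason) {
  b@leftActive <- FALSE
  b@rightActive <- FALSE
  b@stopReason <- reason
  b
}

.terminusStr <- function(contig, side, cw) {
  len <- nchar(contig)
  cw <- min(cw, len)
  if (side == "right") substr(contig, len - cw + 1L, len)
  else substr(contig, 1L, cw)
}

#' One extension iteration on one contig end
#'
#' Runs window cutting, overlap recruitment, score-matrix aggregation,
#' consensus calling and genotype enumeration for a single terminus, and
#' returns the resulting child branches: the main consensus first, then one
#' child per retained alternate genotype (strain/repeat paths), ranked by
#' read support. Left-end extension is performed by reverse-complementing the
#' contig, extending the right end, and reverse-complementing back, so all
#' internal logic is right-end only.
#'
#' A child that gained zero bases has that side deactivated
#' (`no_overlaps`); a child exceeding `maxLength` is trimmed at the growing
#' end and stopped with `max_length`.
#'
#' @param branch an active [ExtensionBranch-class].
#' @param side `"left"` or `"right"`.
#' @param readIndex index from [buildReadIndex()].
#' @param config an [ExtenderConfig-class].
#' @return list of [ExtensionBranch-class] children (main consensus first).
#' @export
extendStep <- function(branch, side, readIndex, config) {
  stopifnot(methods::is(branch, "ExtensionBranch"),
            branch@stopReason == "active", side %in% c("left", "right"))
  contig <- branch@contig
  working <- if (side == "left") .rc(contig) else contig
  W <- min(nchar(working), readIndex$maxLen)
  window <- new("TerminusWindow",
    contigId = branch@seedId, side = "right",
    sequence = substr(working, nchar(working) - W + 1L, nchar(working)),
    windowLength = as.integer(W)
  )
  ov <- findTerminusOverlaps(window, readIndex, config@minQuality,
                             config@minIdentity, config@pairConstraint)
  if (nrow(ov) == 0L)
    return(list(.deactivateSide(branch, side, "no_overlaps")))
  # local coverage: recruited read bases over the window span, floored at 1
  cEst <- max(1, sum(nchar(ov$orientedSeq)) / W)
  tc <- toleranceConfig(config@tolerance, readIndex$maxLen, cEst,
                        config@minBranchSupport, config@maxAlternates)
  sm <- buildScoreMatrix(ov, W)
  cc <- callConsensus(sm, W, tc)
  if (cc@extendedBases == 0L)
    return(list(.deactivateSide(branch, side, "no_overlaps")))

  exts <- cc@sequence
  supports <- Inf
  if (length(cc@ambiguousPositions)) {
    gt <- enumerateGenotypes(ov, W + cc@ambiguousPositions - 1L, tc)
    if (nrow(gt)) {
      mainBases <- paste(
        substring(cc@sequence, cc@ambiguousPositions, cc@ambiguousPositions),
        collapse = ""
      )
      isMain <- gt$bases == mainBases
      if (any(isMain)) supports <- gt$support[isMain]
      alts <- gt[!isMain, , drop = FALSE]
      alts <- head(alts, config@maxAlternates)
      if (nrow(alts)) {
        exts <- c(exts, vapply(alts$bases, function(bb) applyGenotype(cc, bb),
                               character(1), USE.NAMES = FALSE))
        supports <- c(supports, alts$support)
      }
    }
  }

  branchPoint <- length(exts) > 1L
  children <- vector("list", length(exts))
  for (v in seq_along(exts)) {
    child <- branch
    newWorking <- paste0(working, exts[[v]])
    child@contig <- if (side == "left") .rc(newWorking) else newWorking
    child@iterations <- branch@iterations + 1L
    child@support <- supports[[v]]
    if (branchPoint)
      child@lineage <- paste0(branch@lineage, ".", v - 1L)
    if (nchar(child@contig) > config@maxLength) {
      len <- nchar(child@contig)
      child@contig <- if (side == "left")
        substr(child@contig, len - config@maxLength + 1L, len)
      else substr(child@contig, 1L, config@maxLength)
      child <- .stopBranch(child, "max_length")
    }
    children[[v]] <- child
  }
  children
}

#' Detect extension cycles and circular genomes at a terminus
#'
#' Termination guard: if the current terminus window (the terminal
#' `cycleWindow` bases of the growing end) exactly reproduces a window seen
#' earlier on the same side, the extension has entered a loop (`"cycle"`).
#' If it reproduces a window from the opposite end's history, or occurs
#' verbatim elsewhere in the contig (the growing end has wrapped onto the
#' opposite end), the genome is circular (`"circular"`). Viral genomes carry
#' few exact repeats at read-length scale, so a repeated window is a reliable
#' wrap signal.
#'
#' @param branch an [ExtensionBranch-class] that has completed at least one
#'   iteration.
#' @param side `"left"` or `"right"`.
#' @param config an [ExtenderConfig-class]; `cycleWindow = 0` (auto) is not
#'   resolvable here, so pass `cycleWindow` explicitly in that case.
#' @param cycleWindow override for the window length, bp.
#' @return `"none"`, `"cycle"`, or `"circular"`.
#' @export
detectCycle <- function(branch, side, config, cycleWindow = NULL) {
  cw <- if (!is.null(cycleWindow)) as.integer(cycleWindow)
        else config@cycleWindow
  if (cw == 0L)
    stop("cycleWindow is 'auto' in this config; pass cycleWindow explicitly")
  contig <- branch@contig
  len <- nchar(contig)
  if (len < cw + 1L) return("none")
  term <- .terminusStr(contig, side, cw)
  hist <- if (side == "right") branch@historyRight else branch@historyLeft
  opp <- if (side == "right") branch@historyLeft else branch@historyRight
  if (term %in% hist) return("cycle")
  if (term %in% opp) return("circular")
  interior <- if (side == "right") substr(contig, 1L, len - 1L)
              else substr(contig, 2L, len)
  if (grepl(term, interior, fixed = TRUE)) return("circular")
  "none"
}

# After a side has grown: run cycle/circularity detection, update the
# terminus history, apply the circular trimming convention.
.postExtend <- function(b, side, config, cw) {
  chk <- detectCycle(b, side, config, cw)
  if (chk == "cycle") return(.deactivateSide(b, side, "cycle"))
  if (chk == "circular") {
    len <- nchar(b@contig)
    b@contig <- if (side == "right") substr(b@contig, 1L, len - cw)
                else substr(b@contig, cw + 1L, len)
    b@circular <- TRUE
    return(.stopBranch(b, "circular"))
  }
  term <- .terminusStr(b@contig, side, cw)
  if (side == "right") b@historyRight <- c(b@historyRight, term)
  else b@historyLeft <- c(b@historyLeft, term)
  b
}

#' Extend one seed contig through a read set
#'
#' The full recursive driver: alternates right- and left-end extension each
#' iteration, explores alternate consensuses depth-first, detects cycles and
#' circular genomes, and enforces the branch and length budgets: once
#' `branchBudget` branches have been spawned for a seed, further alternate
#' children are discarded (lowest support first), so at `branchBudget = 1`
#' only the main consensus path is ever followed. The extension path
#' contains no randomness: identical inputs and configuration give identical
#' outputs.
#'
#' @param seed the seed contig (single-sequence `DNAStringSet`, `DNAString`,
#'   or named character string).
#' @param reads the read set (`DNAStringSet`, quality-scaled or not, or
#'   character vector); ignored when `readIndex` is supplied.
#' @param config an [ExtenderConfig-class].
#' @param readIndex optional prebuilt [buildReadIndex()] index (used by
#'   [extendAll()] to share one index across seeds).
#' @return list of final [ExtensionBranch-class] objects, sorted by contig
#'   length, longest first.
#' @examples
#' spec <- simulationSpec(genomeLength = 2000L, depth = 20, errorRate = 0,
#'                        seed = 7L)
#' genome <- simulateGenome(spec)
#' reads <- simulateReads(genome, spec)
#' seed <- sampleSeed(genome, 500L, 7L)
#' res <- runExtension(seed, reads)
#' res[[1]]
#' @export
runExtension <- function(seed, reads, config = extenderConfig(),
                         readIndex = NULL) {
  s <- .asSeqChr(seed, "seed")
  seedId <- names(s)
  if (is.null(readIndex)) readIndex <- buildReadIndex(reads, config@kmerSize)
  root <- .newBranch(unname(s), seedId)
  if (readIndex$n == 0L)
    return(list(.stopBranch(root, "no_overlaps")))
  cw <- if (config@cycleWindow == 0L) readIndex$maxLen else config@cycleWindow
  if (cw > readIndex$maxLen) {
    warning("cycleWindow exceeds the longest read length; clamping")
    cw <- readIndex$maxLen
  }
  if (nchar(s) < cw)
    warning("seed (", nchar(s), " bp) is shorter than the cycle window (", cw,
            " bp); cycle detection is weakened")
  root@historyLeft <- .terminusStr(root@contig, "left", cw)
  root@historyRight <- .terminusStr(root@contig, "right", cw)

  stack <- list(root)
  results <- list()
  nBranches <- 1L
  while (length(stack)) {
    b <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    while (b@stopReason == "active") {
      for (side in c("right", "left")) {
        if (b@stopReason != "active" || !.sideActive(b, side)) next
        lenBefore <- nchar(b@contig)
        children <- extendStep(b, side, readIndex, config)
        main <- children[[1L]]
        for (a in children[-1L]) {
          if (nBranches >= config@branchBudget) next # pruned, lowest support last
          nBranches <- nBranches + 1L
          if (a@stopReason == "active") a <- .postExtend(a, side, config, cw)
          if (a@stopReason == "active") {
            stack[[length(stack) + 1L]] <- a
          } else {
            results[[length(results) + 1L]] <- a
          }
        }
        if (main@stopReason == "active" && nchar(main@contig) > lenBefore)
          main <- .postExtend(main, side, config, cw)
        b <- main
      }
    }
    results[[length(results) + 1L]] <- b
  }
  results[order(-vapply(results, function(x) nchar(x@contig), numeric(1)))]
}

#' Extend a batch of seed contigs
#'
#' Per-seed results are independent (no shared mutable state); the read
#' k-mer index is built once and shared.
#'
#' @param seeds a `DNAStringSet` (or named character vector) of seed contigs
#'   with unique ids.
#' @param reads the read set.
#' @param config an [ExtenderConfig-class].
#' @return named list (one element per seed id) of lists of
#'   [ExtensionBranch-class] objects.
#' @export
extendAll <- function(seeds, reads, config = extenderConfig()) {
  if (is.character(seeds)) seeds <- Biostrings::DNAStringSet(seeds)
  if (length(seeds) == 0L) return(stats::setNames(list(), character()))
  ids <- names(seeds)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all seeds must be named")
  if (anyDuplicated(ids))
    stop("duplicate seed id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  idx <- buildReadIndex(reads, config@kmerSize)
  out <- lapply(seq_along(seeds), function(i) {
    runExtension(stats::setNames(as.character(seeds)[i], ids[i]),
                 reads = NULL, config = config, readIndex = idx)
  })
  names(out) <- ids
  out
}

#' Summarize extension results as a run-log table
#'
#' @param results output of [extendAll()] (or a bare [runExtension()] list).
#' @return data.frame with one row per final branch: `seedId`, `lineage`,
#'   `length`, `gained`, `iterations`, `circular`, `stop`.
#' @export
extensionSummary <- function(results) {
  if (length(results) && methods::is(results[[1L]], "ExtensionBranch"))
    results <- list(results)
  rows <- list()
  for (branches in results) {
    for (b in branches) {
      rows[[length(rows) + 1L]] <- data.frame(
        seedId = b@seedId, lineage = b@lineage, length = nchar(b@contig),
        gained = nchar(b@contig) - b@seedLength,
        iterations = b@iterations, circular = b@circular, stop = b@stopReason,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      seedId = character(), lineage = character(), length = integer(),
      gained = integer(), iterations = integer(), circular = logical(),
      stop = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Write final contigs as FASTA with the run-metadata header convention
#'
#' Headers follow
#' `">seedID|branch=<lineage>|len=<n>|circular=<bool>|stop=<reason>"`.
#'
#' @param results output of [extendAll()] (or a bare [runExtension()] list).
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
writeExtensionFasta <- function(results, path) {
  if (length(results) && methods::is(results[[1L]], "ExtensionBranch"))
    results <- list(results)
  seqs <- character()
  for (branches in results) {
    for (b in branches) {
      nm <- sprintf("%s|branch=%s|len=%d|circular=%s|stop=%s",
                    b@seedId, b@lineage, nchar(b@contig),
                    tolower(as.character(b@circular)), b@stopReason)
      seqs[[nm]] <- b@contig
    }
  }
  writeFasta(Biostrings::DNAStringSet(seqs), path)
}
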