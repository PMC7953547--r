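#' Accessors for ContigStretch S4 objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a ContigStretch S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("finalContig", function(x) standardGeneric("finalContig"))

#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @rdname accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname accessors
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname accessors
#' @export
setGeneric("extendedBases", function(x) standardGeneric("extendedBases"))

#' @rdname accessors
#' @export
setGeneric("ambiguousPositions", function(x) standardGeneric("ambiguousPositions"))

#' @rdname accessors
#' @export
setGeneric("voteScores", function(x) standardGeneric("voteScores"))

#' @rdname accessors
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))

#' @rdname accessors
#' @export
setGeneric("matrixOrigin", function(x) standardGeneric("matrixOrigin"))

#' @rdname accessors
#' @export
setGeneric("windowSequence", function(x) standardGeneric("windowSequence"))

#' @rdname accessors
setMethod("finalContig", "ExtensionBranch", function(x) x@contig)

#' @rdname accessors
setMethod("lineage", "ExtensionBranch", function(x) x@lineage)

#' @rdname accessors
setMethod("stopReason", "ExtensionBranch", function(x) x@stopReason)

#' @rdname accessors
setMethod("isCircular", "ExtensionBranch", function(x) x@circular)

#' @rdname accessors
setMethod("consensusSequence", "ConsensusCall", function(x) x@sequence)

#' @rdname accessors
setMethod("extendedBases", "ConsensusCall", function(x) x@extendedBases)

#' @rdname accessors
setMethod("ambiguousPositions", "ConsensusCall", function(x) x@ambiguousPositions)

#' @rdname accessors
setMethod("voteScores", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("voteCounts", "ScoreMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("matrixOrigin", "ScoreMatrix", function(x) x@origin)

#' @rdname accessors
setMethod("windowSequence", "TerminusWindow", function(x) x@sequence)

setMethod("show", "TerminusWindow", function(object) {
  cat(sprintf(
    "TerminusWindow %s/%s: %d bp\n", object@contigId, object@side,
    object@windowLength
  ))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf(
    "ScoreMatrix: %d columns at window coordinates %d..%d\n",
    ncol(object@scores), object@origin,
    object@origin + ncol(object@scores) - 1L
  ))
})

setMethod("show", "ConsensusCall", function(object) {
  cat(sprintf(
    "ConsensusCall: %d extended bases, %d ambiguous position(s)\n",
    object@extendedBases, length(object@ambiguousPositions)
  ))
})

setMethod("show", "ExtensionBranch", function(object) {
  cat(sprintf(
    "ExtensionBranch %s [%s]: %d bp, %d iteration(s)%s (stop: %s)\n",
    object@seedId, object@lineage, nchar(object@contig), object@iterations,
    if (object@circular) ", circular" else "", object@stopReason
  ))
})

setMethod("show", "ExtenderConfig", function(object) {
  cat("ExtenderConfig:\n")
  cat(sprintf("  tolerance        %.3g\n", object@tolerance))
  cat(sprintf("  minQuality       %d\n", object@minQuality))
  cat(sprintf("  minIdentity      %.2f\n", object@minIdentity))
  cat(sprintf("  minBranchSupport %d\n", object@minBranchSupport))
  cat(sprintf("  maxAlternates    %d\n", object@maxAlternates))
  cat(sprintf("  branchBudget     %d\n", object@branchBudget))
  cat(sprintf("  maxLength        %d bp\n", object@maxLength))
  cat(sprintf("  cycleWindow      %s\n",
    if (object@cycleWindow == 0L) "auto (longest read)"
    else paste0(object@cycleWindow, " bp")))
  cat(sprintf("  kmerSize         %d\n", object@kmerSize))
  cat(sprintf("  pairConstraint   %s\n",
    if (object@pairConstraint@enabled) "enabled" else "disabled"))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d bp %s genome, %gx %d bp %s reads, error %.3g%s%s (seed %d)\n",
    object@genomeLength, if (object@circular) "circular" else "linear",
    object@depth, object@readLength,
    if (object@paired) "paired" else "unpaired", object@errorRate,
    if (object@spikePeaks) ", spike-in peaks" else "",
    if (object@strain2Divergence > 0)
      sprintf(", two strains (%.3g)", object@strain2Divergence) else "",
    object@seed
  ))
})
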