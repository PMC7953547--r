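#' @import methods
#' @importFrom stats rnorm runif
#' @importFrom utils head read.delim write.table
NULL

.BASES <- c("A", "C", "G", "T")

#' TerminusWindow: the alignable end of a contig
#'
#' Only the prefix (left end) and suffix (right end) of a contig, each as long
#' as the longest read, can carry reads that overhang the contig and therefore
#' drive extension. A `TerminusWindow` captures one such end.
#'
#' @slot contigId identifier of the contig the window was cut from.
#' @slot side `"left"` or `"right"`.
#' @slot sequence the window sequence (prefix or suffix of the contig),
#'   uppercase over `A`,`C`,`G`,`T`,`N`.
#' @slot windowLength length of `sequence` in bases; equals
#'   `min(contig length, longest read length)`.
#'
#' @seealso [makeWindows()]
#' @exportClass TerminusWindow
setClass("TerminusWindow",
  representation(
    contigId = "character",
    side = "character",
    sequence = "character",
    windowLength = "integer"
  )
)

setValidity("TerminusWindow", function(object) {
  msg <- character()
  if (length(object@side) != 1L || !object@side %in% c("left", "right"))
    msg <- c(msg, "side must be \"left\" or \"right\"")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "window sequence must be a single non-empty string")
  else {
    if (nchar(object@sequence) != object@windowLength)
      msg <- c(msg, "windowLength must equal nchar(sequence)")
    if (grepl("[^ACGTN]", object@sequence))
      msg <- c(msg, "window sequence must be over {A,C,G,T,N}")
  }
  if (length(msg)) msg else TRUE
})

#' PairConstraint: optional mate-pair concordance filter
#'
#' When enabled, a recruited read whose mate places on the same window in a
#' discordant way (wrong relative orientation, or implied insert outside
#' `[minInsert, maxInsert]`) is discarded. A read whose mate is not placed at
#' all is kept: absence of evidence is not discordance. Disabled by default;
#' unconstrained paired-end extension is usually the better trade-off because
#' the insert-size filter removes the very reads that bridge difficult regions.
#'
#' @slot enabled logical flag.
#' @slot minInsert,maxInsert allowed insert-size range in bp (outermost
#'   coordinates of the pair).
#'
#' @export pairConstraint
#' @exportClass PairConstraint
setClass("PairConstraint",
  representation(enabled = "logical", minInsert = "integer", maxInsert = "integer")
)

setValidity("PairConstraint", function(object) {
  if (object@enabled && object@minInsert > object@maxInsert)
    "minInsert must be <= maxInsert when enabled" else TRUE
})

#' @param enabled logical.
#' @param minInsert,maxInsert insert-size range in bp.
#' @rdname PairConstraint-class
pairConstraint <- function(enabled = FALSE, minInsert = 0L, maxInsert = 1000L) {
  new("PairConstraint",
    enabled = isTRUE(enabled),
    minInsert = as.integer(minInsert), maxInsert = as.integer(maxInsert)
  )
}

#' ToleranceConfig: parameters of the extension threshold
#'
#' The consensus caller only writes a base at a position when the winning
#' score exceeds `10^(-tolerance) * readLength^2 * coverageEstimate`. The
#' tolerance `t` is dimensionless: larger `t` lowers the evidence bar (more
#' aggressive extension), smaller `t` is more conservative. `readLength` is
#' the longest read length l, and `coverageEstimate` c is a local estimate of
#' coverage at the terminus (total recruited read bases over the window span,
#' floored at 1).
#'
#' @slot tolerance dimensionless tolerance t (default 2.5).
#' @slot readLength longest read length l, bp.
#' @slot coverageEstimate local coverage estimate c, >= 1.
#' @slot minBranchSupport minimum number of reads that must agree on a
#'   second-best base (and later on a genotype) before a position counts as
#'   ambiguous.
#' @slot maxAlternates maximum number of alternate consensuses spawned per
#'   iteration, beyond the first.
#'
#' @export toleranceConfig
#' @exportClass ToleranceConfig
setClass("ToleranceConfig",
  representation(
    tolerance = "numeric",
    readLength = "integer",
    coverageEstimate = "numeric",
    minBranchSupport = "integer",
    maxAlternates = "integer"
  )
)

setValidity("ToleranceConfig", function(object) {
  msg <- character()
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
  if (object@coverageEstimate < 1) msg <- c(msg, "coverageEstimate must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param tolerance,readLength,coverageEstimate,minBranchSupport,maxAlternates
#'   see slot documentation.
#' @rdname ToleranceConfig-class
toleranceConfig <- function(tolerance = 2.5, readLength = 100L,
                            coverageEstimate = 1, minBranchSupport = 3L,
                            maxAlternates = 2L) {
  new("ToleranceConfig",
    tolerance = as.numeric(tolerance), readLength = as.integer(readLength),
    coverageEstimate = as.numeric(coverageEstimate),
    minBranchSupport = as.integer(minBranchSupport),
    maxAlternates = as.integer(maxAlternates)
  )
}

#' ScoreMatrix: per-position, per-base extension evidence
#'
#' For every position i covered by at least one recruited overlap and every
#' base j in `{A,C,G,T}`, `scores[j, i]` is the sum of squared overlap
#' qualities q_k^2 over the overlaps whose read carries base j at position i,
#' and `counts[j, i]` is the number of such reads. Columns are indexed in
#' window coordinates: column 1 sits at coordinate `origin` (0-based, position
#' 0 being the first base of the terminus window), so columns at coordinates
#' `>= windowLength` lie beyond the contig end.
#'
#' `N` bases vote for nothing: they contribute to no score and no count.
#'
#' @slot origin 0-based window coordinate of the first column.
#' @slot scores 4 x n numeric matrix, rows `A,C,G,T`.
#' @slot counts 4 x n integer matrix of supporting-read counts.
#'
#' @seealso [buildScoreMatrix()], [callConsensus()]
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(origin = "integer", scores = "matrix", counts = "matrix")
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (!identical(rownames(object@scores), .BASES) ||
      !identical(rownames(object@counts), .BASES))
    msg <- c(msg, "scores and counts must have rows A,C,G,T")
  if (!identical(dim(object@scores), dim(object@counts)))
    msg <- c(msg, "scores and counts must have identical dimensions")
  if (length(object@scores) && any(object@scores < 0))
    msg <- c(msg, "scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ConsensusCall: the called extension beyond a contig end
#'
#' @slot sequence the called bases beyond the contig end, truncated at the
#'   first position where no base cleared the extension threshold.
#' @slot extendedBases `nchar(sequence)`.
#' @slot ambiguousPositions 1-based positions within `sequence` where the
#'   second-best base also cleared the threshold with enough supporting reads
#'   (candidate strain/repeat branch points).
#'
#' @seealso [callConsensus()], [applyGenotype()]
#' @exportClass ConsensusCall
setClass("ConsensusCall",
  representation(
    sequence = "character",
    extendedBases = "integer",
    ambiguousPositions = "integer"
  )
)

setValidity("ConsensusCall", function(object) {
  msg <- character()
  if (object@extendedBases != nchar(object@sequence))
    msg <- c(msg, "extendedBases must equal nchar(sequence)")
  if (length(object@ambiguousPositions) &&
      (min(object@ambiguousPositions) < 1L ||
       max(object@ambiguousPositions) > object@extendedBases))
    msg <- c(msg, "ambiguousPositions must index into sequence")
  if (length(msg)) msg else TRUE
})

#' ExtenderConfig: all tunables of the extension driver
#'
#' @slot tolerance dimensionless threshold tolerance t (default 2.5).
#' @slot minQuality minimum overlap quality q_k (agreeing in-contig bases) for
#'   a read placement to be recruited (default 20).
#' @slot minIdentity minimum fraction of the in-contig span that must agree
#'   for the built-in scanner to keep a placement (default 0.8). This plays
#'   the role of an end-to-end aligner's acceptance criterion: a chance k-mer
#'   anchor on an unrelated read yields ~25% identity and is rejected here
#'   even when its absolute agreement count clears `minQuality`.
#' @slot minBranchSupport reads required to call a position ambiguous and to
#'   retain a genotype (default 3).
#' @slot maxAlternates alternate consensuses retained per iteration beyond the
#'   first (default 2).
#' @slot branchBudget maximum total branches per seed (default 16); excess
#'   children are pruned lowest-support-first.
#' @slot maxLength hard cap on extended contig length, bp (default 100000).
#' @slot cycleWindow terminus window length used for cycle/circularity
#'   detection; 0 (default) means "use the longest read length".
#' @slot kmerSize exact-seed anchor size of the built-in overlap scanner
#'   (default 12).
#' @slot pairConstraint a [PairConstraint-class] object.
#'
#' @seealso [runExtension()]
#' @export extenderConfig
#' @exportClass ExtenderConfig
setClass("ExtenderConfig",
  representation(
    tolerance = "numeric",
    minQuality = "integer",
    minIdentity = "numeric",
    minBranchSupport = "integer",
    maxAlternates = "integer",
    branchBudget = "integer",
    maxLength = "integer",
    cycleWindow = "integer",
    kmerSize = "integer",
    pairConstraint = "PairConstraint"
  )
)

setValidity("ExtenderConfig", function(object) {
  msg <- character()
  for (s in c("tolerance", "minQuality", "minBranchSupport", "maxAlternates",
              "branchBudget", "maxLength", "kmerSize")) {
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  }
  if (object@cycleWindow < 0L) msg <- c(msg, "cycleWindow must be >= 0")
  if (object@minIdentity < 0 || object@minIdentity > 1)
    msg <- c(msg, "minIdentity must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @param tolerance,minQuality,minIdentity,minBranchSupport,maxAlternates
#'   see slot documentation.
#' @param branchBudget,maxLength,cycleWindow,kmerSize,pairConstraint
#'   see slot documentation.
#' @rdname ExtenderConfig-class
extenderConfig <- function(tolerance = 2.5, minQuality = 20L, minIdentity = 0.8,
                           minBranchSupport = 3L, maxAlternates = 2L,
                           branchBudget = 16L, maxLength = 100000L,
                           cycleWindow = 0L, kmerSize = 12L,
                           pairConstraint = NULL) {
  if (is.null(pairConstraint))
    pairConstraint <- new("PairConstraint",
      enabled = FALSE, minInsert = 0L, maxInsert = 1000L)
  new("ExtenderConfig",
    tolerance = as.numeric(tolerance), minQuality = as.integer(minQuality),
    minIdentity = as.numeric(minIdentity),
    minBranchSupport = as.integer(minBranchSupport),
    maxAlternates = as.integer(maxAlternates),
    branchBudget = as.integer(branchBudget), maxLength = as.integer(maxLength),
    cycleWindow = as.integer(cycleWindow), kmerSize = as.integer(kmerSize),
    pairConstraint = pairConstraint
  )
}

#' ExtensionBranch: one node/leaf of the extension search tree
#'
#' @slot contig current (or final) contig sequence.
#' @slot seedId identifier of the seed contig this branch grew from.
#' @slot seedLength length of the seed contig, bp.
#' @slot lineage path identifier: `"root"` for the main path, with `.k`
#'   components appended by genotype rank at each branch point
#'   (e.g. `"root.1"`, `"root.1.2"`).
#' @slot circular `TRUE` when circularity was detected and the terminal
#'   overlap trimmed.
#' @slot stopReason one of `active`, `no_overlaps`, `cycle`, `circular`,
#'   `max_length`, `branch_budget`.
#' @slot iterations number of completed extension iterations.
#' @slot support read support of the genotype that spawned this branch
#'   (`Inf` for the main path), used for pruning under the branch budget.
#' @slot historyLeft,historyRight previously seen terminus windows per side,
#'   for cycle/circularity detection.
#' @slot leftActive,rightActive whether each side can still extend.
#' @slot sideReasons per-side stop reasons (internal bookkeeping for the
#'   branch-level `stopReason`).
#'
#' @seealso [runExtension()]
#' @exportClass ExtensionBranch
setClass("ExtensionBranch",
  representation(
    contig = "character",
    seedId = "character",
    seedLength = "integer",
    lineage = "character",
    circular = "logical",
    stopReason = "character",
    iterations = "integer",
    support = "numeric",
    historyLeft = "character",
    historyRight = "character",
    leftActive = "logical",
    rightActive = "logical",
    sideReasons = "character"
  )
)

setValidity("ExtensionBranch", function(object) {
  ok <- c("active", "no_overlaps", "cycle", "circular", "max_length",
          "branch_budget")
  if (!object@stopReason %in% ok)
    paste("stopReason must be one of:", paste(ok, collapse = ", ")) else TRUE
})

.newBranch <- function(contig, seedId) {
  new("ExtensionBranch",
    contig = contig, seedId = seedId, seedLength = nchar(contig),
    lineage = "root", circular = FALSE,
    stopReason = "active", iterations = 0L, support = Inf,
    historyLeft = character(), historyRight = character(),
    leftActive = TRUE, rightActive = TRUE,
    sideReasons = c(left = "", right = "")
  )
}

#' SimulationSpec: parameters of the shotgun read simulator
#'
#' Encodes the in-silico protocol used throughout: a uniformly random genome,
#' uniform read sampling (binomial coverage), independent per-base
#' substitution errors, optional coverage spike-in peaks (50x over 250 bp
#' anchored every 1 kb, emulating uneven coverage), optional circularity,
#' optional paired-end layout, and an optional two-strain mixture in which
#' half the reads derive from a diverged copy of the genome.
#'
#' @slot genomeLength genome length, bp.
#' @slot gcContent GC fraction of the random genome.
#' @slot circular simulate a circular genome (reads may wrap the origin).
#' @slot depth mean coverage depth, x.
#' @slot readLength read length, bp.
#' @slot errorRate per-base substitution probability.
#' @slot paired emit paired reads (`/1` forward, `/2` reverse-complement).
#' @slot insertMean,insertSd insert size distribution for paired reads, bp.
#' @slot spikePeaks add reads over 250 bp intervals anchored every 1 kb so
#'   those intervals reach 50x.
#' @slot strain2Divergence per-base divergence of a second strain; 0 disables
#'   the mixture.
#' @slot seed RNG seed; all randomness of a simulate call flows from it.
#'
#' @seealso [simulateGenome()], [simulateReads()], [sampleSeed()]
#' @export simulationSpec
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    genomeLength = "integer",
    gcContent = "numeric",
    circular = "logical",
    depth = "numeric",
    readLength = "integer",
    errorRate = "numeric",
    paired = "logical",
    insertMean = "numeric",
    insertSd = "numeric",
    spikePeaks = "logical",
    strain2Divergence = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be >= 1")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@readLength > object@genomeLength)
    msg <- c(msg, "readLength must be <= genomeLength")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must be in [0,1]")
  if (object@strain2Divergence < 0 || object@strain2Divergence >= 1)
    msg <- c(msg, "strain2Divergence must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param genomeLength,gcContent,circular,depth,readLength,errorRate
#'   see slot documentation.
#' @param paired,insertMean,insertSd,spikePeaks,strain2Divergence,seed
#'   see slot documentation.
#' @rdname SimulationSpec-class
simulationSpec <- function(genomeLength = 11900L, gcContent = 0.5,
                           circular = FALSE, depth = 20, readLength = 100L,
                           errorRate = 0.01, paired = FALSE,
                           insertMean = 500, insertSd = 50,
                           spikePeaks = FALSE, strain2Divergence = 0,
                           seed = 1L) {
  new("SimulationSpec",
    genomeLength = as.integer(genomeLength), gcContent = as.numeric(gcContent),
    circular = isTRUE(circular), depth = as.numeric(depth),
    readLength = as.integer(readLength), errorRate = as.numeric(errorRate),
    paired = isTRUE(paired), insertMean = as.numeric(insertMean),
    insertSd = as.numeric(insertSd), spikePeaks = isTRUE(spikePeaks),
    strain2Divergence = as.numeric(strain2Divergence), seed = as.integer(seed)
  )
}
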