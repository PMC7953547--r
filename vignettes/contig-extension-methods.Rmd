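---
title: "Seeded contig extension: model, parameters and design notes"
author: "ContigStretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded contig extension: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContigStretch)
```

## The problem

Metagenomic de novo assemblers (metaSPAdes and kin) rarely produce viral
contigs longer than a few kb: coverage valleys, sequencing errors and strain
mixtures terminate De Bruijn graph traversal early, even when reads that
overlap a contig's ends are plainly present in the data. ContigStretch
automates the manual rescue that virologists otherwise perform by hand:
iteratively recruit reads overlapping each contig terminus, vote on the bases
beyond the end, append them, and repeat until no further evidence exists.

The package contains three coordinated parts:

* the extender itself (`runExtension()`, `extendAll()`, and the lower-level
  `findTerminusOverlaps()`, `buildScoreMatrix()`, `callConsensus()`,
  `enumerateGenotypes()`),
* a shotgun read simulator (`simulateGenome()`, `simulateReads()`,
  `sampleSeed()`) that reproduces the benchmark conditions in code, and
* an evaluation harness (`gainedMetrics()`, `largestAlignedSegment()`,
  `evaluateContig()`) that scores outputs against a known reference.

## The extension model

### Overlap recruitment

Only the prefix and the suffix of the contig can carry extending reads, so
alignment is restricted to terminus windows of length
`min(contig length, longest read length)` (`makeWindows()`). Every read is
tested in both orientations; candidate placements are anchored on exact
k-mers (k = 12 by default) and scored ungapped. A placement's quality

\[ q_k = \#\{\text{in-contig positions where read and contig agree}\} \]

counts agreeing bases only over the part of the read inside the contig;
overhanging bases are ignored, and `N` never agrees. Placements must
overhang the end by at least one base (reads wholly inside the contig cannot
extend it), reach `minQuality` (default 20 agreeing bases), and agree on at
least `minIdentity` (default 80%) of their in-contig span.

The identity floor deserves a note. The placement search plays the role an
end-to-end aligner plays in an alignment-backed deployment (`ingestSam()`
accepts SAM records from such an aligner instead). An aligner would never
report a placement that matches a quarter of its bases; a raw k-mer anchor
occasionally would, since an unrelated read sharing one chance 12-mer with
the window agrees on ~25% of the remaining span, which can clear an absolute
count of 20 when the span is long. The identity floor restores the aligner's
behaviour; without it, a dead terminus (zero genuine coverage) can acquire a
short junk extension from exactly such a placement.

Ungapped placement is a deliberate restriction: the consensus model votes
one column per position and has no indel representation, so gapped overlaps
could not be consumed downstream anyway. Indel-aware extension is out of
scope; the substitution-dominated error profile of short-read platforms is
what the scoring is built for.

### Quality-squared consensus

Recruited placements are aggregated into a score matrix: for position `i`
and base `j`,

\[ Q[i][j] = \sum_{k:\ R_k[i]=j} q_k^2 , \]

summing squared qualities of the reads voting `j` at `i`
(`buildScoreMatrix()`; reads also carry a per-base supporting-read count).
Squaring makes a long, well-anchored overlap worth more than several
marginal ones, which is what lets extension cross low-coverage valleys
without a hard depth cutoff.

The consensus base at each position beyond the contig end is the argmax of
`Q[i][ ]` provided it exceeds the threshold

\[ \text{threshold} = 10^{-t}\, l^2\, c , \]

with tolerance `t` (default 2.5, dimensionless), `l` the longest read length
(bp) and `c` a local coverage estimate. Larger `t` lowers the evidence bar
(aggressive, longer but riskier extension); smaller `t` is conservative.
Because thresholds scale with `l^2 c` while a column's score is roughly
(number of covering reads) x (overlap length)^2, the criterion is
self-normalizing: at any depth, extension survives out to overlaps of length
about `l * 10^(-t/3)`. At the first position where no base clears the
threshold the call truncates - undefined positions are not N-filled, because
the next iteration re-aligns against the grown terminus and re-votes those
columns with fresh evidence.

Two choices here were genuinely open:

* **Coverage estimate `c`.** Defined nowhere in the printed formula's terms,
  it is computed locally as (total recruited read bases) / (window length),
  floored at 1 and recomputed every iteration. A local estimate keeps the
  threshold proportionate in coverage valleys and spike regions alike.
* **Tie-breaking.** Argmax ties break in fixed `A<C<G<T` order so that runs
  are byte-for-byte deterministic.

### Ambiguity, genotypes and DFS branching

A called column is *ambiguous* when the second-best base also clears the
threshold and at least `minBranchSupport` reads (default 3) carry it - the
signature of a strain mixture or a repeat, as opposed to scattered
sequencing error. (The read-count requirement matters: at a 5% error rate a
single full-length erroneous read has `q^2` large enough to clear the
threshold on its own, but three reads sharing the same substitution at the
same column are vanishingly unlikely unless a second haplotype is real. The
second-best base is compared against the same threshold as the winner; the
specification of a separate second threshold was left open, and equal
thresholds are the parsimonious choice.)

Each read covering *all* ambiguous positions of a call is restricted to
exactly those positions, giving that read's joint genotype
(`enumerateGenotypes()`). Genotypes are ranked by supporting read count,
thresholded at `minBranchSupport`, capped at `maxAlternates` (default 2)
beyond the first, and each surviving genotype is written over the call
(`applyGenotype()`) to spawn an alternate consensus. The driver explores
these branches depth-first, so each strain (or repeat copy) gets its own
extension path instead of derailing the main one. Genotypes are linked only
within one iteration's call window; phasing across iterations is a
non-goal, so two heterozygous sites further apart than one call can in
principle recombine across branches.

Genotype support is counted in raw reads, not quality-weighted reads - the
ranking is a frequency argument, and weighting would double-count the
quality information already spent on the ambiguity decision.

### Termination: exhaustion, cycles, circular genomes

A branch side stops when no placement overhangs it, or when no base clears
the threshold. Additionally, after each growth step the terminal
`cycleWindow` bases are compared against every terminus seen before on that
branch (`detectCycle()`):

* same-side repeat → `cycle`: the extension would loop forever through the
  identical alignments;
* opposite-side repeat, or the terminal window recurring verbatim anywhere
  else in the contig → `circular`: the growing end has wrapped onto the
  opposite end. The contig is trimmed by one `cycleWindow` so the terminal
  overlap appears exactly once and the branch is flagged circular.

`cycleWindow` defaults to the longest read length: that is the scale at
which alignments repeat exactly once a loop closes, and random viral-size
genomes essentially never contain exact repeats that long, so a repeated
window is a reliable wrap signal. Genomes with long exact repeats (not the
viral regime this targets) could trigger a false circular call; lowering
`cycleWindow` below the repeat length is not advisable for the same reason.

Budgets bound the search: `maxLength` (default 100 kb - deliberately
desk-scale; raise it for large targets such as a ~236 kb herpesvirus)
trims and stops a branch, and `branchBudget` (default 16) caps the total
branches per seed. Once the budget is full, further alternate children are
discarded lowest-support-first, so `branchBudget = 1` follows exactly the
main consensus path and returns exactly one contig per seed.

### Side alternation and strand symmetry

Each iteration extends the right end, then the left, for every active
branch. The two ends are independent evidence-wise; alternation simply
keeps branch trees balanced. Internally only right-end extension exists:
the left end is handled by reverse-complementing the contig, extending, and
reverse-complementing back, which halves the code surface and makes strand
symmetry (extending the reverse-complemented seed yields reverse-
complemented outputs) a tested property rather than a hope. Reads are never
consumed: sibling branches may recruit the same read, which is what allows
repeats and strain mixtures to be followed down every path.

## The simulator

`simulateReads()` emulates ideal shotgun sequencing: read count
`round(depth * G / l)`, uniform start positions (wrapping the origin for
circular genomes), strand flips with probability 1/2, and i.i.d.
substitutions at `errorRate` (always to a different base). Coverage is
therefore binomial per position - at 10x mean depth, positions at 1-2x
arise by chance, which is precisely the failure mode that terminates
assemblers and that the benchmarks probe. Optional features mirror the
benchmark protocol: 250 bp spike-in peaks anchored every 1 kb raised to 50x
coverage (additive over background; whether the original spike-ins replace
or add to background was unstated, and additive is the simpler reading),
two-strain mixtures (half the reads from a diverged genome copy), and
paired layouts (`/1` forward, `/2` reverse-complement, insert
~ Normal(`insertMean`, `insertSd`) clamped to at least one read length).

What the simulator does *not* model - indels, GC-coverage bias, quality
score profiles, chimeric library artifacts - bounds what passing tests
prove: they validate the algorithm against its stated error model, not
against every artifact of a real Illumina run. Adapter-like contamination
is covered indirectly: a read with a random tail aligns poorly wherever the
tail lands, so it either fails recruitment or is outvoted; it cannot form a
genotype because its junk appears at a random position, never in three
reads at the same columns.

All randomness flows from the spec's single seed through an isolated RNG
scope (`withr::with_seed`), so the simulator never perturbs - and is never
perturbed by - the session RNG. The extension path itself draws no random
numbers at all.

## Evaluation

`gainedMetrics()` is the benchmark-table arithmetic (gained length, percent
of seed, percent of genome). `largestAlignedSegment()` replaces a BLAST
search with a self-contained aligner so that tests need no external binary
or database: exact 15-mer matches between contig (both strands) and
reference (doubled when circular) are clustered by diagonal (drift at most
10 bp, so larger indels split segments), chained along the contig (seed
gaps up to 100 bp, far beyond anything a 5% substitution rate produces),
and verified ungapped at the dominant diagonal with a 95% identity floor.
These parameters are declared, not inferred from any external tool's
defaults. A contig whose largest single aligned segment covers less than
98% of it is flagged chimeric (`evaluateContig()`), matching the
nearly-perfect-alignment convention used to screen real extensions;
the cutoff is a parameter.

## Problem sizes in the test suite

The shipped tests run entirely on simulated data chosen to mirror the
benchmark conditions at sizes a laptop handles comfortably: the
reconstruction suites use the 11.9 kb genome / 100 bp / 20x / 1 kb-seed
setting at both 1% and 5% error (ten seeded trials each), the circular
fixture is a 1 kb plasmid at 20x, strain-branching uses a 1.5 kb two-strain
mixture at 10x per strain, and the accuracy-under-low-coverage run uses
11.9 kb at 10x with error-free reads. The last choice is deliberate: with
substitution errors present, a coverage valley crossed by a single witness
read necessarily copies that read's errors (any consensus caller would),
so the genome-exactness assertion isolates what it is meant to test -
that low coverage truncates extension rather than inducing mis-joins.

## Known limitations

* No indel handling anywhere in the scoring path.
* Phred qualities are carried through I/O but never weighted into `q_k`,
  which is a pure agreement count by definition.
* Genotype linkage does not extend across iterations.
* Circularity detection assumes exact terminal windows; a genome whose wrap
  region mutated between passes (impossible here, possible with real
  strain mixtures) would fall back to cycle detection.
* Optimized for viral genome scale (kb to hundreds of kb) and viral repeat
  content; bacterial/eukaryotic repeat structures will branch heavily and
  the budget will truncate the search.
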