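---
title: "Streaming analysis of multiple genome alignments with mafstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming analysis of multiple genome alignments with mafstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafstream)
```

## The problem

Whole-genome multiple alignments record homologous positions across two or
more genomes. Because genomes rearrange, such alignments are not one long
matrix but a series of *synteny blocks* — rearrangement-free regions, each
stored as a small alignment with per-row genomic coordinates, strands and
optional base-quality scores, in the UCSC Multiple Alignment Format (MAF).
Files routinely reach gigabytes, so any practical processor must stream:
read one block, transform it, hand it on, forget it.

`mafstream` implements that model. A *source* (a MAF or whole-genome Fasta
file) yields blocks one at a time; *filters* are composable operators that
consume a lazy block stream and emit one; *sinks* (MAF, Fasta/Clustal/
Phylip, Newick, CSV, VCF writers) ride along inside the chain. A pipeline
is either assembled programmatically or described in a `key=value` option
file and run from the `mafstream` command line.

## Coordinate model

All internal interval arithmetic is 0-based half-open on the forward
strand, following the MAF conventions:

* `start` is strand-relative: for a `-` strand row it counts from the
  start of the reverse-complemented source sequence.
* `size` counts residues (non-gap characters); `src_size` is the full
  chromosome length. A `-` row's forward-strand footprint is the
  reflection `[src_size - start - size, src_size - start)`
  (`to_plus_strand_interval()`).
* Exported alignment rows are named
  `species.chromosome/first-last(strand)` with 1-based inclusive
  forward-strand positions. This "Ensembl-style" dialect is pinned and
  parseable (`parse_coord_header()`) because downstream tools must be able
  to recover provenance exactly; it is our own definition, documented
  rather than guessed.
* In the R API, alignment *columns* are 1-based inclusive (`subblock(b, 4,
  5)` behaves like `substr`), which is the idiomatic choice for R users;
  genomic coordinates remain 0-based as above.

Quality scores are stored gap-expanded — one integer per column with a
sentinel `-1` at gaps — so that every column-slicing operation treats text
and scores uniformly. MAF `q` lines are converted on read and write
(digits, `F` = 99, `-` at gaps).

## Design choices in the filters

**Block scores are dropped by column-modifying filters.** A MAF `a score=`
value is an aligner-specific total for the whole block; no principled
rescaling exists for a fragment, so `subblock()` and everything built on
it discard it rather than emit a misleading number.

**Merging.** Two consecutive blocks merge when every focal species occurs
exactly once in both, on the same chromosome and strand, separated by
`0..max_dist` bases. The bridged gap is *unknown sequence*, not deletion,
so focal rows are filled with `N`; focal species sharing the same gap
distance share one inserted segment. Non-focal rows are joined with `-`
fill when their own coordinates are compatible and `-`-padded otherwise.
Merging is greedy left-to-right, so whole syntenic runs collapse into one
block.

**Window cleaning.** `flt_sliding_window_clean()` slides a window of
`window_size` columns by `step` and flags windows by one of five
predicates: total gap count, gap-opening events (maximal gap runs, the
stricter variant used to catch alignment breakpoints), count of
high-entropy columns (Shannon entropy over A/C/G/T frequencies, gaps and
`N` excluded rather than treated as a fifth state — the standard practice),
soft-mask (lowercase) count, and mean quality. Failing windows are merged
into maximal runs before excision, avoiding fragment shredding, and
tie-breaking is deterministic left-to-right. One subtlety: when
`step < window_size`, fragments have their own window offsets, so a single
excision pass cannot guarantee that no failing window remains; the filter
therefore re-scans each fragment and iterates to a fixed point. This
terminates (fragments strictly shrink) and is what makes the
"no failing window after cleaning" invariant hold unconditionally. With
`action = "mask"` failing regions are overwritten with `N` instead (gaps
are left in place, so coordinates remain exact); the removal invariant
does not apply to masking, since masking cannot change gap structure.

**Duplicate species.** `flt_subset(remove_duplicates = TRUE)` drops the
whole block when a focal species occurs twice. Paralogy is the usual cause,
and silently picking one row corrupts downstream genealogies; `keep_first`
is available when the user knows better.

**Thresholds are inclusive** ("keep if compliant"): a 300-column block
passes `MinBlockLength(min_length=300)`.

**Errors abort.** The pipeline engine stops at the first filter error,
reporting the block ordinal; skipping blocks silently is worse than
failing in genomic pipelines. Recoverable oddities (a block missing the
reference species, a quality filter on unscored data) instead pass the
block through with a warning, as documented per filter.

## Statistics

A "complete" site has no gap and no ambiguity in the rows under
consideration; for group statistics this is evaluated over the group's
rows only. Parsimony-informative sites require two states each carried by
two rows, with gap/`N` not counted as states (a flag enables the
five-state variant). Pairwise divergence is reported in percent.
Watterson's estimator is `S / a_n`, `a_n = sum(1/i, i < n)`, per block by
default and per complete site on request. The unfolded site-frequency
spectrum uses strictly biallelic ingroup columns and polarizes by the
outgroup allele; columns where the outgroup carries a third allele are
counted as unpolarizable, monomorphic or multi-allelic columns as ignored,
so the histogram total always equals the polarizable-site count.
Multi-allelic columns still count toward `S` — the standard definitions.

## Phylogenetics

Distances use the Kimura two-parameter closed form
`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` over columns where both rows
are unambiguous. When a logarithm argument is non-positive the pair is
*saturated* and the distance is `NA`; tree building refuses `NA` matrices
outright instead of imputing, because silently imputed distances corrupt
block-wise genealogies — the user is told to filter such blocks upstream.
Neighbor joining follows the Saitou–Nei Q criterion with the standard
branch-length formulas; BioNJ adds the variance-weighted reduction;
UPGMA/WPGMA produce rooted ultrametric trees. Tie-breaking is by lowest
index pair, so all trees are deterministic; negative branch-length
estimates are clamped to zero (standard practice). Rerooting on an
outgroup splits the outgroup's terminal branch at its midpoint, preserving
all path lengths.

## The synthetic-data module

Tests and demonstrations need data with known ground truth, not
multi-gigabyte downloads. Three generators cover this:

* `simulate_k80_block()` evolves a uniform root sequence down a tree using
  the exact K80 transition probabilities per branch (closed form, not
  Gillespie — deterministic per seed and faster). `kappa` is the
  transition/transversion *rate* ratio; the default `kappa = 4` yields the
  2:1 expected transition:transversion *count* ratio typical of nuclear
  DNA, and is what the estimator-recovery tests use at the reference
  distance 0.17018. Gaps, soft-masking and quality scores are injected
  post hoc — there is deliberately no indel evolution model.
* `make_synteny_fixture()` emits blocks with programmed inter-block
  distances, plus a paired GFF3, and returns its own ledger of what
  downstream filters must produce (number of blocks after merging, block
  starts, total columns), so tests assert against the generator's
  bookkeeping. Species rows are copies of a per-block ancestral sequence
  at 5% default divergence — realistic enough that distance estimation on
  fixtures does not saturate.
* `make_topology_mixture()` produces quartet tree sets with exact
  largest-remainder apportioned counts, shuffled by seed, for validating
  topology tallies.

What a green test on this synthetic world does **not** establish: realism
of indel structure (gaps are i.i.d., real gaps cluster), of rearrangement
breakpoints (fixtures are colinear), or of base composition and rate
heterogeneity (K80 is homogeneous). The generators state the world the
tests run in; conclusions about real alignments need real alignments.

## Numerical and degenerate-input policy

* Entropy uses log base 2 with `0 * log 0 = 0`; all-gap columns have
  entropy 0.
* Internally assembled Newick strings carry 17 significant digits, so
  path-length round-trips are exact to ~1e-12.
* An empty block has length 0; `subblock` rejects inverted or
  out-of-range bounds as caller bugs.
* zip archives: reading takes the first member and buffers it (zip is not
  stream-decompressable through R connections); writing produces a
  single-member archive assembled in-package (DEFLATE payload from
  `memCompress`, CRC32 computed internally). gzip and bzip2 stream both
  ways.
* The MAF `src` field splits into species and chromosome at the *first*
  dot; a dot-free `src` is used as both (degenerate single-genome files).

## Limitations

No realignment, no indel-aware merging across rearrangements, no MAF
`e`/`i` line semantics, no maximum-likelihood trees, no Tajima's D, no
parallel execution. Concatenation across non-contiguous blocks flags its
output `coordinateless`; coordinates of non-ingroup rows become
approximate after ingroup-gap-column removal — both are inherent to the
operations, not bugs, and are documented on the respective filters.
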