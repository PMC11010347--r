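---
title: "splitkit: models and methods for SPLiT-seq barcode processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splitkit: models and methods for SPLiT-seq barcode processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitkit)
```

## The problem

SPLiT-seq (split-pool ligation-based transcriptome sequencing) identifies
each cell by the *combination* of three barcodes ligated in successive
split-pool rounds, separated by fixed linker sequences, rather than by a
single synthesized bead barcode. With $b$ barcodes per round and $r$
rounds the combinatorial space holds $b^r$ cell barcodes
(`max_unique_barcodes(96, 3)` = 884,736). The price of this design is paid
at analysis time: the cell barcode (CB) must be reassembled from three
elements read at different positions of a structured barcode read, each of
which may carry sequencing errors.

splitkit provides a laboratory for exactly this preprocessing step. It

1. **simulates** truth-labelled paired reads whose barcode elements carry a
   controlled substitution-error burden,
2. **demultiplexes** them with the three extraction-strategy families used
   by published SPLiT-seq pipelines, followed by whitelist error
   correction,
3. **quantifies** corrected reads into a sparse UMI count matrix (with
   random-hexamer collapsing and a read-support cell filter), and
4. **benchmarks** each strategy against the simulated ground truth.

It deliberately does *not* align reads to a genome; read 1 carries one of
eight synthetic 120-base feature references so that feature assignment is
an identity lookup and every downstream difference is attributable to
barcode handling.

## Read geometry

The barcode read (read 2) is the concatenation, in order, of UMI, BC3,
LINKER2, BC2, LINKER1, BC1. All coordinates in the package are 0-based
half-open; the published positional configurations ("BC3 at 10–17",
1-based variants "11–18") are inclusive index ranges and convert to the
spans below:

```{r layout}
build_layout(chemistry("v2"))
build_layout(chemistry("v1"))
```

The v1/v2 protocol versions differ only in the length of linker 1 (30 vs
22 nt), which shifts BC1 from span [86,94) to [78,86). The linker
*sequences* are not structurally constrained, only their lengths; the
package ships fixed default sequences and accepts overrides, so that the
toolkit is self-contained without claiming any vendor's proprietary
oligos.

## Whitelists and minimum-distance codes

Correction at Hamming distance $\le d$ is unambiguous precisely when the
whitelist's minimum pairwise separation exceeds $2d$. Two presets ship:

* **realistic** — 96 barcodes per round at minimum pairwise Hamming
  distance 3, built by seeded greedy rejection sampling
  (`generate_whitelist()`): candidates are drawn uniformly and accepted if
  they keep the running minimum distance. This emulates the density of
  commercial plate sets, where 2-substitution errors can land within
  distance 2 of a *wrong* barcode.
* **guarantee** — 16 barcodes per round at minimum distance exactly 6.
  Separation 6 makes outcomes analytically forced: a 2-substitution mutant
  is at distance 2 from its origin and $\ge 4$ from everything else
  (unique correction), while a 3-substitution mutant is at distance
  $\ge 3$ from every entry (guaranteed failure). The acceptance checks of
  the package lean on this preset because expected values are exact.

The guarantee preset is a *constructed* code rather than a greedy one:
greedy rejection at length 8 stalls around 14–16 accepted barcodes for
distance 6, far short of a full plate, and there is no randomness worth
having in a code whose purpose is to force outcomes. We take the 16
codewords of a shortened quaternary Hamming code of length 4 (minimum
distance 3) and double every base, which doubles pairwise distances to
exactly 6.

The same construction, at length 10, supplies the simulator's **UMI
code**: a shortened quaternary Hamming code with $4^{10-3} = 16{,}384$
codewords at minimum distance 3, sampled by seed. Greedy rejection *can*
reach 10,000 such UMIs but needs roughly $7\times10^5$ candidate draws
(minutes of runtime per dataset); the linear code is instant and its
distance property is a theorem rather than an audit. The code is built
once and reused across cells — the distance constraint only matters within
a cell, where it prevents distinct molecules from being merged by
UMI-collapsing heuristics downstream.

## The synthetic dataset

`sim_config()` defaults encode the synthetic study design: 500 cells,
10,000 reads per cell, read 1 of 120 bases, eight equally likely read
categories:

| category | elements mutated | substitutions per element |
|---|---|---|
| `perfect` | 0 | – |
| `correctable_1/2/3` | exactly 1 / 2 / 3 | 2 |
| `uncorrectable_1/2/3` | exactly 1 / 2 / 3 | 3 |
| `random` | whole read 2 randomized | – |

The substitution counts sit exactly on the correction boundary (the
correction distance is 2 everywhere): "correctable" means *at most* 2
errors per element and is simulated at exactly 2; "uncorrectable" means
*at least* 3 and is simulated at exactly 3. Both are configurable, but the
boundary values are the default because they are the hardest instances of
each class. Which elements are hit is drawn uniformly; substituted
positions are drawn without replacement and the new base always differs
from the old one, so per-element Hamming distances from truth are exactly
0, 2 or 3 by category — an invariant the test suite audits over whole
datasets.

Design choices worth stating explicitly:

* **Cells are distinct after hexamer collapsing.** Each synthetic cell
  draws one fixed round-1 barcode (oligo-dT or random-hexamer half of the
  plate) and cells are sampled without replacement *in the collapsed
  space*, so the collapsed matrix should contain exactly `n_cells` cells.
* **Category `random` randomizes read 2 only.** Read 1 keeps the
  category's feature sequence, so the fate of these reads remains
  traceable in the count matrix; whether the original design randomized
  one or both mates is underdetermined, and randomizing read 2 is the
  choice that actually stresses the demultiplexer.
* **Read 1 is error-free and qualities are constant** (`I`, Q40). Feature
  retrieval is meant to be trivial; the analysis ignores base qualities.
* **Remainders round-robin.** When `reads_per_cell` is not divisible by
  the category mix, leftover reads are assigned one each to the leading
  categories in order, so counts are deterministic.
* Every read name encodes its full truth record
  (`SK<serial>:<cell>:<category>:<bc1>:<bc2>:<bc3>:<umi>:<feature>`);
  `parse_read_name()` inverts `encode_read_name()` exactly, and a
  `truth.tsv` sidecar carries the same fields.

The simulator is a deterministic function of its configuration: identical
config and seed give byte-identical FASTQ, matrices and reports.

## Extraction strategies

Published SPLiT-seq demultiplexers fall into three algorithmic families,
all implemented here behind a common call interface:

1. **Fixed position** (`extract_fixed()`): slice elements at their
   theoretical spans. Fast, position-rigid.
2. **Linker-anchored** (`extract_linker_aligned()`): place each linker by
   best Hamming score within ±`max_shift` (default 3) bases of its
   theoretical position and re-derive element spans from the placements
   (UMI and BC3 hang off linker 2; BC2 and BC1 off linker 1). Ties prefer
   the theoretical position, then the nearest, then the leftmost
   placement. A linker whose best mismatch rate exceeds
   `max_mismatch_rate` (default 20%) fails the read. The window and budget
   are our parameters — published tools do not print theirs — and both are
   exposed as options.
3. **Whitelist alignment** (`extract_bc_aligned()`): score every whitelist
   entry concatenated with an `anchor_length` fragment of the adjoining
   linker near the theoretical span; the best unique hit within
   `max_mismatch` total mismatches fixes the element *position*, and the
   element sequence is the read's bases at that position. Equal best
   scores from different entries leave the element unassigned
   (`ambiguous`) rather than arbitrarily resolved.

On substitution-only reads with intact linkers the first two strategies
are exactly equivalent, and all three agree on every read they assign.
They differ by design at the margins: only the aligning strategies survive
position shifts (tested with a 1-base prepended read), and whitelist
alignment cannot return an element farther than its mismatch budget from
every whitelist entry, so uncorrectable elements surface as `not_found`
rather than as an extracted-but-uncorrectable sequence.

## Correction

`correct_element()` corrects each element independently against its round
whitelist ("errors per barcode element"), taking the unique entry at
minimal distance $\le$ `max_distance` (default 2, the setting used across
pipelines). Tied minima within range are rejected as ambiguous —
conservative, and the only choice that never miscorrects silently. The
default metric is Hamming: the error model is substitution-only, and on
substitutions Hamming and Levenshtein coincide at these distances;
Levenshtein (via `utils::adist`) is available by flag for indel-bearing
data. A read is `assigned` only when all three elements correct uniquely.

## Quantification

* **Hexamer collapsing** (`collapse_hexamer_index()`,
  `collapse_matrix()`): round-1 indices above `hexamer_split` (default 48
  of 96) are the random-hexamer twins of the oligo-dT barcodes in the same
  wells; collapsing subtracts the split and merges the resulting duplicate
  cells by row summation. The operation conserves totals exactly and is
  idempotent.
* **UMI deduplication** is exact-match: the simulator's distance-3 UMI
  code makes near-match merging unnecessary by construction. This is a
  deliberate divergence from tools that collapse UMIs at distance 1, and
  it is why the simulator enforces the within-cell distance in the first
  place.
* **Feature assignment** (`assign_feature()`) takes the best unique
  reference at positional identity $\ge$ 0.9. The eight references are
  kept mutually $\ge 25\%$ divergent, so the threshold is far from both
  the match and the mismatch distributions.
* **Cell filter** (`filter_cells()`): keep cells with *strictly more*
  than `min_reads = 100` assigned reads. Reads, not UMIs, are counted —
  matching the phrase "reads assigned to them" — and the strict reading
  of "more than" is tested at the 100/101 boundary.

## Benchmarking

`join_truth()` labels each read `correct` (called CB equals truth),
`miscorrected` (called but wrong) or `dropped`. **Captured = correct
only**; miscorrections are reported separately rather than folded into
capture, because the two failure modes have opposite remedies (the sum
recovers the looser definition when needed). `capture_rates()` aggregates
by category or by correctability group (perfect + correctable vs
uncorrectable, with `random` kept apart); `barcode_recovery()` is the set
comparison (found / missed / spurious) of matrix cells against truth
cells; `strategy_overlap()` produces exclusive (upset-style) intersection
counts whose rows sum to the union; `cell_stats()` reports genes and UMIs
per cell with midpoint-mean medians.

Under the guarantee preset the per-read outcomes are analytically forced —
capture 1.0 for perfect + correctable categories, 0.0 for uncorrectable —
and the acceptance suite asserts them exactly. One statistic is forced
only *after* the cell filter: a fully randomized barcode read slices into
three random 8-mers, and each lands within distance 2 of some
separation-6 whitelist entry with probability $16 \cdot 277 / 4^8 \approx
6.8\%$ (the radius-2 balls around a distance-6 code are disjoint), so a
whole random read assigns somewhere by chance with probability
$\approx 3 \times 10^{-4}$ — roughly one spurious singleton cell per few
thousand random reads. Unfiltered recovery is therefore asserted as
found = `n_cells`, missed = 0 with spurious cells bounded to sub-filter
singletons, and exact (`n_cells`, 0, 0) recovery is asserted with the
default > 100-read filter, which such singletons can never pass. Under
the realistic preset outcomes are no longer forced at all (a
2-substitution mutant can tie between entries) and only the monotonicity
correctable $\ge$ uncorrectable is asserted.

## Problem sizes and determinism

The test suite runs the simulator at full design scale (500 × 10,000
reads) once, audits error structure on a 100,000-read prefix and UMI
separation on an exhaustive 2,000-UMI sample of one cell, and uses small
configurations (tens of cells, tens to hundreds of reads per cell)
everywhere outcomes are scale-invariant. The corrector is cross-checked
against a brute-force distance scan on $10^4$ random instances. All
randomness flows from explicit seeds; rerunning any artifact-producing
step with the same configuration reproduces it byte for byte (provenance
files record the configuration echo, seed and package version, and no
timestamps, for exactly this reason).

## Known limitations

* The error model is substitution-only: no indels, no quality-dependent
  errors, no PCR duplication, no ambient RNA or doublets. Passing the
  forced-outcome checks therefore says nothing about indel robustness —
  use the Levenshtein metric and the aligning strategies on real data
  where indels matter.
* Feature assignment replaces genome alignment; results on real
  transcriptomes additionally depend on the aligner and counting method,
  which this package intentionally excludes.
* The shipped whitelists are generated, not vendor plate sets; load real
  whitelists with `load_whitelist()` for production use.
* Random-hexamer collapsing assumes the standard plate pairing (index
  $i$ with index $i + s$); exotic plate layouts need a custom mapping.
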