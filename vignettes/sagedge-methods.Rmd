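---
title: "Tag-based differential expression with sagedge: models, conventions and design choices"
author: "sagedge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based differential expression with sagedge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagedge)
```

# The measurement model

SuperSAGE and its deep-sequencing variant quantify a transcriptome by
counting 26-bp tags anchored at NlaIII restriction sites: each tag is the
recognition site CATG plus the 22 bases immediately downstream, taken (for
a completely digested transcript) from the 3'-most qualifying site.  A
library is a multiset of sequenced tags; after aggregation, each distinct
sequence is a *unitag* and its count is the expression measurement.  Tags
sequenced exactly once (*singlets*) are overwhelmingly dominated by
sequencing error and are excluded before analysis; the library size
$N$ used for normalization is the total sequenced-tag mass *before* that
exclusion, because it is the sampling depth that generated the counts.

`extractTags()` implements the digestion model, `buildLibrary()` the
aggregation and singlet exclusion (per library; pooled-across-libraries
exclusion can be emulated by aggregating first and splitting afterwards —
we default to per-library exclusion because each library is sequenced and
error-contaminated independently), and `findSisters()` detects *sister
unitags*: pairs at Hamming distance exactly one outside the anchor, which
arise from SNPs, alternative transcripts, or surviving sequencing errors.
Sister detection uses a masked-position hash (22 buckets per tag), with
the quadratic all-pairs scan retained in the test suite as an oracle.

# The exact two-library test

For a unitag with counts $x$ and $y$ in libraries of sizes $N_1$ and
$N_2$, the Audic–Claverie significance of the difference is computed in
its conditional-binomial form: under the null of equal relative abundance,
conditional on the pooled count $n = x + y$,

$$ y \mid n \;\sim\; \mathrm{Binomial}\!\left(n,\; \frac{N_2}{N_1+N_2}\right), $$

and the two-sided p-value is twice the smaller tail probability, observed
outcome included, capped at 1.  `audicClaveriePValue()` delegates the tail
sums to `pbinom()`, which is accurate for counts far beyond $10^6$; the
test suite checks the implementation against direct term-by-term
summation over a grid of small counts to a relative error of $10^{-9}$.
Tail doubling (rather than summing opposite-tail outcomes with smaller
likelihood) was chosen because it is symmetric under library exchange and
matches the common implementations of this test; the classification is
strict (`p < alpha`, ties are non-significant).  No multiple-testing
correction is applied by default — the classic SuperSAGE workflow calls
each unitag at raw $p < 0.05$ — but `runContrast(adjust = "BH")` exposes
Benjamini–Hochberg as a clearly-labelled extension.

Because the test is exact and counts are discrete it is conservative: on
simulated null unitags its size at $\alpha = 0.05$ is around 3–5%,
which the calibration test pins to the band $[0.03, 0.06]$.

# Fold changes

Expression ratios are reported as signed fold changes of the normalized
frequencies $f = c/N \times 10^6$ (tags per million; the divisor is a
configurable choice — the convention in this literature reports
"normalized frequencies" without fixing a scale, and per-million keeps
printed magnitudes in a familiar range).  A zero frequency is replaced by
one *on the normalized scale* before forming the ratio
$R = f_1'/f_2'$ — this is what makes fold changes like 110.4 against an
absent counterpart representable — and

$$ \mathrm{FC} = \begin{cases} R & R \ge 1 \\ -1/R & R < 1. \end{cases} $$

Consequently $|\mathrm{FC}| \ge 1$ always, the sign encodes direction, and
no value falls in $(-1, 1)$.  Counts, not frequencies, enter the
significance test; frequencies are used only for fold changes and
reporting.

# Anchoring and region classification

`matchTag()` places a unitag on reference sequences under the
*tolerating-a-single-mismatch* rule: at most one mismatch in tag positions
4–25, and an exactly matching CATG at positions 0–3 on the aligned strand.
A full-length 26-mer match at ≤1 mismatch strictly dominates the
BLASTn score/e-value regime this rule originally encoded, so the package
uses a direct exact matcher (candidate windows are the reference's CATG
sites) instead of heuristic alignment; the brute-force sliding-window
Hamming scan over every offset and both strands is kept as a test oracle.
By default EST/transcript references are searched plus/plus only, genomic
references on both strands (genes lie on both); both policies are
arguments.  Coordinates are 0-based half-open internally and converted
from GFF3's 1-based inclusive convention at the boundary
(`readGeneModels()`, via `rtracklayer`).

`classifyRegion()` assigns each 26-nt anchor interval exactly one of four
categories: `exon` (entirely within exonic bases of an overlapping gene),
`intron` (overlaps a gene but no exonic base), `exon_intron_border`
(covers both), `intergenic` (no overlapping gene model).
`partitionByEvidence()` computes the exclusive three-set Venn regions over
EST, chromosome and scaffold evidence; all Venn algebra goes through
`vennSets()`, which partitions the union by membership signature so the
region sizes always sum to the union size.

# Annotation and GO summaries

Best-hit selection follows three consecutive rounds of redundancy
elimination: hits with both an informative description and GO terms beat
hits with only one of the two, which beat hits with neither.  Within the
winning class, hits are ranked by taxonomy tier (focal species, then
related legumes, then other angiosperms, then anything else — the shipped
tier map is a documented approximation and fully user-replaceable), then
alignment score, length, identity, and target id as a deterministic
tie-break.  "Informative description" is operationalized as a
configurable blacklist predicate (`isAdequate()`; defaults: *unknown*,
*clone*, *chromosome*, *hypothetical*, …, matched case-insensitively on
word boundaries) because the underlying workflow gives examples, not a
rule.  The alignment score surrogate is $26 - 2m$ for $m$ mismatches,
preserving the perfect > one-mismatch ordering without reimplementing
BLAST scoring.

`summarizeGo()` counts distinct UR and DR unitags per GO term; a tag with
$k$ terms contributes to $k$ rows, so per-term counts are a multiset view
and column sums may exceed the number of distinct DE tags.  GO terms are
used as assigned — there is no propagation through the GO DAG, because
the summaries this reproduces count assigned terms, not ancestors.

# Contrast panels, summary tables and set algebra

`runContrastPanel()` runs each contrast over the union of the two
libraries' unitags (absent means count 0); unitags absent from both are
excluded from that contrast's universe, which is why per-contrast totals
differ.  Contrasts are identified by explicit library pairs — the
literature's roman-numeral "approach" labels are ambiguous between
Methods text and figure captions, so numbering is left to a caller-side
label map.  Summary percentages are rounded half-up to one decimal
(`roundHalfUp()`), the convention that reproduces printed values such as
18.083 → 18.1 and 47.702 → 47.7; base R's half-to-even `round()` does
not.

# Clustering and heat-map export

`clusterRows()` clusters fold-change profiles across contrasts with, by
default, uncentered correlation similarity and average linkage — the
Cluster 3.0 defaults this workflow is compatible with — and no
normalization of FC values.  A tag not expressed in a contrast is missing
(`NA`), never imputed: $|\mathrm{FC}| \ge 1$ by construction, so a 0
would be a fake signal, and similarities are computed pairwise-complete
over shared columns only.  A row pair sharing no column gets similarity 0
with a warning.  The agglomeration itself is `stats::hclust` over the
package's distance matrix; merge heights are verified against a naive
agglomerative oracle in the tests.  `writeCdtGtr()` emits the
tab-delimited CDT/GTR pair (GID/UNIQID/NAME/GWEIGHT header, rows in leaf
order, missing values as empty fields, GTR similarities as $1 - h$)
readable by TreeView-compatible viewers, and `readCdt()` inverts the data
part for round-trip checks.

# qPCR relative expression (REST conventions)

Amplification efficiency is $E = 10^{-1/\text{slope}} - 1$ from the
standard-curve slope; the amplification base used in ratio arithmetic is
$1 + E$ (storing the fraction $E$ but exponentiating $1+E$ avoids a
classic factor-of-interpretation bug, and is asserted in tests via the
closed form: slope $-1/\log_{10} 2 \Rightarrow E = 1$).  For each gene,
technical replicates are averaged within biological replicate, then
$\Delta Ct = \overline{Ct}_{\text{control}} - \overline{Ct}_{\text{treatment}}$
and the gene factor is $(1+E)^{\Delta Ct}$; the expression ratio is the
target factor over the *geometric mean* of the reference-gene factors
(the REST/geNorm convention; with one reference and $E = 1$ this is the
classic $2^{-\Delta\Delta Ct}$).  Significance is a pair-wise fixed
reallocation test: whole biological replicates (carrying all genes
jointly) are reassigned between groups with group sizes fixed, the ratio
recomputed, and the two-sided p-value is the fraction of arrangements
with $|\log \text{ratio}|$ at least the observed (observed included, so
$p \ge 1/\text{permutations}$).  Spaces of at most 10,000 arrangements
are enumerated exhaustively — a 3 vs 3 design has $\binom{6}{3} = 20$,
with minimum attainable $p = 2/20 = 0.1$ — larger spaces use 2,000
Monte-Carlo draws by default.  `concordanceCheck()` encodes the
platform-agreement rule: one significant time point with matching
direction suffices.

# The synthetic experiment generator

`simulationConfig()` / `simulateReferences()` / `simulateLibraries()` /
`simulateCtTables()` generate a fully ground-truthed four-library
root-dehydration design: a tolerant and a sensitive accession, each with
an unstressed control and a stress bulk pooling six stress times
(25–150 min).  The defaults are the study conditions this emulates:

* **Library sizes** — per-accession sequenced-tag totals of 1,030,443
  (tolerant) and 1,520,843 (sensitive).  How each total split between
  control and stress library is not recorded, so the generator splits
  each equally; the split is a config key.
* **DE planting** — 30% of transcripts differentially expressed in the
  stress bulks (the DE-call fraction a stress-vs-control contrast of this
  design produces), 65% of effects inductions (the observed UR share),
  $|\mathrm{FC}|$ log-uniform on $[2, 50]$.
* **Abundance–effect coupling** — each planted effect moves a frequency
  mass of about `deMassFactor` (default 0.5) average transcripts:
  strongly induced genes start rare and repressed genes are abundant,
  with the repressed budget scaled so induced and released mass balance
  in expectation.  This mirrors stress transcriptomes, where the largest
  fold changes belong to transcripts nearly absent at baseline, and it
  keeps the total composition shift small — without it, heavy planted
  effects dilute every null transcript under the fixed-total draw and
  the recorded fold changes are no longer true on the frequency scale
  the pipeline measures.
* **Counts** — multinomial given the exact library size (totals are
  conserved by construction; the conditional test is agnostic to
  multinomial versus independent Poisson sampling).
* **Stress bulk** — an equal-weight mixture of six per-time profiles;
  `timeProfile = "transient"` plants effects active at only the first
  two times, diluting them threefold in the bulk, to mirror transient
  early responses.
* **Sequencing error** — per-base substitution probability $10^{-3}$
  over the 22 non-anchor positions (anchor errors would break CATG and
  be discarded upstream), converting a binomial share of each tag's
  reads into recorded sister tags; singlets arise naturally.

Baseline abundances are log-normal (sdlog 1.2), a realistic breadth for
transcript frequency distributions.  All generators are deterministic
given the seed.

What the generator does **not** emulate: real nucleotide composition,
read-level errors with quality scores, biological replicate variance
within a library (the emulated design has none), partial-digestion site
preferences, and GC or length biases.  Passing tests on this generator
therefore demonstrate correctness of the counting, testing, anchoring and
reporting machinery under the stated sampling model — not robustness to
the full messiness of real libraries.  The abundance–effect coupling also
means detection power is not probed for rare transcripts with small
effects; the sensitivity figures apply to the coupled design.

# Problem sizes and numerical choices

Unit and property tests run at desk scale: 150–200 transcripts with
20,000-tag libraries for end-to-end properties, 1,000 transcripts with
100,000-tag libraries (a tenth of the emulated depth) over 20 seeds for
the recovery experiment, a 10,000-unitag grid for test-size calibration,
and ≤20 kb references for the anchoring oracle.  These sizes are the
package's chosen trade-off between statistical resolution and a test
suite that runs in a couple of minutes.

Degenerate inputs are defined, not special-cased: $x = y = 0$ gives
$p = 1$; both frequencies zero give $\mathrm{FC} = 1$; an empty hit list
selects no annotation; an empty region is an empty character vector.
Deterministic tie-breaks are fixed throughout (lexicographic tag order,
target id, smaller row index) so identical inputs give byte-identical
outputs.

# Known limitations

* The one-mismatch matcher is exact by design and will not reproduce
  BLASTn's occasional acceptance of gapped or partial-length alignments.
* Region classification is interval arithmetic against supplied gene
  models; spliced alignment across exon junctions is out of scope, so a
  tag spanning a junction maps (correctly, at the genome level) as a
  border case rather than to the mature transcript.
* The Audic–Claverie test models sampling noise only; with no replicates
  per library, biological variance is unidentifiable and calls should be
  read as "beyond sampling noise", not "beyond biological noise".
* GO summaries count assigned terms without DAG propagation or
  enrichment statistics.
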