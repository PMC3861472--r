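# sagedge

Tag-based differential gene expression for SuperSAGE / DeepSuperSAGE
experiments.

SuperSAGE quantifies a transcriptome by sequencing 26-bp tags anchored at
NlaIII (CATG) restriction sites; each distinct tag sequence (*unitag*) and
its per-library count is the expression measurement. The design this
package serves is the classic deep-sequenced stress experiment: a handful
of unreplicated libraries — here a drought-tolerant and a
drought-sensitive accession, each with an unstressed control and a bulk of
stress time points — compared pairwise to call each unitag up-regulated
(UR), down-regulated (DR) or non-significant. `sagedge` is written for
people who want that pipeline as tested, scriptable R instead of a chain
of one-off tools: tag extraction, library building, the exact count test,
anchoring and annotation, summary tables and Venn partitions, heat-map
export, and qPCR validation, plus a ground-truthed simulator so every
stage is testable without any external download.

## The statistics at the core

**Audic–Claverie exact test.** For a unitag with counts $x, y$ in
libraries of sizes $N_1, N_2$, under the null of equal relative abundance
and conditional on $n = x + y$,

$$ y \mid n \sim \mathrm{Binomial}\!\left(n, \tfrac{N_2}{N_1+N_2}\right), $$

and the two-sided p-value is twice the smaller tail (observed outcome
included), capped at 1. Calls are UR/DR at raw $p < 0.05$ by default (no
multiple-testing correction, matching the classic workflow; BH is an
option).

**Signed fold change.** With normalized frequencies $f = c/N \times 10^6$
(tags per million) and zeros replaced by one, $R = f_1'/f_2'$ and
$\mathrm{FC} = R$ if $R \ge 1$, else $-1/R$ — so $|\mathrm{FC}| \ge 1$ and
the sign encodes direction.

**TSM anchoring.** A unitag maps to a reference if it matches full-length
with at most one mismatch outside the anchor and an intact CATG
("tolerating a single mismatch"); genomic hits are classified
exon / intron / exon–intron border / intergenic against GFF3 gene models.

**REST qPCR.** Efficiency $E = 10^{-1/\mathrm{slope}} - 1$; the
expression ratio is the target's $(1+E)^{\Delta Ct}$ over the geometric
mean of the reference genes', with significance from a pair-wise fixed
reallocation randomization test (exhaustive for small replicate designs).

## A worked example

Simulate a small four-library experiment with planted truth, build the
tolerant-accession libraries, and run the stress-vs-control contrast:

```r
library(sagedge)

cfg <- simulationConfig(nTranscripts = 300L, nChromosomeGenes = 30L,
                        librarySizes = c(ET0 = 50000L, `ET1.6` = 50000L,
                                         BT0 = 50000L, `BT1.6` = 50000L),
                        seed = 2)
refs <- simulateReferences(cfg)
sim  <- simulateLibraries(cfg, refs)

lib1 <- buildLibrary(sim$counts[["ET1.6"]], "ET1.6", "tolerant", "stress_bulk")
lib0 <- buildLibrary(sim$counts[["ET0"]],  "ET0",  "tolerant", "control")
lib1
#> TagLibrary 'ET1.6' (tolerant, stress_bulk)
#>   373 unitags; 50,000 tags sequenced; 900 singlets excluded

res <- runContrast(lib1, lib0)
head(res[, c("tag", "count_1", "count_2", "p_value", "fold_change", "call")], 5)
#>                          tag count_1 count_2      p_value fold_change call
#> 1 CATGAAACAGGTGGCAAAGGAATAGG     115       0 4.814825e-35      2300.0   UR
#> 2 CATGTGTCGTGTATCACAAGAGCCCG      80       0 1.654361e-24      1600.0   UR
#> 3 CATGTCTTTAAGACAGGTGTCAGCAG      41       0 9.094947e-13       820.0   UR
#> 4 CATGATTGACAACATTCTTGATGTGA     153       2 5.294719e-43        76.5   UR
#> 5 CATGTAAGATGGGGCAGGTCTAACGC     135       2 1.085266e-37        67.5   UR

summaryTable(list(`ET1.6 vs ET0` = res))
#>       contrast n_UR n_DR n_NS n_total pct_UR pct_DR pct_NS
#> 1 ET1.6 vs ET0   68   34  360     462   14.7    7.4   77.9
```

Reading the output: `count_1`/`count_2` are raw unitag counts in the two
libraries, `p_value` is the exact conditional-binomial significance of
the difference, and `fold_change` is the signed ratio of tags-per-million
frequencies (a tag absent from the control, like the first three rows,
gets the zero→one substitution, hence the very large FCs). The summary
row counts calls over the 462-unitag contrast universe, with percentages
rounded half-up to one decimal.

The same objects flow into the rest of the pipeline: `matchTag()` /
`classifyRegion()` for anchoring, `selectBestHit()` / `summarizeGo()` for
annotation, `vennSets()` for UR/DR set algebra, `fcMatrix()` +
`clusterRows()` + `writeCdtGtr()` for TreeView-compatible heat maps, and
`restRatio()` / `restRandomizationTest()` for qPCR validation.
`runPipeline()` drives everything from a YAML config and writes a JSON
run manifest. The methods vignette
(`vignettes/sagedge-methods.Rmd`) documents every model, convention and
default in detail.

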