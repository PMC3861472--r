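test_that("matchTag finds planted tags and applies the one-mismatch rule", {
  set.seed(21)
  tag <- randomTags(1)
  ref <- c(r1 = paste0(randomSeq(100), tag, randomSeq(74)))

  hit <- matchTag(tag, ref)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 100)
  expect_equal(hit$mismatches, 0)

  # one substitution at tag position 10 (0-based): found only at mm = 1
  mut <- ref
  substr(mut[["r1"]], 111, 111) <-
    setdiff(BASES, substr(mut[["r1"]], 111, 111))[1]
  h1 <- matchTag(tag, mut, maxMismatch = 1)
  expect_equal(h1$mismatches, 1)
  expect_equal(h1$mismatch_pos, 10)
  expect_equal(nrow(matchTag(tag, mut, maxMismatch = 0)), 0)

  # a broken CATG anchor (substitution at tag position 2) kills the hit
  broken <- ref
  substr(broken[["r1"]], 103, 103) <-
    setdiff(BASES, substr(broken[["r1"]], 103, 103))[1]
  expect_equal(nrow(matchTag(tag, broken, maxMismatch = 1)), 0)

  # minus-strand recovery with correct plus-strand coordinates
  rcRef <- c(r1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref[["r1"]]))))
  expect_equal(nrow(matchTag(tag, rcRef, strands = "plus_only")), 0)
  hMinus <- matchTag(tag, rcRef, strands = "both")
  expect_equal(hMinus$strand, "-")
  expect_equal(hMinus$start, nchar(ref[["r1"]]) - 100 - 26)
})

test_that("matchTag equals the brute-force sliding Hamming scan", {
  set.seed(22)
  refs <- c(rA = randomSeq(4000), rB = randomSeq(2500))
  # tags planted (some mutated) plus random ones
  planted <- vapply(1:15, function(i) {
    r <- sample(names(refs), 1)
    off <- sample(nchar(refs[[r]]) - 200, 1)
    t <- extractTags(substr(refs[[r]], off, off + 199), "all_sites")
    if (length(t)) t[1] else NA_character_
  }, character(1))
  planted <- planted[!is.na(planted)]
  tags <- unique(c(planted,
                   vapply(planted, function(t) mutateAt(t, sample(5:26, 1)),
                          character(1)),
                   randomTags(30)))
  for (tag in tags) {
    got <- matchTag(tag, refs, strands = "both")
    want <- bruteForceMatch(tag, refs)
    expect_equal(got[c("target", "start", "strand", "mismatches")],
                 want, ignore_attr = TRUE)
  }
})

test_that("extracted tags round-trip through matching at their origin", {
  set.seed(23)
  for (i in 1:20) {
    ref <- c(r = randomSeq(500))
    tags <- extractTags(ref[["r"]], mode = "all_sites")
    for (tag in tags) {
      hits <- matchTag(tag, ref)
      expect_true(any(hits$mismatches == 0 &
                        substr(ref[["r"]], hits$start + 1,
                               hits$start + 26) == tag))
    }
  }
})

test_that("region classification is total and respects gene structure", {
  # two-exon toy gene on a 1000-nt target: exon1 101-300, exon2 501-800
  g <- geneModel("g1", "t1", rbind(c(101, 300), c(501, 800)))
  models <- list(g)
  hitAt <- function(start0, target = "t1")
    list(target = target, start = start0)

  expect_identical(classifyRegion(hitAt(150), models), "exon")
  expect_identical(classifyRegion(hitAt(350), models), "intron")
  # straddles the exon1/intron boundary (ends at base 305)
  expect_identical(classifyRegion(hitAt(279), models), "exon_intron_border")
  expect_identical(classifyRegion(hitAt(10), models), "intergenic")
  expect_identical(classifyRegion(hitAt(100, "elsewhere"), models),
                   "intergenic")
  # exact containment boundaries
  expect_identical(classifyRegion(hitAt(100), models), "exon")  # 101..126
  expect_identical(classifyRegion(hitAt(99), models),
                   "exon_intron_border")                        # 100..125
  # inconsistent model rejected
  badExons <- rbind(c(101, 300), c(250, 400))
  expect_error(classifyRegion(hitAt(150),
                              list(list(gene_id = "bad", target_id = "t1",
                                        strand = "+", exons = badExons))),
               "overlap")
  # totality: every random hit gets exactly one category
  set.seed(30)
  cats <- vapply(sample(0:974, 100), function(s)
    classifyRegion(hitAt(s), models), character(1))
  expect_true(all(cats %in% c("exon", "intron", "exon_intron_border",
                              "intergenic")))
})

test_that("evidence partition conserves the tag universe", {
  p <- partitionByEvidence(c("a", "b"), "b", character(0))
  expect_identical(sort(p[["est"]]), "a")
  expect_identical(p[["est&chromosome"]], "b")
  expect_true(all(lengths(p[setdiff(names(p), c("est", "est&chromosome"))])
                  == 0))
  set.seed(31)
  for (i in 1:20) {
    ids <- as.character(1:100)
    sets <- list(est = sample(ids, 40), chromosome = sample(ids, 70),
                 scaffold = sample(ids, 10))
    part <- partitionByEvidence(sets$est, sets$chromosome, sets$scaffold)
    expect_equal(sum(lengths(part)), length(unique(unlist(sets))))
    expect_false(any(duplicated(unlist(part))))
  }
})

test_that("GFF3 gene models written by the simulator read back consistently", {
  sim <- smallSimulation()
  tmp <- withr::local_tempdir()
  paths <- writeReferences(sim$refs, tmp)
  models <- readGeneModels(paths[["gff3"]])
  expect_length(models, length(sim$refs$models))
  byId <- stats::setNames(models, vapply(models, `[[`, "", "gene_id"))
  for (m in sim$refs$models) {
    got <- byId[[m$gene_id]]
    expect_equal(unname(got$exons), unname(m$exons))
    expect_identical(got$target_id, m$target_id)
  }
})
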