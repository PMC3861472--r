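twoLibraries <- function(c1, c2, N1 = NULL, N2 = NULL) {
  tags <- randomTags(max(length(c1), length(c2)), seed = 50)
  l1 <- buildLibrary(stats::setNames(as.integer(c1), tags[seq_along(c1)]),
                     "L1")
  l2 <- buildLibrary(stats::setNames(as.integer(c2), tags[seq_along(c2)]),
                     "L2")
  list(l1, l2)
}

test_that("a contrast covers the union universe and classifies correctly", {
  t1 <- makeTag("A"); t2 <- makeTag("C"); t3 <- makeTag("G")
  l1 <- buildLibrary(stats::setNames(c(100L, 5L), c(t1, t2)), "A")
  l2 <- buildLibrary(stats::setNames(c(5L, 80L), c(t2, t3)), "B")
  res <- runContrast(l1, l2)
  expect_setequal(res$tag, c(t1, t2, t3))
  # identical libraries: everything NS at fc 1
  resSame <- runContrast(l1, l1)
  expect_true(all(resSame$call == "NS"))
  expect_true(all(resSame$fold_change == 1))
  expect_true(all(resSame$p_value == 1))
  # deterministic order: descending |fc| then tag
  expect_false(is.unsorted(rev(abs(res$fold_change))))
})

test_that("a 100-vs-0 tag at N = 1e6 is a confident UR call", {
  tags <- randomTags(2, seed = 51)
  l1 <- buildLibrary(stats::setNames(c(100L, 999900L), tags), "A")
  l2 <- buildLibrary(stats::setNames(stats::setNames(1000000L, tags[2]),
                                     tags[2]), "B")
  res <- runContrast(l1, l2)
  row <- res[res$tag == tags[1], ]
  expect_identical(row$call, "UR")
  expect_lt(row$p_value, 0.05)
})

test_that("swapping the libraries negates fc, swaps UR and DR, keeps p", {
  sim <- smallSimulation()
  libs <- lapply(names(sim$sim$counts), function(id)
    buildLibrary(sim$sim$counts[[id]], id))
  names(libs) <- names(sim$sim$counts)
  fwd <- runContrast(libs$`ET1.6`, libs$ET0)
  bwd <- runContrast(libs$ET0, libs$`ET1.6`)
  m <- match(fwd$tag, bwd$tag)
  expect_equal(fwd$p_value, bwd$p_value[m], tolerance = 1e-12)
  swap <- abs(fwd$fold_change) > 1
  expect_equal(fwd$fold_change[swap], -bwd$fold_change[m][swap])
  expect_identical(fwd$call[fwd$call == "UR"],
                   chartr("DR", "UR", bwd$call[m][fwd$call == "UR"]))
  expect_true(all((fwd$call == "DR") == (bwd$call[m] == "UR")))
})

test_that("the contrast panel validates its specs", {
  sim <- smallSimulation()
  libs <- lapply(names(sim$sim$counts), function(id)
    buildLibrary(sim$sim$counts[[id]], id))
  names(libs) <- names(sim$sim$counts)
  specs <- data.frame(contrast_id = "I", library_1 = "ET1.6",
                      library_2 = "ET0", stringsAsFactors = FALSE)
  panel <- runContrastPanel(specs, libs)
  expect_named(panel, "I")
  expect_error(runContrastPanel(
    data.frame(contrast_id = "X", library_1 = "ET0", library_2 = "ET0"),
    libs), "must differ")
  expect_error(runContrastPanel(
    data.frame(contrast_id = "X", library_1 = "ET0", library_2 = "nope"),
    libs), "unknown library")
})

test_that("summary percentages use round-half-up and sum to ~100", {
  s <- summaryTable(list(I = c(UR = 13532, DR = 7423, NS = 53878)))
  expect_equal(s$n_total, 74833)
  expect_equal(s$pct_UR, 18.1)
  expect_equal(s$pct_DR, 9.9)
  expect_equal(s$pct_NS, 72.0)
  expect_equal(summaryTable(list(a = c(UR = 0, DR = 0, NS = 10)))$pct_UR, 0)
  expect_equal(summaryTable(list(a = c(UR = 1, DR = 1, NS = 1)))$pct_UR, 33.3)
  # half-up, not half-even
  expect_equal(roundHalfUp(0.25, 1), 0.3)
  expect_equal(roundHalfUp(18.083), 18.1)
  expect_equal(roundHalfUp(47.702), 47.7)
  set.seed(52)
  for (i in 1:20) {
    n <- sample(1:1000, 3)
    s <- summaryTable(list(x = c(UR = n[1], DR = n[2], NS = n[3])))
    expect_lte(abs(s$pct_UR + s$pct_DR + s$pct_NS - 100), 0.2)
  }
})

test_that("Venn regions reproduce inclusion-exclusion on random instances", {
  v <- vennSets(list(I = c("a", "b", "c"), II = "b", IV = c("b", "c")))
  expect_identical(v[["I"]], "a")
  expect_identical(v[["I&IV"]], "c")
  expect_identical(v[["I&II&IV"]], "b")
  expect_identical(v[["II"]], character(0))

  same <- vennSets(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(sort(same[["A&B"]]), c("x", "y"))
  expect_true(all(lengths(same[names(same) != "A&B"]) == 0))

  set.seed(53)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ids <- as.character(seq_len(50))
    sets <- stats::setNames(
      lapply(seq_len(k), function(j) sample(ids, sample(0:40, 1))),
      LETTERS[seq_len(k)])
    regions <- vennSets(sets)
    expect_length(regions, 2^k - 1)
    # conservation of the union
    expect_equal(sum(lengths(regions)), length(unique(unlist(sets))))
    # inclusion-exclusion: each set's size equals the sum of the regions
    # whose signature includes it
    for (nm in names(sets)) {
      inRegions <- vapply(strsplit(names(regions), "&", fixed = TRUE),
                          function(sig) nm %in% sig, logical(1))
      expect_equal(sum(lengths(regions[inRegions])),
                   length(unique(sets[[nm]])))
    }
  }
  expect_error(vennSets(list(a = "x")), "2 to 4")
})

test_that("four-way characterization partitions the tag set", {
  ann <- data.frame(
    tag = c("t1", "t2", "t3"),
    description = c("kinase", "kinase", ""),
    go_terms = c("GO:0000001", "", "GO:0000001"),
    stringsAsFactors = FALSE)
  got <- characterizeTags(c("t1", "t2", "t3", "t4"), ann)
  expect_equal(unname(got), c(1, 1, 1, 1, 4))
  all3 <- characterizeTags(c("t1"), ann)
  expect_equal(unname(all3), c(1, 0, 0, 0, 1))
  set.seed(54)
  for (i in 1:10) {
    tags <- paste0("t", 1:30)
    ann <- data.frame(
      tag = sample(tags, 20),
      description = sample(c("kinase", "unknown", ""), 20, replace = TRUE),
      go_terms = sample(c("GO:0000001", ""), 20, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- characterizeTags(tags, ann)
    expect_equal(sum(got[1:4]), got[["total"]])
    expect_equal(got[["total"]], 30)
  }
})
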