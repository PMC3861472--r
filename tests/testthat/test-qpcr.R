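# build a Ct table in code: named list gene -> list(control=, treatment=)
# of per-biological-replicate mean Cts (technical reps synthesized around
# them with zero spread unless techSd > 0)
ctTable <- function(genes, techSd = 0, nTech = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(genes)) for (grp in c("control", "treatment")) {
    cts <- genes[[g]][[grp]]
    for (b in seq_along(cts)) for (tr in seq_len(nTech)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, group = grp, bio_rep = paste0(substr(grp, 1, 1), b),
        tech_rep = tr, ct = cts[b] + rnorm(1, 0, techSd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("efficiency follows E = 10^(-1/slope) - 1", {
  expect_equal(efficiencyFromSlope(-1 / log10(2)), 1, tolerance = 1e-12)
  expect_equal(efficiencyFromSlope(-3.6), 10^(1 / 3.6) - 1)
  expect_equal(round(efficiencyFromSlope(-3.6), 4), 0.8957)
  expect_error(efficiencyFromSlope(1), "negative")
  expect_warning(efficiencyFromSlope(-10), "outside")
})

test_that("the REST ratio reduces to known closed forms", {
  # all Cts identical across groups -> ratio 1
  g <- list(target = list(control = c(24, 24, 24), treatment = c(24, 24, 24)),
            ref = list(control = c(20, 20, 20), treatment = c(20, 20, 20)))
  expect_equal(restRatio(ctTable(g), "target", "ref"), 1)
  # target drops one cycle, references unchanged, E = 1 -> ratio 2
  g$target$treatment <- c(23, 23, 23)
  expect_equal(restRatio(ctTable(g), "target", "ref"), 2)
  # two references both dropping one cycle, target unchanged -> ratio 0.5
  g2 <- list(target = list(control = c(24, 24, 24), treatment = c(24, 24, 24)),
             r1 = list(control = c(20, 20, 20), treatment = c(19, 19, 19)),
             r2 = list(control = c(22, 22, 22), treatment = c(21, 21, 21)))
  expect_equal(restRatio(ctTable(g2), "target", c("r1", "r2")), 0.5)
  # with a single reference and E = 1 this is the classic 2^-ddCt
  g3 <- list(target = list(control = c(25, 26, 24), treatment = c(22, 23, 21)),
             ref = list(control = c(20, 20, 20), treatment = c(20.5, 20.5, 20.5)))
  ddct <- (mean(c(22, 23, 21)) - mean(c(25, 26, 24))) -
    (20.5 - 20)
  expect_equal(restRatio(ctTable(g3), "target", "ref"), 2^-ddct)
  # efficiency correction uses base 1 + E per gene
  e <- c(target = 0.8, ref = 1)
  expect_equal(restRatio(ctTable(g), "target", "ref", efficiencies = e),
               1.8^1 / 2^0)
})

test_that("the REST ratio is shift-invariant and inverts under group swap", {
  g <- list(target = list(control = c(25, 24.5, 25.5),
                          treatment = c(23, 22.5, 23.5)),
            ref = list(control = c(20, 20.2, 19.8),
                       treatment = c(20.1, 19.9, 20)))
  ct <- ctTable(g)
  r <- restRatio(ct, "target", "ref")
  shifted <- ct; shifted$ct <- shifted$ct + 5
  expect_equal(restRatio(shifted, "target", "ref"), r)
  swapped <- ct
  swapped$group <- ifelse(ct$group == "control", "treatment", "control")
  expect_equal(restRatio(swapped, "target", "ref"), 1 / r)
})

test_that("randomization p is exhaustive for small spaces and includes the observed", {
  # total separation with 3 vs 3 replicates: p = 2 / C(6,3) = 0.1
  g <- list(target = list(control = c(25, 25.1, 24.9),
                          treatment = c(20, 20.1, 19.9)),
            ref = list(control = c(18, 18, 18), treatment = c(18, 18, 18)))
  ct <- ctTable(g)
  res <- restRandomizationTest(ct, "target", "ref")
  expect_true(res$exhaustive)
  expect_equal(res$n_arrangements, choose(6, 3))
  expect_equal(res$p, 2 / choose(6, 3))
  expect_identical(res$call, "n.s.")  # 0.1 is not < 0.05
  expect_gt(res$ratio, 1)

  # swapping the groups leaves the exhaustive p unchanged, inverts the ratio
  swapped <- ct
  swapped$group <- ifelse(ct$group == "control", "treatment", "control")
  res2 <- restRandomizationTest(swapped, "target", "ref")
  expect_equal(res2$p, res$p)
  expect_equal(res2$ratio, 1 / res$ratio, tolerance = 1e-12)
  expect_error(restRandomizationTest(ct, "target", "ref", permutations = 0),
               ">= 1")
})

test_that("Monte-Carlo p agrees with exhaustive within binomial error", {
  g <- list(target = list(control = c(25, 24.6, 25.3, 24.8),
                          treatment = c(23.9, 24.2, 23.6, 24.4)),
            ref = list(control = c(20, 20.1, 19.9, 20),
                       treatment = c(20, 20.05, 19.95, 20)))
  ct <- ctTable(g)
  ex <- restRandomizationTest(ct, "target", "ref")
  expect_true(ex$exhaustive)
  mc <- restRandomizationTest(ct, "target", "ref", permutations = 2000,
                              seed = 7, exhaustiveLimit = 1)
  expect_false(mc$exhaustive)
  se <- sqrt(ex$p * (1 - ex$p) / 2000)
  expect_lt(abs(mc$p - ex$p), 4 * se + 1 / 2000)
})

test_that("null randomization p is not anti-conservative", {
  set.seed(70)
  hits <- 0
  for (i in 1:200) {
    g <- list(target = list(control = 24 + rnorm(3, 0, 0.3),
                            treatment = 24 + rnorm(3, 0, 0.3)),
              ref = list(control = rep(20, 3), treatment = rep(20, 3)))
    res <- restRandomizationTest(ctTable(g, seed = i), "target", "ref")
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 200, 0.08)
})

test_that("platform concordance needs one significant matching time point", {
  up <- list(ratio = 2.1, p = 0.01)
  dn <- list(ratio = 0.4, p = 0.02)
  ns <- list(ratio = 1.8, p = 0.3)
  expect_true(concordanceCheck("UR", list(ns, up)))
  expect_false(concordanceCheck("UR", list(ns, ns)))
  expect_false(concordanceCheck("DR", list(up)))
  expect_true(concordanceCheck("DR", list(dn, ns)))
  expect_false(concordanceCheck("NS", list(up, dn)))
  expect_error(concordanceCheck("UR", list()), "time point")
})

test_that("simulated Ct tables recover planted ratios", {
  # zero noise: exact recovery
  s0 <- simulateCtTables("g1", 2.5, noiseSd = 0, bioSd = 0, seed = 3)
  expect_equal(restRatio(s0$ct, "g1", c("actin", "rna18s")), 2.5,
               tolerance = 1e-9)
  # reference-only shift compensates: target ratio follows the references
  s1 <- simulateCtTables("g1", 1, noiseSd = 0, bioSd = 0, seed = 4)
  ct <- s1$ct
  ct$ct[ct$gene %in% c("actin", "rna18s") & ct$group == "treatment"] <-
    ct$ct[ct$gene %in% c("actin", "rna18s") & ct$group == "treatment"] - 1
  expect_equal(restRatio(ct, "g1", c("actin", "rna18s")), 0.5)
})
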