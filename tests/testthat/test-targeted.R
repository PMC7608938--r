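test_that("SCFA totals, BCFA totals and per-sample ratios", {
  p <- scfaPanel(data.frame(sample_id = c("s1", "s2"),
                            acetate = c(100, 200), propionate = c(50, 100),
                            butyrate = c(50, 100), isobutyrate = c(20, 0),
                            methylbutyrate2 = c(20, 0), isovalerate = c(60, 0)))
  tot <- scfaTotals(p)
  expect_equal(tot$total_scfa, c(200, 400))
  expect_equal(tot$total_bcfa, c(100, 0))
  expect_equal(tot$ratio[1], 2)
  expect_true(is.na(tot$ratio[2]))  # zero BCFA -> missing ratio
})

test_that("mean of per-sample ratios differs from ratio of mean totals", {
  # per-sample ratios {2, 4}: group mean 3, but ratio of mean totals differs
  p <- scfaPanel(data.frame(sample_id = c("s1", "s2"),
                            acetate = c(200, 100), propionate = c(0, 0),
                            butyrate = c(0, 0), isobutyrate = c(100, 25),
                            methylbutyrate2 = c(0, 0), isovalerate = c(0, 0)))
  tot <- scfaTotals(p)
  expect_equal(mean(tot$ratio), 3)
  expect_equal(mean(tot$total_scfa) / mean(tot$total_bcfa), 150 / 62.5)
  expect_false(isTRUE(all.equal(mean(tot$ratio),
                                mean(tot$total_scfa) / mean(tot$total_bcfa))))
})

test_that("group summary: means, SEs, unrounded delta and t-test p", {
  d <- toyDesign(nPer = 2, weeks = 3L)
  v <- setNames(c(1, 3, 2, 6), sampleIDs(d))
  gs <- groupSummary(v, d, week = 3)
  expect_equal(gs$mean_LRS, 2)
  expect_equal(gs$mean_HRS, 4)
  expect_equal(gs$se_LRS, 1)
  expect_equal(gs$se_HRS, 2)
  expect_equal(gs$delta, 2)
  expect_equal(gs$delta, gs$mean_HRS - gs$mean_LRS, tolerance = 1e-9)
  ref <- t.test(c(2, 6), c(1, 3), var.equal = TRUE)
  expect_equal(gs$p, ref$p.value, tolerance = 1e-10)

  same <- setNames(c(1, 3, 1, 3), sampleIDs(d))
  expect_equal(groupSummary(same, d, week = 3)$delta, 0)
})

test_that("group table linearity: mean of totals equals sum of analyte means", {
  d <- simulateDesign(c(6, 6), missingRate = 0, seed = 61)
  sp <- simulateScfa(d, cv = 0.2, seed = 61)
  tab <- scfaGroupTable(sp, d, week = 3)
  for (g in c("LRS", "HRS")) {
    col <- paste0("mean_", g)
    straight <- tab[[col]][tab$analyte %in% c("acetate", "propionate", "butyrate")]
    expect_equal(tab[[col]][tab$analyte == "total_scfa"], sum(straight),
                 tolerance = 1e-9)
  }
  # explicit exclusion list removes subjects (never automatic)
  tabEx <- scfaGroupTable(sp, d, week = 3, excludeSubjects = "S01")
  expect_identical(tabEx$n_LRS[1], tab$n_LRS[1] - 1L)
})

test_that("totals and deltas reconstruct from published group means", {
  ref <- referenceScfaMeansWide(3)
  tab <- scfaMeanTable(ref)
  expect_equal(tab$LRS[tab$analyte == "total_scfa"], 5440.0, tolerance = 1e-9)
  expect_equal(tab$HRS[tab$analyte == "total_scfa"], 7315.4, tolerance = 1e-9)
  expect_equal(tab$delta[tab$analyte == "acetate"], 675.6, tolerance = 1e-9)
  da <- groupMeanDeltas(referenceAlphaMeansWide(6))
  expect_equal(da$delta[da$index == "S"], 7.81, tolerance = 1e-9)
})

test_that("redox ratios are exact on the log scale and flagged derived", {
  r <- redoxRatio(setNames(c(8, 5, 3), paste0("s", 1:3)),
                  setNames(c(2, 5, 0), paste0("s", 1:3)), source = "sugar")
  expect_equal(r$ratio[1:2], c(4, 1))
  expect_equal(r$log2_ratio[1:2], c(2, 0))
  expect_true(all(abs(r$log2_ratio[1:2] -
                        (log2(r$hydroxyl[1:2]) - log2(r$oxo[1:2]))) < 1e-12))
  expect_true(is.na(r$ratio[3]))  # oxo <= 0 -> missing
  expect_true(all(r$derived))

  # derived features are excluded from q-value estimation in the cascade
  d <- toyDesign(nPer = 4, weeks = c(3L, 6L))
  withr::with_seed(62, {
    m <- matrix(2^rnorm(16 * 12, 8), 16, 12,
                dimnames = list(sampleIDs(d), sprintf("f%02d", 1:12)))
  })
  fm <- featureMatrix(m, scale = "raw")
  res <- differentialCascade(fm, d, vip = FALSE,
                             derivedFeatures = c("f01", "f02"))
  expect_true(all(is.na(res$q[res$feature %in% c("f01", "f02")])))
  expect_true(all(is.na(res$significant[res$feature %in% c("f01", "f02")])))
  expect_true(all(!is.na(res$q[!res$feature %in% c("f01", "f02")])))
})

test_that("diet composition formulas match their definitions", {
  lrs <- referenceDiets()$LRS
  expect_equal(nfe(lrs), 29.3, tolerance = 1e-9)
  expect_equal(nfe(dietComposition(0, 0, 0, 0, 0)), 100)
  expect_equal(nfe(dietComposition(20, 20, 40, 10, 10)), 0)
  expect_error(dietComposition(50, 30, 30, 5, 5), "exceed")

  expect_equal(percentCook(72.2, 100), 72.2)
  expect_equal(percentCook(50, 50), 100)
  expect_equal(percentCook(36.1, 50), 72.2)
  expect_error(percentCook(10, 0), "positive")
  expect_error(percentCook(60, 50), "exceed")

  expect_equal(apparentDigestibility(100, 15), 85)
  expect_equal(apparentDigestibility(100, 0), 100)
  expect_equal(apparentDigestibility(50, 10), 80)
  expect_warning(apparentDigestibility(50, 60), "negative")

  expect_equal(organicDryMatter(60, 10), 30)
  expect_equal(organicDryMatter(0, 0), 100)
  expect_equal(organicDryMatter(64.8, 8.2), 27.0)
  expect_error(organicDryMatter(80, 30), "exceed")
})
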