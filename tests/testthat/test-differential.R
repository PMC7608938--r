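test_that("log2 fold change is the HRS - LRS mean on the transformed scale", {
  d <- toyDesign(nPer = 2, weeks = 3L)
  m <- matrix(c(1, 1, 2, 4), 4, 1,
              dimnames = list(sampleIDs(d), "f"))
  expect_equal(unname(log2FoldChange(m, d, week = 3)), 2)
  expect_equal(unname(log2FoldChange(cbind(m, f2 = c(5, 5, 5, 5)), d)[2]), 0)

  # raw values exactly 2x correspond to log2FC = 1
  d6 <- toyDesign(nPer = 3, weeks = 3L)
  raw <- matrix(c(4, 4, 4, 8, 8, 8), 6, 1, dimnames = list(sampleIDs(d6), "f"))
  fmRaw <- featureMatrix(raw, scale = "raw")
  expect_equal(unname(log2FoldChange(toLog2(fmRaw), d6, week = 3)), 1)
  expect_error(log2FoldChange(fmRaw, d6), "log2 or CLR")
})

test_that("replicate collections are averaged per subject before testing", {
  d <- studyDesign(data.frame(
    sample_id = c("a1", "a2", "b1", "c1", "c2", "d1"),
    subject_id = c("sA", "sA", "sB", "sC", "sC", "sD"),
    group = c("LRS", "LRS", "LRS", "HRS", "HRS", "HRS"),
    week = 3L, collection = c(1L, 2L, 1L, 1L, 2L, 1L)))
  m <- matrix(c(1, 3, 2, 10, 20, 15), 6, 1,
              dimnames = list(c("a1", "a2", "b1", "c1", "c2", "d1"), "f"))
  # subject means: sA = 2, sB = 2, sC = 15, sD = 15 -> FC = 13
  expect_equal(unname(log2FoldChange(m, d, week = 3)), 13)
})

test_that("pooled t-test matches the textbook case and stats::t.test", {
  d <- toyDesign(nPer = 3, weeks = 3L)
  m <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1, dimnames = list(sampleIDs(d), "f"))
  tt <- twoGroupTTest(m, d, week = 3)
  expect_equal(abs(tt$t), 3.674, tolerance = 1e-3)
  expect_identical(tt$df, 4L)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)
  ref <- t.test(m[4:6, 1], m[1:3, 1], var.equal = TRUE)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)

  # location invariance
  tt2 <- twoGroupTTest(m + 100, d, week = 3)
  expect_equal(tt2$t, tt$t, tolerance = 1e-12)

  # identical groups: t = 0, p = 1 (zero variance is not an error)
  mEq <- matrix(rep(c(1, 2, 3), 2), 6, 1, dimnames = list(sampleIDs(d), "f"))
  ttEq <- twoGroupTTest(mEq, d, week = 3)
  expect_equal(ttEq$t, 0)
  expect_equal(ttEq$p, 1)
  mconst <- matrix(5, 6, 1, dimnames = list(sampleIDs(d), "f"))
  expect_equal(twoGroupTTest(mconst, d, week = 3)$p, 1)

  dTiny <- toyDesign(nPer = 1, weeks = 3L)
  expect_error(twoGroupTTest(m[c(1, 4), , drop = FALSE], dTiny, week = 3),
               ">= 2 subjects")
})

test_that("mixed model collapses to the pooled t-test with one obs per subject", {
  withr::with_seed(41, {
    d <- toyDesign(nPer = 9, weeks = 3L)
    m <- matrix(rnorm(18 * 100), 18, 100,
                dimnames = list(sampleIDs(d), sprintf("f%03d", 1:100)))
    mm <- mixedModelTest(m, d, randomTerms = "subject", weeks = 3L)
    tt <- twoGroupTTest(m, d, week = 3)
    expect_true(all(abs(mm$p - tt$p) < 1e-6))
    expect_true(all(mm$converged))
  })
})

test_that("mixed model estimate is replication-invariant and recovers variance components", {
  withr::with_seed(42, {
    d <- toyDesign(nPer = 5, weeks = c(3L, 6L))
    ids <- sampleIDs(d)
    m <- matrix(rnorm(length(ids)), ncol = 1, dimnames = list(ids, "f"))
    base <- mixedModelTest(m, d, randomTerms = "subject")
    # duplicating every row verbatim as a second collection leaves the
    # group estimate unchanged
    dd <- designTable(d)
    dd2 <- dd; dd2$collection <- 2L; dd2$sample_id <- paste0(dd$sample_id, "r")
    dBoth <- studyDesign(rbind(dd, dd2))
    m2 <- rbind(m, matrix(m[, 1], dimnames = list(paste0(ids, "r"), "f")))
    dup <- mixedModelTest(m2, dBoth, randomTerms = "subject")
    expect_equal(dup$estimate, base$estimate, tolerance = 1e-6)

    # parameter recovery at 200 subjects, subject_sd = residual_sd = 0.5
    n <- 200
    grp <- rep(c("LRS", "HRS"), each = n / 2)
    dBig <- studyDesign(data.frame(
      sample_id = paste0("x", 1:(2 * n)),
      subject_id = rep(sprintf("c%03d", 1:n), each = 2),
      group = rep(grp, each = 2), week = rep(c(3L, 6L), n), collection = 1L))
    yv <- rep(rnorm(n, 0, 0.5), each = 2) + rnorm(2 * n, 0, 0.5)
    yb <- matrix(yv, ncol = 1, dimnames = list(paste0("x", 1:(2 * n)), "f"))
    frame <- data.frame(y = yv, subject = rep(sprintf("c%03d", 1:n), each = 2),
                        group = factor(rep(grp, each = 2), c("LRS", "HRS")))
    fit <- lme4::lmer(y ~ group + (1 | subject), data = frame, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))$sdcor
    expect_lt(abs(vc[1] - 0.5) / 0.5, 0.2)
    expect_lt(abs(vc[2] - 0.5) / 0.5, 0.2)
    # and the package's wrapper agrees with the direct fit
    mmB <- mixedModelTest(yb, dBig, randomTerms = "subject")
    expect_equal(mmB$estimate, unname(lme4::fixef(fit)[2]), tolerance = 1e-9)
  })
})

test_that("Storey q-values: worked example, clamps, monotonicity, null pi0", {
  qr <- storeyQValues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(qvalues(qr), rep(0.04, 4))

  all1 <- storeyQValues(rep(1, 20))
  expect_equal(pi0Estimate(all1), 1)
  expect_equal(qvalues(all1), rep(1, 20))

  withr::with_seed(43, {
    p <- runif(10000)
    qr2 <- storeyQValues(p)
    expect_gte(pi0Estimate(qr2), 0.9)
    expect_lte(pi0Estimate(qr2), 1)
    o <- order(p)
    expect_true(all(diff(qvalues(qr2)[o]) >= -1e-12))
    # BH equivalence at pi0 = 1
    expect_equal(qvalues(storeyQValues(p, pi0 = 1)), p.adjust(p, "BH"),
                 tolerance = 1e-12)
  })
  expect_error(storeyQValues(c(0.5, 1.2)), "0, 1")
  # fewer than 10 p-values: pi0 pinned at 1
  expect_equal(pi0Estimate(storeyQValues(c(0.2, 0.4, 0.6))), 1)
})

test_that("q-values equal the brute-force min-over-thresholds oracle", {
  withr::with_seed(44, {
    for (i in 1:30) {
      m <- sample(3:12, 1)
      p <- round(runif(m), 3)
      for (pi0 in c(1, 0.7)) {
        expect_equal(qvalues(storeyQValues(p, pi0 = pi0)),
                     bruteQValues(p, pi0), tolerance = 1e-12)
      }
    }
  })
})

test_that("the dual criterion is inclusive at both thresholds", {
  expect_true(dualCriterion(0.05, 0.1))
  expect_false(dualCriterion(0.04, 0.2))
  expect_false(dualCriterion(0.2, 0.05))
  expect_identical(dualCriterion(c(0.01, 0.06), c(0.05, 0.05)), c(TRUE, FALSE))
})

test_that("class MANOVA reduces to the t-test in 1-D and controls type I error", {
  d <- toyDesign(nPer = 5, weeks = 3L)
  withr::with_seed(45, {
    m <- matrix(rnorm(10), 10, 1, dimnames = list(sampleIDs(d), "f1"))
    cm <- classManova(m, d, week = 3, label = "solo")
    tt <- twoGroupTTest(m, d, week = 3)
    expect_equal(cm$F, tt$t^2, tolerance = 1e-9)
    expect_equal(cm$p, tt$p, tolerance = 1e-9)

    # identical group matrices: Wilks' lambda = 1
    mEq <- matrix(rep(rnorm(5), 2), 10, 2)
    dimnames(mEq) <- list(sampleIDs(d), c("f1", "f2"))
    mEq[, 2] <- mEq[, 2] + rnorm(10, 0, 1e-3)  # keep E nonsingular
    mEq[6:10, ] <- mEq[1:5, ]
    cmEq <- classManova(mEq, d, week = 3, label = "same")
    expect_gt(cmEq$wilks, 0.9999)
    expect_gt(cmEq$p, 0.99)

    # type-I rate for a 2-feature null class
    hits <- vapply(1:1000, function(i) {
      mm <- matrix(rnorm(20), 10, 2, dimnames = list(sampleIDs(d), c("a", "b")))
      classManova(mm, d, week = 3)$p <= 0.05
    }, logical(1L))
    expect_gte(mean(hits), 0.03)
    expect_lte(mean(hits), 0.07)
  })

  # too many features for the sample size: explicit untestable row
  withr::with_seed(46, {
    big <- matrix(rnorm(10 * 9), 10, 9,
                  dimnames = list(sampleIDs(d), paste0("f", 1:9)))
    cmBig <- classManova(big, d, week = 3, label = "wide")
    expect_false(cmBig$testable)
    expect_true(is.na(cmBig$p))
  })
})

test_that("classTests runs one joint test per class", {
  d <- toyDesign(nPer = 5, weeks = 3L)
  withr::with_seed(47, {
    m <- matrix(2^rnorm(10 * 6, 8), 10, 6,
                dimnames = list(sampleIDs(d), paste0("f", 1:6)))
    fm <- featureMatrix(m, scale = "raw",
                        featureClass = setNames(rep(c("indole", "dipeptide"), 3),
                                                paste0("f", 1:6)))
    ct <- classTests(toLog2(fm), d, week = 3)
    expect_identical(ct$class, c("dipeptide", "indole"))
    expect_identical(ct$n_features, c(3L, 3L))
    expect_true(all(ct$testable))
  })
})

test_that("persistence regression recovers exact and null relationships", {
  fc3 <- c(-1, 0, 0.5, 1, 2)
  pr <- suppressWarnings(persistenceRegression(fc3, fc3))  # exact fit
  expect_equal(pr$slope, 1)
  expect_equal(pr$adjR2, 1)
  pr2 <- suppressWarnings(persistenceRegression(fc3, 2 * fc3))
  expect_equal(pr2$slope, 2)
  expect_equal(pr2$adjR2, 1)
  withr::with_seed(48, {
    a <- rnorm(1000); b <- rnorm(1000)
    pr3 <- persistenceRegression(a, b)
    expect_lt(abs(pr3$slope), 0.1)
    expect_lt(pr3$adjR2, 0.01)
  })
  expect_error(persistenceRegression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(persistenceRegression(1:2, 1:2), ">= 3")
})

test_that("summary fractions count significant features by FC sign", {
  res <- data.frame(significant = c(rep(TRUE, 4), rep(FALSE, 6)),
                    log2FC_pooled = c(1, 2, 0.5, -1, rnorm(6)))
  fr <- summarizeFractions(res)
  expect_equal(fr$fractionSignificant, 0.4)
  expect_equal(fr$fractionUp, 0.3)
  expect_equal(fr$fractionDown, 0.1)
  none <- data.frame(significant = rep(FALSE, 5), log2FC_pooled = rnorm(5))
  expect_equal(unlist(summarizeFractions(none), use.names = FALSE), c(0, 0, 0))
  allUp <- data.frame(significant = TRUE, log2FC_pooled = c(1, 2))
  expect_equal(unlist(summarizeFractions(allUp), use.names = FALSE), c(1, 1, 0))
})
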