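test_that("Hill numbers match closed forms and the vegan oracle", {
  u <- rep(1 / 8, 8)
  for (q in c(0, 0.5, 1, 2, 5)) expect_equal(hillNumber(u, q), 8)
  expect_equal(hillNumber(c(0.8, 0.2), 2), 1 / 0.68)
  expect_equal(hillNumber(c(0.8, 0.2), 0), 2)
  expect_error(hillNumber(c(0, 0), 1), "all-zero")
  expect_error(hillNumber(c(-0.1, 1.1), 1), "negative")

  skip_if_not_installed("vegan")
  withr::with_seed(21, {
    p <- randomComposition(12)
    for (q in c(0.25, 1, 2, 4)) {
      ren <- vegan::renyi(p, scales = q)
      expect_equal(hillNumber(p, q), exp(as.numeric(ren)), tolerance = 1e-10)
    }
  })
})

test_that("alpha summary reproduces entropy arithmetic and its invariants", {
  m <- matrix(c(10, 10, 10, 10), 1, dimnames = list("s", paste0("t", 1:4)))
  a <- alphaSummary(m)
  expect_equal(unlist(a[1, c("S", "expH", "invSimp", "J")]),
               c(S = 4, expH = 4, invSimp = 4, J = 1))

  a2 <- alphaSummary(matrix(c(8, 2), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(a2$expH, exp(0.5004), tolerance = 1e-4)
  expect_equal(a2$invSimp, 1.4706, tolerance = 1e-4)
  expect_equal(a2$J, 0.7219, tolerance = 1e-4)

  a3 <- alphaSummary(matrix(c(7, 0), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(unlist(a3[1, c("S", "expH", "invSimp")]),
               c(S = 1, expH = 1, invSimp = 1))
  expect_true(is.na(a3$J))

  withr::with_seed(22, {
    m <- matrix(rpois(60, 5) + 1L, 5, 12,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:12)))
    a <- alphaSummary(m)
    expect_true(all(1 <= a$invSimp & a$invSimp <= a$expH & a$expH <= a$S))
  })
})

test_that("diversity profiles are monotone, consistent and tail-limited", {
  u <- matrix(1, 1, 6, dimnames = list("s", paste0("t", 1:6)))
  prof <- alphaProfile(u)
  expect_equal(unname(prof[1, ]), rep(6, ncol(prof)))

  m <- matrix(c(18, 1, 1), 1, dimnames = list("s", c("a", "b", "c")))
  prof2 <- alphaProfile(m)
  expect_equal(prof2[1, "1.00"], alphaSummary(m)$expH, tolerance = 1e-12)
  expect_true(all(diff(prof2[1, ]) <= 1e-12))

  skew <- matrix(c(0.9, 0.05, 0.05) * 200, 1, dimnames = list("s", c("a", "b", "c")))
  prof3 <- alphaProfile(skew)
  expect_lt(abs(prof3[1, "9.95"] - 1 / 0.9) / (1 / 0.9), 0.05)

  expect_error(alphaProfile(u, qGrid = c(0.5, 0.4)), "increasing")
  expect_error(alphaProfile(u, qGrid = c(0, 1)), "positive")
})

test_that("q-beta decomposition matches direct evaluation and bounds", {
  # worked case: p1 = (1,0), p2 = (0.5,0.5), q = 2 -> beta 1.2, qbeta 1/3
  cts <- rbind(s1 = c(10, 0), s2 = c(5, 5))
  colnames(cts) <- c("a", "b")
  expect_equal(betaProfile(cts, qGrid = 2)$qbeta, 1 / 3, tolerance = 1e-12)

  # identical assemblages: qbeta = 0 across the whole grid
  dup <- rbind(s1 = c(3, 7, 5), s2 = c(3, 7, 5))
  colnames(dup) <- paste0("t", 1:3)
  expect_true(all(abs(betaProfile(dup)$qbeta) < 1e-10))

  # disjoint equal-richness assemblages: near-complete turnover at small q
  dis <- rbind(s1 = c(5, 5, 0, 0), s2 = c(0, 0, 5, 5))
  colnames(dis) <- paste0("t", 1:4)
  expect_gt(betaProfile(dis, qGrid = 0.05)$qbeta, 0.98)

  expect_error(betaProfile(cts[1, , drop = FALSE]), "at least 2")

  # permutation invariance in sample order, qbeta within [0, 1]
  withr::with_seed(23, {
    m <- matrix(rpois(40, 4), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
    m[rowSums(m) == 0, 1] <- 1
    b1 <- betaProfile(m, qGrid = c(0.05, 1, 2, 5))
    b2 <- betaProfile(m[4:1, ], qGrid = c(0.05, 1, 2, 5))
    expect_equal(b1$qbeta, b2$qbeta, tolerance = 1e-12)
    expect_true(all(b1$qbeta >= 0 & b1$qbeta <= 1))
  })
})

test_that("CqN reduces to Sorensen (q=0) and Morisita-Horn (q=2) for two samples", {
  withr::with_seed(24, {
    for (i in 1:25) {
      x1 <- rpois(12, 2); x2 <- rpois(12, 2)
      if (sum(x1) == 0) x1[1] <- 1
      if (sum(x2) == 0) x2[1] <- 1
      m <- rbind(s1 = x1, s2 = x2)
      colnames(m) <- paste0("t", 1:12)
      qb0 <- betaProfile(m, qGrid = 0)$qbeta
      expect_equal(1 - qb0, sorensenOracle(x1, x2), tolerance = 1e-12)
      qb2 <- betaProfile(m, qGrid = 2)$qbeta
      expect_equal(1 - qb2, morisitaHornOracle(x1, x2), tolerance = 1e-10)
    }
  })
})

test_that("the q = 1 limit is continuous", {
  withr::with_seed(25, {
    m <- matrix(rpois(30, 5) + 1L, 3, 10,
                dimnames = list(paste0("s", 1:3), paste0("t", 1:10)))
    at1 <- alphaProfile(m, qGrid = 1)
    just <- alphaProfile(m, qGrid = c(1 - 1e-6, 1 + 1e-6))
    expect_lt(max(abs(just - cbind(at1, at1))), 1e-5)
    b1 <- betaProfile(m, qGrid = 1)$qbeta
    bnear <- betaProfile(m, qGrid = c(1 - 1e-6, 1 + 1e-6))$qbeta
    expect_lt(max(abs(bnear - b1)), 1e-5)
  })
})

test_that("Bacteroidetes:Firmicutes ratio handles guards and arithmetic", {
  tx <- data.frame(taxon_id = paste0("t", 1:3),
                   phylum = c("Bacteroidetes", "Firmicutes", "Proteobacteria"),
                   family = "f", genus = paste0("g", 1:3))
  m <- matrix(c(30, 60, 10,   20, 20, 5,   10, 0, 5), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  ct <- countTable(m, tx)
  r <- bfRatio(ct)
  expect_equal(unname(r[1]), 0.5)
  expect_equal(unname(r[2]), 1)
  expect_true(is.na(r[3]))  # zero Firmicutes -> missing, not Inf

  txBad <- tx; txBad$phylum[1] <- "Other"
  expect_error(bfRatio(countTable(m, txBad)), "Bacteroidetes")
})

test_that("group beta profiles stratify by group and week", {
  d <- simulateDesign(c(4, 4), missingRate = 0, seed = 31)
  tr <- syntheticTruth(nFeatures = 10, nTaxa = 20, seed = 31)
  ct <- simulateCounts(d, tr, seed = 31)
  gb <- groupBetaProfiles(ct, d, qGrid = c(0.5, 2))
  expect_setequal(unique(gb$label), c("LRS_w3", "LRS_w6", "HRS_w3", "HRS_w6"))
  expect_true(all(gb$qbeta >= 0 & gb$qbeta <= 1))
  gb2 <- groupBetaProfiles(ct, d, by = "group", qGrid = c(0.5, 2))
  expect_setequal(unique(gb2$label), c("LRS", "HRS"))
})
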