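# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (brute force /
# classical formulas), independent of the package implementation paths
# they check.

# -- fixtures -----------------------------------------------------------

# Balanced toy design: nPer subjects per group, one sample per subject
# per week, single collection.
toyDesign <- function(nPer = 3L, weeks = c(3L, 6L), collections = 1L) {
  n <- 2L * nPer
  subj <- sprintf("c%02d", seq_len(n))
  grp <- rep(c("LRS", "HRS"), each = nPer)
  rows <- expand.grid(collection = collections, week = weeks,
                      i = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  studyDesign(data.frame(
    sample_id = sprintf("%s_w%d_c%d", subj[rows$i], rows$week, rows$collection),
    subject_id = subj[rows$i], group = grp[rows$i],
    week = rows$week, collection = rows$collection))
}

# Random composition of given richness (strictly positive proportions).
randomComposition <- function(s) {
  x <- stats::rexp(s)
  x / sum(x)
}

# -- oracles ------------------------------------------------------------

# Brute-force Storey q-values: literal min over thresholds t >= p_i of
# pi0 * m * t / #{p <= t}, scanning every observed p as threshold.
bruteQValues <- function(p, pi0) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), numeric(1L))))
  }, numeric(1L))
}

# Classical Sorensen similarity from presence/absence sets (N = 2).
sorensenOracle <- function(x1, x2) {
  a <- sum(x1 > 0 & x2 > 0)
  b <- sum(x1 > 0 & x2 == 0)
  c <- sum(x1 == 0 & x2 > 0)
  2 * a / (2 * a + b + c)
}

# Classical Morisita-Horn similarity from relative abundances (N = 2).
morisitaHornOracle <- function(x1, x2) {
  p1 <- x1 / sum(x1)
  p2 <- x2 / sum(x2)
  2 * sum(p1 * p2) / (sum(p1^2) + sum(p2^2))
}

# SVD-based PLS1 scores: weight = dominant left singular vector of the
# deflated cross-covariance X'y (no NIPALS iteration).
svdPlsScores <- function(X, y, A, scale = TRUE) {
  Xc <- base::scale(X, center = TRUE, scale = scale)
  yc <- y - mean(y)
  S <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    w <- svd(crossprod(Xc, yc))$u[, 1L]
    t <- drop(Xc %*% w)
    pl <- drop(crossprod(Xc, t)) / sum(t^2)
    qa <- sum(yc * t) / sum(t^2)
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - t * qa
    S[, a] <- t
  }
  S
}

# Max column-wise score discrepancy allowing per-factor sign flips.
scoreDiffUpToSign <- function(S1, S2) {
  max(vapply(seq_len(ncol(S1)), function(a) {
    min(max(abs(S1[, a] - S2[, a])), max(abs(S1[, a] + S2[, a])))
  }, numeric(1L)))
}
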