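# PLS-DA by NIPALS with VIP scoring and K-fold cross-validation for
# factor selection. Two-class problems use a single centered 0/1 dummy
# response, which is equivalent to the two-column indicator coding.

# Core NIPALS PLS1 on a pre-centered/scaled X and centered y.
# Sign convention: each weight vector's largest-magnitude element is
# forced positive so fits are deterministic.
nipalsCore <- function(X, y, maxFactors) {
  n <- nrow(X); p <- ncol(X)
  A <- min(maxFactors, p, n - 1L)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tt <- matrix(0, n, A)
  qv <- numeric(A); ssy <- numeric(A)
  ssyTotal <- sum(y^2)
  yres <- y
  a <- 0L
  for (k in seq_len(A)) {
    if (sum(X^2) < 1e-12 || sum(yres^2) < 1e-12) break
    w <- drop(crossprod(X, yres))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(X, t)) / tt
    qk <- sum(yres * t) / tt
    X <- X - tcrossprod(t, pl)
    yres <- yres - t * qk
    a <- k
    W[, k] <- w; P[, k] <- pl; Tt[, k] <- t
    qv[k] <- qk; ssy[k] <- qk^2 * tt
  }
  if (a == 0L) stop("no PLS factor could be extracted (X or y degenerate)")
  idx <- seq_len(a)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Tt = Tt[, idx, drop = FALSE], q = qv[idx], ssy = ssy[idx],
       r2y = cumsum(ssy[idx]) / ssyTotal)
}

prepareXY <- function(X, y, scale) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopIfNot(nlevels(y) == 2L && length(unique(as.character(y))) == 2L,
            "y must have exactly two classes")
  stopIfNot(nrow(X) >= 3L, "need at least 3 samples")
  y01 <- as.numeric(y == levels(y)[2L])
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1  # constant columns carry no signal; leave them centered
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  list(X = Xs, y = y01 - mean(y01), yMean = mean(y01), center = ctr, scale = scl)
}

#' Fit a PLS-DA model by NIPALS
#'
#' X is column-centered and (by default) autoscaled to unit variance;
#' the group indicator is coded 0/1 and centered. Factors are extracted
#' by NIPALS deflation up to \code{maxFactors} (capped at the matrix
#' rank), stopping early when the residual X or y variance is exhausted.
#'
#' @param X \linkS4class{FeatureMatrix} (log2 or clr scale) or numeric
#'   matrix, samples x features.
#' @param y two-level group factor (or anything coercible), one entry
#'   per sample; for a \linkS4class{StudyDesign} pass
#'   \code{designTable(d)$group}.
#' @param maxFactors size of the factor search space (default 15).
#' @param scale autoscale columns to unit variance (default TRUE);
#'   FALSE centers only.
#' @return A \linkS4class{PlsModel}.
#' @export
plsdaFit <- function(X, y, maxFactors = 15L, scale = TRUE) {
  if (is(X, "FeatureMatrix")) {
    stopIfNot(featureScale(X) != "raw",
              "X must be on the log2 or CLR scale; see toLog2()")
    X <- featureValues(X)
  }
  prep <- prepareXY(X, y, scale)
  if (maxFactors > min(ncol(X), nrow(X) - 1L))
    warning("maxFactors exceeds the matrix rank; truncating")
  core <- nipalsCore(prep$X, prep$y, maxFactors)
  dimnames(core$W) <- list(colnames(X), NULL)
  new("PlsModel", weights = core$W, loadings = core$P, scores = core$Tt,
      yloadings = core$q, ssy = core$ssy, r2y = core$r2y,
      q2 = rep(NA_real_, ncol(core$W)), chosenFactors = NA_integer_,
      center = prep$center, scaleVec = prep$scale, yMean = prep$yMean)
}

#' Variable importance in projection (VIP) scores
#'
#' \code{VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)} over the
#' first \code{aFactors} factors (weights are unit norm). The scores are
#' normalized so the mean squared VIP equals 1; features with VIP > 1
#' contribute more than an average feature to the group separation.
#'
#' @param model a fitted \linkS4class{PlsModel}.
#' @param aFactors number of factors to accumulate (defaults to the
#'   cross-validation choice if present, else all fitted factors).
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vipScores <- function(model, aFactors = NULL) {
  A <- ncol(model@weights)
  if (is.null(aFactors))
    aFactors <- if (!is.na(model@chosenFactors)) model@chosenFactors else A
  stopIfNot(aFactors >= 1L && aFactors <= A,
            "aFactors must lie in 1..", A)
  idx <- seq_len(aFactors)
  ssy <- model@ssy[idx]
  if (sum(ssy) <= 0) stop("zero explained y variance; VIP undefined")
  W2 <- model@weights[, idx, drop = FALSE]^2
  p <- nrow(W2)
  drop(sqrt(p * (W2 %*% ssy) / sum(ssy)))
}

# Deterministic stratified fold assignment: within each class, shuffle
# (seeded) and deal round-robin across folds.
stratifiedFolds <- function(y, K, seed) {
  y <- as.factor(y)
  folds <- integer(length(y))
  withSeed(childSeed(seed, 6L), {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      folds[idx] <- rep(seq_len(K), length.out = length(idx))
    }
  })
  # every training set must contain both classes
  for (k in seq_len(K)) {
    tr <- y[folds != k]
    if (nlevels(droplevels(tr)) < 2L)
      stop("fold ", k, " leaves a training set with one class; ",
           "reduce K or add samples")
  }
  folds
}

#' K-fold cross-validated Q2 and factor selection
#'
#' Deterministic stratified folds are drawn from the seed; for each
#' factor count A the predictive residual sum of squares PRESS(A) is
#' accumulated over held-out folds and \code{Q2(A) = 1 - PRESS(A)/SSY}.
#' The chosen factor count minimizes the root mean PRESS.
#'
#' @inheritParams plsdaFit
#' @param K number of folds (default 7).
#' @param seed seed for the fold assignment.
#' @return list with \code{q2} (per factor), \code{rmsep} (root mean
#'   PRESS per factor), \code{chosenFactors}, \code{folds}, and
#'   \code{model}: the full-data \linkS4class{PlsModel} with its
#'   \code{q2}/\code{chosenFactors} slots filled.
#' @export
kfoldQ2 <- function(X, y, K = 7L, maxFactors = 15L, scale = TRUE, seed = 1L) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  y <- as.factor(y)
  stopIfNot(nrow(X) >= K, "need at least K samples")
  folds <- stratifiedFolds(y, K, seed)
  y01 <- as.numeric(y == levels(y)[2L])
  A <- min(maxFactors, ncol(X), nrow(X) - 2L)
  press <- numeric(A)
  for (k in seq_len(K)) {
    tr <- folds != k
    if (!any(!tr)) next
    prep <- prepareXY(X[tr, , drop = FALSE], y[tr], scale)
    core <- tryCatch(nipalsCore(prep$X, prep$y, A), error = function(e) NULL)
    if (is.null(core)) next
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, prep$center), 2L,
                 prep$scale, "/")
    yte <- y01[!tr]
    Ak <- ncol(core$W)
    # accumulate predictions factor by factor via deflation-free scores
    Xd <- Xte
    pred <- rep(prep$yMean, nrow(Xte))
    for (a in seq_len(A)) {
      if (a <= Ak) {
        t <- drop(Xd %*% core$W[, a])
        pred <- pred + t * core$q[a]
        Xd <- Xd - tcrossprod(t, core$P[, a])
      }
      press[a] <- press[a] + sum((yte - pred)^2)
    }
  }
  ssy <- sum((y01 - mean(y01))^2)
  q2 <- 1 - press / ssy
  rmsep <- sqrt(press / length(y01))
  chosen <- which.min(rmsep)
  model <- plsdaFit(X, y, maxFactors = A, scale = scale)
  Afit <- ncol(model@weights)
  model@q2 <- q2[seq_len(min(Afit, A))]
  model@chosenFactors <- as.integer(min(chosen, Afit))
  list(q2 = q2, rmsep = rmsep, chosenFactors = as.integer(chosen),
       folds = folds, model = model)
}
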