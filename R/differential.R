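# The differential-testing cascade building blocks: per-week two-group
# tests, random-intercept mixed models across the study, Storey
# q-values, the dual p/q significance criterion, class-level MANOVA,
# fold-change persistence and summary fractions.

# Subject-level values: average replicate collections per subject
# (optionally within one week). Returns a subjects x features matrix and
# the per-subject group factor, LRS first.
subjectValues <- function(values, design, week = NULL) {
  d <- designTable(design)
  d <- d[d$sample_id %in% rownames(values), , drop = FALSE]
  if (!is.null(week)) d <- d[d$week == week, , drop = FALSE]
  if (nrow(d) == 0L) stop("no design rows match the value matrix",
                          if (!is.null(week)) paste0(" at week ", week))
  v <- values[d$sample_id, , drop = FALSE]
  subj <- factor(d$subject_id, levels = unique(d$subject_id))
  sv <- rowsum(v, subj) / as.vector(table(subj))
  grp <- factor(vapply(split(d$group, subj), `[`, character(1L), 1L),
                levels = GROUP_LEVELS)
  list(values = sv[levels(subj), , drop = FALSE], group = grp)
}

asValueMatrix <- function(values) {
  if (is(values, "FeatureMatrix")) {
    if (featureScale(values) == "raw")
      stop("values must be on the log2 or CLR scale; see toLog2()")
    featureValues(values)
  } else as.matrix(values)
}

#' Convert a raw-scale FeatureMatrix to log2
#'
#' @param x a raw-scale \linkS4class{FeatureMatrix}.
#' @return The same matrix with values log2-transformed and scale
#'   \code{"log2"}.
#' @export
toLog2 <- function(x) {
  stopIfNot(is(x, "FeatureMatrix") && featureScale(x) == "raw",
            "toLog2 expects a raw-scale FeatureMatrix")
  featureMatrix(log2(featureValues(x)), scale = "log2",
                featureClass = featureClasses(x))
}

#' Per-feature log2 fold change (HRS minus LRS)
#'
#' Group mean difference on the transformed (log2 or CLR) scale; since
#' the values are already logged this is the log2 fold change of HRS
#' over LRS. Replicate collections are averaged per subject first so
#' every cat contributes one value.
#'
#' @param values \linkS4class{FeatureMatrix} (log2/clr) or matrix of
#'   transformed values, samples x features.
#' @param design a \linkS4class{StudyDesign}.
#' @param week restrict to week 3 or 6; NULL pools all samples.
#' @return Named numeric vector of fold changes, one per feature.
#' @export
log2FoldChange <- function(values, design, week = NULL) {
  v <- asValueMatrix(values)
  sv <- subjectValues(v, design, week)
  for (g in GROUP_LEVELS)
    if (sum(sv$group == g) < 1L)
      stop("group ", g, " has no subjects",
           if (!is.null(week)) paste0(" at week ", week))
  colMeans(sv$values[sv$group == "HRS", , drop = FALSE]) -
    colMeans(sv$values[sv$group == "LRS", , drop = FALSE])
}

#' Pooled-variance two-group t-test per feature
#'
#' Two-sided independent t-test with pooled variance on subject-level
#' values (replicate collections averaged first). Zero variance in both
#' groups with equal means yields p = 1 rather than an error.
#'
#' @inheritParams log2FoldChange
#' @return data.frame with columns \code{feature}, \code{estimate}
#'   (HRS - LRS), \code{t}, \code{df}, \code{p}.
#' @examples
#' d <- studyDesign(data.frame(sample_id = paste0("s", 1:6),
#'   subject_id = paste0("c", 1:6), group = rep(c("LRS", "HRS"), each = 3),
#'   week = 3L, collection = 1L))
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
#'             dimnames = list(paste0("s", 1:6), "f"))
#' twoGroupTTest(m, d, week = 3)  # t = 3.674, df = 4, p = 0.0213
#' @export
twoGroupTTest <- function(values, design, week = NULL) {
  v <- asValueMatrix(values)
  sv <- subjectValues(v, design, week)
  n1 <- sum(sv$group == "LRS")
  n2 <- sum(sv$group == "HRS")
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 subjects")
  x1 <- sv$values[sv$group == "LRS", , drop = FALSE]
  x2 <- sv$values[sv$group == "HRS", , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(sweep(x1, 2L, m1)^2)
  ss2 <- colSums(sweep(x2, 2L, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- m2 - m1
  t <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), 0)
  p[se == 0 & est == 0] <- 1
  data.frame(feature = colnames(v), estimate = est, t = t, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random-intercept linear mixed model per feature
#'
#' Fits \code{value ~ group + (1 | subject)} (and optionally
#' \code{+ (1 | collection)}) by REML per feature, with the two-sided
#' p-value from a Wald t statistic on containment (between-subject
#' residual) degrees of freedom, \code{n_subjects - 2}, appropriate for
#' the between-subject group effect. Variance components are constrained
#' nonnegative by the optimizer. When the design has exactly one
#' observation per subject the subject intercept is unidentifiable and
#' the model collapses analytically to ordinary least squares, which for
#' a single group factor is the pooled t-test; that reduction is applied
#' directly. Features whose fit fails to converge are returned with
#' missing p (never a silent zero) and \code{converged = FALSE}.
#'
#' All features share one model frame, so after the first REML fit the
#' remaining features are refit against the same design
#' (\code{lme4::refit}), keeping genome-scale runs fast.
#'
#' @inheritParams log2FoldChange
#' @param randomTerms subset of \code{c("subject", "collection")}.
#' @param weeks weeks to include (default both).
#' @return data.frame with columns \code{feature}, \code{estimate},
#'   \code{se}, \code{t}, \code{df}, \code{p}, \code{converged}.
#' @export
mixedModelTest <- function(values, design, randomTerms = "subject",
                           weeks = c(3L, 6L)) {
  stopIfNot(length(randomTerms) >= 1L &&
              all(randomTerms %in% c("subject", "collection")),
            "randomTerms must be a non-empty subset of {subject, collection}")
  v <- asValueMatrix(values)
  d <- designTable(design)
  d <- d[d$sample_id %in% rownames(v) & d$week %in% weeks, , drop = FALSE]
  if (nrow(d) == 0L) stop("no design rows match the value matrix")
  nSubj <- length(unique(d$subject_id))
  if (min(table(vapply(split(d$group, d$subject_id), `[`, character(1L), 1L))) < 2L)
    stop("each group needs >= 2 subjects")
  v <- v[d$sample_id, , drop = FALSE]
  feats <- colnames(v)
  dfDen <- nSubj - 2L

  if (max(table(d$subject_id)) == 1L) {
    # one observation per subject: exact OLS / pooled-t collapse
    tt <- twoGroupTTest(v, design, week = NULL)
    se <- ifelse(is.finite(tt$t) & tt$t != 0, tt$estimate / tt$t, NA_real_)
    return(data.frame(feature = feats, estimate = tt$estimate, se = se,
                      t = tt$t, df = tt$df, p = tt$p, converged = TRUE,
                      row.names = NULL, stringsAsFactors = FALSE))
  }

  frame <- data.frame(y = v[, 1L],
                      group = factor(d$group, levels = GROUP_LEVELS),
                      subject = factor(d$subject_id),
                      collection = factor(d$collection))
  terms <- paste(sprintf("(1 | %s)", randomTerms), collapse = " + ")
  form <- stats::as.formula(paste("y ~ group +", terms))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  template <- NULL
  fitOne <- function(j) {
    fit <- tryCatch({
      suppressMessages(suppressWarnings({
        if (is.null(template)) {
          frame$y <- v[, j]
          template <<- lme4::lmer(form, data = frame, REML = TRUE, control = ctrl)
          template
        } else {
          lme4::refit(template, newresp = v[, j])
        }
      }))
    }, error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    b <- lme4::fixef(fit)[2L]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2L]
    t <- b / se
    c(b, se, t, 2 * stats::pt(-abs(t), dfDen), 1)
  }
  res <- vapply(seq_along(feats), fitOne, numeric(5L))
  data.frame(feature = feats, estimate = res[1L, ], se = res[2L, ],
             t = res[3L, ], df = dfDen, p = res[4L, ],
             converged = res[5L, ] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' The proportion of true nulls pi0 is estimated from
#' \code{pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))} on the grid
#' lambda = 0.05, 0.10, ..., 0.95, smoothed with a cubic smoothing
#' spline and evaluated at the largest lambda, then clamped to (0, 1].
#' With fewer than 10 p-values the smoother is unreliable and pi0 is
#' fixed at 1 (the conservative BH limit). The q-value of p_i is
#' \code{min over t >= p_i of pi0 * m * t / #\{p <= t\}}, so q-values
#' are monotone non-decreasing in p and reduce to Benjamini-Hochberg
#' adjusted p-values when pi0 = 1.
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0 optional fixed pi0 overriding estimation.
#' @param lambdaGrid tuning grid for the pi0 smoother.
#' @return A \linkS4class{QValueResult}.
#' @examples
#' qvalues(storeyQValues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1))  # all 0.04
#' @export
storeyQValues <- function(p, pi0 = NULL, lambdaGrid = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10L) {
      pi0 <- 1
    } else {
      pi0l <- vapply(lambdaGrid, function(l) sum(p > l) / (m * (1 - l)),
                     numeric(1L))
      fit <- stats::smooth.spline(lambdaGrid, pi0l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambdaGrid))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) pi0 <- .Machine$double.eps
    }
  }
  stopIfNot(pi0 > 0 && pi0 <= 1, "pi0 must lie in (0, 1]")
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # rank of each sorted p counts ties: #{p <= p_(i)}
  rk <- rank(p, ties.method = "max")[o]
  q <- pi0 * m * p[o] / rk
  q <- pmin(cummin(q), 1)[ro]
  new("QValueResult", pi0 = pi0, qvalues = q, lambdaGrid = lambdaGrid)
}

#' @rdname storeyQValues
#' @param object a \linkS4class{QValueResult}.
#' @export
qvalues <- function(object) object@qvalues

#' @rdname storeyQValues
#' @export
pi0Estimate <- function(object) object@pi0

#' Dual significance criterion
#'
#' A feature is called significant when both \code{p <= 0.05} and
#' \code{q <= 0.1} hold (inclusive thresholds).
#'
#' @param p,q vectors of p- and q-values (recycled to common length).
#' @param pThreshold,qThreshold inclusive cutoffs.
#' @return Logical vector.
#' @export
dualCriterion <- function(p, q, pThreshold = 0.05, qThreshold = 0.1) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE) &&
              all(q >= 0 & q <= 1, na.rm = TRUE),
            "p and q must lie in [0, 1]")
  p <= pThreshold & q <= qThreshold
}

#' Class-level joint test (one-way MANOVA, Wilks' lambda)
#'
#' Tests whether the diet group shifts a whole class of features jointly
#' at one week: a model is fit for each member feature and the models
#' are tested together via Wilks' lambda (det(E)/det(E+H)) with Rao's F
#' approximation. Single-feature classes reduce exactly to the squared
#' t-test. Classes with too few samples (n < k + 2) or a singular error
#' matrix are returned as explicitly untestable rather than dropped.
#'
#' @param values \linkS4class{FeatureMatrix} (log2/clr) or matrix,
#'   restricted to the class members.
#' @param design a \linkS4class{StudyDesign}.
#' @param week week to test (3 or 6).
#' @param label class label carried through to the result.
#' @return One-row data.frame: \code{class}, \code{n_features},
#'   \code{wilks}, \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{testable}.
#' @export
classManova <- function(values, design, week, label = "class") {
  v <- asValueMatrix(values)
  sv <- subjectValues(v, design, week)
  k <- ncol(v)
  n <- nrow(sv$values)
  untestable <- data.frame(class = label, n_features = k, wilks = NA_real_,
                           F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                           p = NA_real_, testable = FALSE,
                           stringsAsFactors = FALSE)
  if (n < k + 2L) return(untestable)
  g <- sv$group
  if (k == 1L) {
    tt <- tryCatch(twoGroupTTest(v, design, week), error = function(e) NULL)
    if (is.null(tt) || !is.finite(tt$t)) return(untestable)
    Fv <- tt$t^2
    df2 <- tt$df
    lam <- df2 / (df2 + Fv)  # E/(E+H) in one dimension
    return(data.frame(class = label, n_features = 1L, wilks = lam, F = Fv,
                      df1 = 1, df2 = df2, p = tt$p, testable = TRUE,
                      stringsAsFactors = FALSE))
  }
  res <- tryCatch({
    fit <- stats::manova(sv$values ~ g)
    sm <- summary(fit, test = "Wilks")$stats
    data.frame(class = label, n_features = k, wilks = sm[1L, "Wilks"],
               F = sm[1L, "approx F"], df1 = sm[1L, "num Df"],
               df2 = sm[1L, "den Df"], p = sm[1L, "Pr(>F)"], testable = TRUE,
               stringsAsFactors = FALSE)
  }, error = function(e) untestable)
  res
}

#' Run the class-level MANOVA across all feature classes
#'
#' @param values a \linkS4class{FeatureMatrix} with class annotation.
#' @param design a \linkS4class{StudyDesign}.
#' @param week week to test.
#' @return data.frame with one \code{\link{classManova}} row per class.
#' @export
classTests <- function(values, design, week) {
  stopIfNot(is(values, "FeatureMatrix"), "values must be a FeatureMatrix")
  cls <- featureClasses(values)
  m <- asValueMatrix(values)
  out <- lapply(sort(unique(cls)), function(cc) {
    classManova(m[, cls == cc, drop = FALSE], design, week, label = cc)
  })
  do.call(rbind, out)
}

#' Fold-change persistence regression
#'
#' Ordinary least squares of week-6 fold changes on week-3 fold changes;
#' a slope near 1 with high adjusted R-squared indicates the diet effect
#' is persistent across the study.
#'
#' @param fcWeek3,fcWeek6 aligned numeric vectors (>= 3 features).
#' @return list with \code{slope}, \code{intercept}, \code{adjR2},
#'   \code{p} (slope test), \code{n}.
#' @export
persistenceRegression <- function(fcWeek3, fcWeek6) {
  stopIfNot(length(fcWeek3) == length(fcWeek6) && length(fcWeek3) >= 3L,
            "need >= 3 aligned fold changes")
  keep <- is.finite(fcWeek3) & is.finite(fcWeek6)
  fcWeek3 <- fcWeek3[keep]; fcWeek6 <- fcWeek6[keep]
  if (stats::var(fcWeek3) == 0) stop("zero variance in week-3 fold changes")
  fit <- stats::lm(fcWeek6 ~ fcWeek3)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adjR2 = sm$adj.r.squared,
       p = unname(sm$coefficients[2L, 4L]),
       n = length(fcWeek3))
}

#' Summary fractions of the differential results
#'
#' @param results data.frame with columns \code{significant} and
#'   \code{log2FC_pooled} (the cascade output).
#' @return list with \code{fractionSignificant}, \code{fractionUp},
#'   \code{fractionDown}, over all tested features; up/down split
#'   significant features by the sign of the pooled fold change.
#' @export
summarizeFractions <- function(results) {
  stopIfNot(is.data.frame(results) && nrow(results) > 0L,
            "results must be non-empty")
  sig <- results$significant %in% TRUE
  n <- nrow(results)
  list(fractionSignificant = sum(sig) / n,
       fractionUp = sum(sig & results$log2FC_pooled > 0) / n,
       fractionDown = sum(sig & results$log2FC_pooled < 0) / n)
}
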