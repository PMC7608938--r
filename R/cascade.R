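# End-to-end differential cascade: per-week tests, mixed models across
# the study, Storey q-values, the dual criterion, and VIP scores.

weekHasReplicates <- function(d, week) {
  dw <- d[d$week == week, , drop = FALSE]
  any(table(dw$subject_id) > 1L)
}

#' Run the full differential-testing cascade
#'
#' For each feature: per-week group comparisons (pooled t-test when each
#' cat contributed one sample at the week, random-intercept mixed model
#' with subject as random factor when replicate collections are
#' available), a mixed model across the whole study (subject, plus
#' collection number when replicates exist, as random factors), Storey
#' q-values per p-value vector, the dual significance criterion
#' \code{p <= 0.05 and q <= 0.1} on the designated test, and PLS-DA VIP
#' scores per week. Metabolome features should arrive on the log2 scale
#' (raw input is transformed automatically); microbiome features should
#' arrive CLR-transformed (see \code{\link{countsToClr}}).
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param design a \linkS4class{StudyDesign}.
#' @param qInput which p-value vector feeds the dual criterion:
#'   \code{"mixed"} (across-study mixed model, default) or
#'   \code{"week"} (significant if the criterion holds at either week).
#' @param vip compute PLS-DA VIP scores per week (default TRUE).
#' @param maxFactors,K PLS-DA search space and CV folds.
#' @param seed seed for the CV fold assignment.
#' @param excludeSubjects explicit subject exclusion list.
#' @param derivedFeatures feature ids that are derived ratios: they are
#'   excluded from every q-value input vector and get NA q and
#'   significance.
#' @return data.frame with one row per feature: \code{feature},
#'   \code{class}, \code{log2FC_w3}, \code{p_w3}, \code{q_w3},
#'   \code{log2FC_w6}, \code{p_w6}, \code{q_w6}, \code{log2FC_pooled},
#'   \code{p_mixed}, \code{q}, \code{VIP_w3}, \code{VIP_w6},
#'   \code{significant}. The Storey pi0 estimates are attached as
#'   attribute \code{"pi0"}.
#' @export
differentialCascade <- function(features, design, qInput = c("mixed", "week"),
                                vip = TRUE, maxFactors = 15L, K = 7L,
                                seed = 1L, excludeSubjects = character(),
                                derivedFeatures = character()) {
  qInput <- match.arg(qInput)
  stopIfNot(is(features, "FeatureMatrix"), "features must be a FeatureMatrix")
  if (featureScale(features) == "raw") features <- toLog2(features)
  d <- designTable(design)
  if (length(excludeSubjects) > 0L) {
    d <- d[!d$subject_id %in% excludeSubjects, , drop = FALSE]
    design <- studyDesign(d)
  }
  v <- featureValues(features)
  d <- d[d$sample_id %in% rownames(v), , drop = FALSE]
  design <- studyDesign(d)
  feats <- colnames(v)
  res <- data.frame(feature = feats,
                    class = unname(featureClasses(features)[feats]),
                    stringsAsFactors = FALSE)

  for (w in WEEK_LEVELS) {
    fc <- log2FoldChange(v, design, week = w)
    if (weekHasReplicates(d, w)) {
      dw <- studyDesign(d[d$week == w, , drop = FALSE])
      mm <- mixedModelTest(v, dw, randomTerms = "subject", weeks = w)
      pw <- mm$p
    } else {
      pw <- twoGroupTTest(v, design, week = w)$p
    }
    res[[paste0("log2FC_w", w)]] <- unname(fc[feats])
    res[[paste0("p_w", w)]] <- pw
  }

  anyReps <- any(table(paste(d$subject_id, d$week)) > 1L)
  rterms <- if (anyReps) c("subject", "collection") else "subject"
  mm <- mixedModelTest(v, design, randomTerms = rterms)
  res$log2FC_pooled <- unname(log2FoldChange(v, design)[feats])
  res$p_mixed <- mm$p

  qFor <- function(p) {
    q <- rep(NA_real_, length(p))
    use <- !res$feature %in% derivedFeatures & !is.na(p)
    if (sum(use) > 0L) q[use] <- qvalues(storeyQValues(p[use]))
    q
  }
  res$q_w3 <- qFor(res$p_w3)
  res$q_w6 <- qFor(res$p_w6)
  res$q <- qFor(res$p_mixed)
  pi0s <- c(w3 = attrSafePi0(res$p_w3, res$feature, derivedFeatures),
            w6 = attrSafePi0(res$p_w6, res$feature, derivedFeatures),
            mixed = attrSafePi0(res$p_mixed, res$feature, derivedFeatures))

  res$VIP_w3 <- NA_real_
  res$VIP_w6 <- NA_real_
  if (vip) {
    for (w in WEEK_LEVELS) {
      sv <- subjectValues(v, design, week = w)
      cv <- tryCatch(
        kfoldQ2(sv$values, sv$group, K = K, maxFactors = maxFactors,
                seed = childSeed(seed, w)),
        error = function(e) NULL)
      if (!is.null(cv))
        res[[paste0("VIP_w", w)]] <-
          unname(vipScores(cv$model)[feats])
    }
  }

  res$significant <- if (qInput == "mixed") {
    dualCriterion(res$p_mixed, res$q)
  } else {
    dualCriterion(res$p_w3, res$q_w3) | dualCriterion(res$p_w6, res$q_w6)
  }
  res$significant[res$feature %in% derivedFeatures] <- NA
  attr(res, "pi0") <- pi0s
  res
}

attrSafePi0 <- function(p, feats, derived) {
  use <- !feats %in% derived & !is.na(p)
  if (sum(use) == 0L) return(NA_real_)
  pi0Estimate(storeyQValues(p[use]))
}
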