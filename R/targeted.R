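# Deterministic arithmetic summaries for targeted panels: SCFA/BCFA
# totals and ratios, group summary tables, redox hydroxyl:oxo pairs,
# and diet composition / digestibility formulas.

#' Per-sample SCFA and BCFA totals and their ratio
#'
#' \code{total_scfa = acetate + propionate + butyrate} (straight-chain,
#' saccharolytic fermentation products);
#' \code{total_bcfa = isobutyrate + 2-methylbutyrate + isovalerate}
#' (branched-chain, amino-acid putrefaction products). The ratio is the
#' per-sample ratio of totals, which when averaged over a group differs
#' in general from the ratio of group-mean totals; group tables report
#' the mean of per-sample ratios, matching how the trial's summary
#' tables are built. Samples with zero BCFA get an NA ratio.
#'
#' @param panel an \linkS4class{ScfaPanel}.
#' @return data.frame with columns \code{sample_id}, \code{total_scfa},
#'   \code{total_bcfa}, \code{ratio}.
#' @export
scfaTotals <- function(panel) {
  stopIfNot(is(panel, "ScfaPanel"), "panel must be an ScfaPanel")
  d <- panelData(panel)
  scfa <- d$acetate + d$propionate + d$butyrate
  bcfa <- d$isobutyrate + d$methylbutyrate2 + d$isovalerate
  data.frame(sample_id = d$sample_id, total_scfa = scfa, total_bcfa = bcfa,
             ratio = ifelse(bcfa > 0, scfa / bcfa, NA_real_),
             stringsAsFactors = FALSE)
}

#' Group summary (mean, SE, delta, t-test p) for one analyte
#'
#' Per-group mean and standard error of the mean, the unrounded delta
#' \code{mean(HRS) - mean(LRS)}, and the pooled-variance t-test p-value.
#' Replicate collections are averaged per subject first (so each cat
#' contributes once), matching the repeated-measures structure.
#'
#' @param values named numeric vector of per-sample values (names are
#'   sample ids).
#' @param design a \linkS4class{StudyDesign}.
#' @param week restrict to one week; NULL uses all samples.
#' @return One-row data.frame: \code{mean_LRS}, \code{se_LRS},
#'   \code{n_LRS}, \code{mean_HRS}, \code{se_HRS}, \code{n_HRS},
#'   \code{delta}, \code{p}.
#' @export
groupSummary <- function(values, design, week = NULL) {
  stopIfNot(!is.null(names(values)), "values must be named by sample id")
  v <- matrix(values, ncol = 1L, dimnames = list(names(values), "v"))
  sv <- subjectValues(v, design, week)
  out <- list()
  for (g in GROUP_LEVELS) {
    x <- sv$values[sv$group == g, 1L]
    if (length(x) < 2L) stop("group ", g, " needs >= 2 subjects")
    out[[paste0("mean_", g)]] <- mean(x)
    out[[paste0("se_", g)]] <- stats::sd(x) / sqrt(length(x))
    out[[paste0("n_", g)]] <- length(x)
  }
  tt <- twoGroupTTest(v, design, week)
  out$delta <- out$mean_HRS - out$mean_LRS
  out$p <- tt$p
  as.data.frame(out)
}

#' Group table for a full SCFA panel (trial-table layout)
#'
#' One \code{\link{groupSummary}} row per analyte plus rows for the
#' per-sample totals and the SCFA/BCFA ratio.
#'
#' @param panel an \linkS4class{ScfaPanel}.
#' @param design a \linkS4class{StudyDesign}.
#' @param week week to summarize.
#' @param excludeSubjects explicit subject exclusion list (e.g. recorded
#'   statistical outliers); subjects are never auto-removed.
#' @return data.frame, one row per analyte/total/ratio.
#' @export
scfaGroupTable <- function(panel, design, week = NULL,
                           excludeSubjects = character()) {
  d <- designTable(design)
  if (length(excludeSubjects) > 0L)
    design <- studyDesign(d[!d$subject_id %in% excludeSubjects, , drop = FALSE])
  pd <- panelData(panel)
  tot <- scfaTotals(panel)
  rows <- lapply(SCFA_ANALYTES, function(a) {
    cbind(analyte = a,
          groupSummary(setNames(pd[[a]], pd$sample_id), design, week))
  })
  rows <- c(rows, list(
    cbind(analyte = "total_scfa",
          groupSummary(setNames(tot$total_scfa, tot$sample_id), design, week)),
    cbind(analyte = "total_bcfa",
          groupSummary(setNames(tot$total_bcfa, tot$sample_id), design, week)),
    cbind(analyte = "scfa_bcfa_ratio",
          groupSummary(setNames(tot$ratio, tot$sample_id), design, week))))
  do.call(rbind, rows)
}

#' Totals and deltas from published per-analyte group means
#'
#' Reconstructs the Total SCFA / Total BCFA rows and the HRS - LRS
#' deltas of a printed summary table directly from per-analyte group
#' means: by linearity of the mean, the group mean of per-sample totals
#' equals the sum of the per-group analyte means. (The SCFA/BCFA ratio
#' row of such tables is a mean of per-sample ratios and cannot be
#' recovered from group means; it is deliberately absent here.)
#'
#' @param means data.frame with columns \code{analyte} (the six SCFA
#'   analytes), \code{LRS}, \code{HRS} (group means, one week).
#' @return data.frame with rows for the six analytes plus
#'   \code{total_scfa} and \code{total_bcfa}, and columns \code{analyte},
#'   \code{LRS}, \code{HRS}, \code{delta}.
#' @export
scfaMeanTable <- function(means) {
  stopIfNot(all(c("analyte", "LRS", "HRS") %in% names(means)),
            "means needs columns analyte, LRS, HRS")
  miss <- setdiff(SCFA_ANALYTES, means$analyte)
  stopIfNot(length(miss) == 0L,
            "missing analytes: ", paste(miss, collapse = ", "))
  m <- means[match(SCFA_ANALYTES, means$analyte), c("analyte", "LRS", "HRS")]
  straight <- m$analyte %in% c("acetate", "propionate", "butyrate")
  tot <- data.frame(analyte = c("total_scfa", "total_bcfa"),
                    LRS = c(sum(m$LRS[straight]), sum(m$LRS[!straight])),
                    HRS = c(sum(m$HRS[straight]), sum(m$HRS[!straight])),
                    stringsAsFactors = FALSE)
  out <- rbind(m, tot)
  out$delta <- out$HRS - out$LRS
  rownames(out) <- NULL
  out
}

#' Group-mean deltas for a published summary table
#'
#' @param means data.frame with columns \code{index} (or any id column
#'   named by \code{idCol}), \code{LRS}, \code{HRS}.
#' @param idCol name of the identifier column.
#' @return The input with an unrounded \code{delta = HRS - LRS} column.
#' @export
groupMeanDeltas <- function(means, idCol = "index") {
  stopIfNot(all(c(idCol, "LRS", "HRS") %in% names(means)),
            "means needs columns ", idCol, ", LRS, HRS")
  means$delta <- means$HRS - means$LRS
  means
}

#' Hydroxyl:oxo redox pair ratio
#'
#' Ratio of the reduced (hydroxyl) to the oxidized (oxo) member of an
#' NADH:NAD+-coupled redox pair, computed per sample on the raw scale;
#' \code{log2(ratio) = log2(hydroxyl) - log2(oxo)} exactly. The result
#' is flagged \code{derived = TRUE} so the differential stage excludes
#' it from q-value input vectors (a derived ratio is not an independent
#' measurement). Samples with a nonpositive oxo member get NA.
#'
#' @param hydroxyl,oxo named numeric vectors (raw scale, aligned).
#' @param source source amino acid or sugar of the pair.
#' @return data.frame with columns \code{sample_id}, \code{hydroxyl},
#'   \code{oxo}, \code{ratio}, \code{log2_ratio}, \code{source},
#'   \code{derived}.
#' @export
redoxRatio <- function(hydroxyl, oxo, source = "unknown") {
  stopIfNot(length(hydroxyl) == length(oxo),
            "hydroxyl and oxo must be aligned")
  ids <- names(hydroxyl)
  if (is.null(ids)) ids <- as.character(seq_along(hydroxyl))
  ok <- !is.na(oxo) & oxo > 0 & !is.na(hydroxyl) & hydroxyl > 0
  ratio <- ifelse(ok, hydroxyl / oxo, NA_real_)
  data.frame(sample_id = ids, hydroxyl = hydroxyl, oxo = oxo, ratio = ratio,
             log2_ratio = ifelse(ok, log2(hydroxyl) - log2(oxo), NA_real_),
             source = source, derived = TRUE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Nitrogen-free extract (NFE)
#'
#' \code{NFE = 100 - (crude fiber + protein + fat + ash + moisture)},
#' the proximate-analysis remainder approximating digestible
#' carbohydrate.
#'
#' @param diet a \linkS4class{DietComposition}.
#' @return Percentage in [0, 100].
#' @export
nfe <- function(diet) {
  stopIfNot(is(diet, "DietComposition"), "diet must be a DietComposition")
  100 - (diet@crudeFiber + diet@protein + diet@fat + diet@ash + diet@moisture)
}

#' Percent cook (starch gelatinization)
#'
#' \code{(gelatinized starch / total starch) * 100}: the fraction of
#' food starch that is gelatinized and hence enzymatically digestible;
#' low percent cook indicates retained resistant starch.
#'
#' @param gelatinized,total starch percentages; total must be positive
#'   and gelatinized cannot exceed total.
#' @return Percentage in [0, 100].
#' @export
percentCook <- function(gelatinized, total) {
  stopIfNot(total > 0, "total starch must be positive")
  stopIfNot(gelatinized <= total, "gelatinized starch cannot exceed total")
  stopIfNot(gelatinized >= 0, "gelatinized starch must be >= 0")
  gelatinized / total * 100
}

#' Apparent digestibility coefficient
#'
#' \code{(consumed - fecal) / consumed}, reported as a percentage. A
#' fecal mass exceeding intake gives a negative coefficient, which is
#' allowed but flagged with a warning.
#'
#' @param consumed mass consumed (> 0).
#' @param fecal mass recovered in feces (>= 0).
#' @return Percentage (<= 100).
#' @export
apparentDigestibility <- function(consumed, fecal) {
  stopIfNot(consumed > 0, "consumed mass must be positive")
  stopIfNot(fecal >= 0, "fecal mass must be >= 0")
  if (fecal > consumed)
    warning("fecal mass exceeds intake; negative digestibility")
  (consumed - fecal) / consumed * 100
}

#' Organic dry matter
#'
#' \code{100 - (moisture + ash)} percent of the fecal homogenate.
#'
#' @param moisture,ash percentages with sum <= 100.
#' @return Percentage in [0, 100].
#' @export
organicDryMatter <- function(moisture, ash) {
  stopIfNot(moisture >= 0 && ash >= 0, "components must be >= 0")
  stopIfNot(moisture + ash <= 100, "moisture + ash cannot exceed 100%")
  100 - (moisture + ash)
}
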