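#' @import methods
NULL

GROUP_LEVELS <- c("LRS", "HRS")
WEEK_LEVELS <- c(3L, 6L)
SCFA_ANALYTES <- c("acetate", "propionate", "butyrate",
                   "isobutyrate", "methylbutyrate2", "isovalerate")

#' StudyDesign: per-sample metadata for a two-diet repeated-measures trial
#'
#' Holds one row per collected fecal sample: the sample identifier, the
#' subject (cat) it came from, the diet group (\code{LRS} or \code{HRS}),
#' the collection week (3 or 6), and the replicate collection number
#' (1 or 2). Missing collections are represented by absent rows, never
#' imputed.
#'
#' @slot data data.frame with columns \code{sample_id}, \code{subject_id},
#'   \code{group}, \code{week}, \code{collection}.
#' @aliases StudyDesign-class
#' @exportClass StudyDesign
setClass("StudyDesign", representation(data = "data.frame"))

setValidity("StudyDesign", function(object) {
  d <- object@data
  need <- c("sample_id", "subject_id", "group", "week", "collection")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return("design has no rows")
  if (anyDuplicated(d$sample_id)) return("sample_id values must be unique")
  if (!all(d$group %in% GROUP_LEVELS))
    return(paste0("group labels must be in {LRS, HRS}; found: ",
                  paste(unique(setdiff(d$group, GROUP_LEVELS)), collapse = ", ")))
  if (!all(d$week %in% WEEK_LEVELS)) return("week must be 3 or 6")
  if (!all(d$collection %in% c(1L, 2L))) return("collection must be 1 or 2")
  key <- paste(d$subject_id, d$week, d$collection)
  if (anyDuplicated(key))
    return("each (subject_id, week, collection) may appear at most once")
  gx <- tapply(d$group, d$subject_id, function(g) length(unique(g)))
  if (any(gx > 1L)) return("a subject may belong to exactly one group")
  TRUE
})

#' Construct a StudyDesign
#'
#' @param data data.frame with columns \code{sample_id}, \code{subject_id},
#'   \code{group} (\code{"LRS"}/\code{"HRS"}), \code{week} (3 or 6) and
#'   \code{collection} (1 or 2).
#' @return A validated \linkS4class{StudyDesign}.
#' @examples
#' studyDesign(data.frame(
#'   sample_id = c("a", "b"), subject_id = c("s1", "s2"),
#'   group = c("LRS", "HRS"), week = 3L, collection = 1L))
#' @export
studyDesign <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$sample_id <- as.character(data$sample_id)
  data$subject_id <- as.character(data$subject_id)
  data$group <- as.character(data$group)
  data$week <- as.integer(data$week)
  data$collection <- as.integer(data$collection)
  rownames(data) <- NULL
  new("StudyDesign", data = data)
}

#' CountTable: genus-level OTU counts with taxonomy
#'
#' A samples-by-taxa matrix of nonnegative integer counts together with a
#' phylum/family/genus annotation per taxon (genus may be
#' \code{"unknown"}). Raw input to the diversity and compositional stages.
#'
#' @slot counts integer-valued matrix, samples in rows, taxa in columns;
#'   every sample total must be positive.
#' @slot taxonomy data.frame with columns \code{taxon_id}, \code{phylum},
#'   \code{family}, \code{genus}, one row per column of \code{counts}.
#' @aliases CountTable-class
#' @exportClass CountTable
setClass("CountTable", representation(counts = "matrix", taxonomy = "data.frame"))

setValidity("CountTable", function(object) {
  m <- object@counts
  tx <- object@taxonomy
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(m))) return("duplicate sample ids")
  if (anyDuplicated(colnames(m))) return("duplicate taxon ids")
  if (any(is.na(m))) return("counts contain NA")
  if (any(m < 0)) return("counts must be nonnegative")
  if (any(m != round(m))) return("counts must be integers")
  if (any(rowSums(m) <= 0)) {
    bad <- rownames(m)[rowSums(m) <= 0][1L]
    return(paste0("sample '", bad, "' has zero total count"))
  }
  need <- c("taxon_id", "phylum", "family", "genus")
  if (!all(need %in% names(tx)))
    return("taxonomy needs columns taxon_id, phylum, family, genus")
  if (!identical(as.character(tx$taxon_id), colnames(m)))
    return("taxonomy rows must match count columns (same taxa, same order)")
  TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of nonnegative integers, samples x taxa,
#'   with sample rownames and taxon colnames.
#' @param taxonomy optional data.frame (\code{taxon_id}, \code{phylum},
#'   \code{family}, \code{genus}); defaults to all-\code{"unknown"}
#'   annotation.
#' @return A validated \linkS4class{CountTable}.
#' @export
countTable <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = colnames(counts),
                           phylum = "unknown", family = "unknown",
                           genus = "unknown", stringsAsFactors = FALSE)
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  taxonomy$taxon_id <- as.character(taxonomy$taxon_id)
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  new("CountTable", counts = counts, taxonomy = taxonomy)
}

#' FeatureMatrix: metabolite (or transformed microbiome) abundances
#'
#' Samples-by-features matrix carrying a scale tag: \code{"raw"} (strictly
#' positive abundances), \code{"log2"}, or \code{"clr"} (rows sum to ~0).
#' Each feature may carry a biochemical class label (e.g. "dipeptide",
#' "indole") used by the class-level joint tests.
#'
#' @slot values numeric matrix, samples in rows.
#' @slot scale one of \code{"raw"}, \code{"log2"}, \code{"clr"}.
#' @slot featureClass named character vector, one class label per feature.
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", representation(values = "matrix", scale = "character",
                                         featureClass = "character"))

setValidity("FeatureMatrix", function(object) {
  m <- object@values
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("values must have sample rownames and feature colnames")
  if (anyDuplicated(rownames(m))) return("duplicate sample ids")
  if (anyDuplicated(colnames(m))) return("duplicate feature ids")
  if (length(object@scale) != 1L || !object@scale %in% c("raw", "log2", "clr"))
    return("scale must be one of 'raw', 'log2', 'clr'")
  if (any(is.na(m))) return("values contain NA")
  if (object@scale == "raw" && any(m <= 0))
    return("raw-scale values must be strictly positive")
  if (object@scale == "clr" && any(abs(rowSums(m)) > 1e-6))
    return("clr rows must sum to ~0")
  if (!identical(names(object@featureClass), colnames(m)))
    return("featureClass names must match feature columns")
  TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, samples x features, with dimnames.
#' @param scale \code{"raw"} (default), \code{"log2"} or \code{"clr"}.
#' @param featureClass optional named character vector mapping feature ids
#'   to class labels; defaults to \code{"unclassified"}.
#' @return A validated \linkS4class{FeatureMatrix}.
#' @export
featureMatrix <- function(values, scale = c("raw", "log2", "clr"),
                          featureClass = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(featureClass)) {
    featureClass <- setNames(rep("unclassified", ncol(values)), colnames(values))
  } else {
    featureClass <- featureClass[colnames(values)]
    names(featureClass) <- colnames(values)
    featureClass[is.na(featureClass)] <- "unclassified"
  }
  new("FeatureMatrix", values = values, scale = scale,
      featureClass = setNames(as.character(featureClass), colnames(values)))
}

#' DietComposition: proximate analysis of a study food
#'
#' Percent (0-100) components from proximate analysis plus the gelatinized
#' and total starch fractions used for the percent-cook calculation.
#'
#' @slot moisture,fat,protein,crudeFiber,ash numeric percentages.
#' @slot gelatinizedStarch,totalStarch numeric percentages (may be NA when
#'   starch analysis was not run).
#' @aliases DietComposition-class
#' @exportClass DietComposition
setClass("DietComposition",
         representation(moisture = "numeric", fat = "numeric", protein = "numeric",
                        crudeFiber = "numeric", ash = "numeric",
                        gelatinizedStarch = "numeric", totalStarch = "numeric"))

setValidity("DietComposition", function(object) {
  comp <- c(object@moisture, object@fat, object@protein, object@crudeFiber, object@ash)
  if (any(comp < 0 | comp > 100)) return("components must lie in [0, 100]")
  if (sum(comp) > 100 + 1e-9)
    return("moisture + fat + protein + crude fiber + ash must not exceed 100%")
  st <- c(object@gelatinizedStarch, object@totalStarch)
  if (any(!is.na(st) & (st < 0 | st > 100))) return("starch fractions must lie in [0, 100]")
  TRUE
})

#' Construct a DietComposition
#'
#' @param moisture,fat,protein,crudeFiber,ash proximate components, percent.
#' @param gelatinizedStarch,totalStarch starch fractions, percent (optional).
#' @return A validated \linkS4class{DietComposition}.
#' @examples
#' nfe(dietComposition(moisture = 4.9, fat = 18.9, protein = 37.6,
#'                     crudeFiber = 3.2, ash = 6.1))
#' @export
dietComposition <- function(moisture, fat, protein, crudeFiber, ash,
                            gelatinizedStarch = NA_real_, totalStarch = NA_real_) {
  new("DietComposition", moisture = as.numeric(moisture), fat = as.numeric(fat),
      protein = as.numeric(protein), crudeFiber = as.numeric(crudeFiber),
      ash = as.numeric(ash), gelatinizedStarch = as.numeric(gelatinizedStarch),
      totalStarch = as.numeric(totalStarch))
}

#' ScfaPanel: targeted short-chain fatty acid concentrations
#'
#' Per-sample concentrations (ppm) of the three straight-chain SCFA
#' (acetate, propionate, butyrate) and the three branched-chain fatty
#' acids (isobutyrate, 2-methylbutyrate, isovalerate).
#'
#' @slot data data.frame with column \code{sample_id} plus the six analytes.
#' @aliases ScfaPanel-class
#' @exportClass ScfaPanel
setClass("ScfaPanel", representation(data = "data.frame"))

setValidity("ScfaPanel", function(object) {
  d <- object@data
  need <- c("sample_id", SCFA_ANALYTES)
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$sample_id)) return("duplicate sample ids")
  vals <- as.matrix(d[, SCFA_ANALYTES])
  if (any(is.na(vals)) || any(vals < 0)) return("analyte values must be >= 0")
  TRUE
})

#' Construct an ScfaPanel
#'
#' @param data data.frame with columns \code{sample_id}, \code{acetate},
#'   \code{propionate}, \code{butyrate}, \code{isobutyrate},
#'   \code{methylbutyrate2}, \code{isovalerate} (ppm).
#' @return A validated \linkS4class{ScfaPanel}.
#' @export
scfaPanel <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$sample_id <- as.character(data$sample_id)
  rownames(data) <- NULL
  new("ScfaPanel", data = data)
}

#' SyntheticTruth: ground-truth parameters for the study-shaped simulator
#'
#' Records what the generator planted, so downstream recovery can be
#' checked: which features carry group effects (signed, log2 scale), the
#' random-intercept and residual standard deviations on the log2 scale,
#' and the compositional parameters for the count simulator.
#'
#' @slot affectedFeatures named numeric vector of signed log2 effect sizes
#'   (names are feature ids); empty for a null simulation.
#' @slot fractionUp,fractionDown planted fractions of up/down features.
#' @slot subjectSd,residualSd nonnegative standard deviations (log2 scale
#'   for the metabolome; logit scale for counts).
#' @slot taxaBaseLogits baseline log-abundance logits, one per taxon.
#' @slot taxaGroupShift log-fold shift added to HRS samples, one per taxon.
#' @slot librarySizeRange integer pair, inclusive range of sample totals.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(affectedFeatures = "numeric", fractionUp = "numeric",
                        fractionDown = "numeric", subjectSd = "numeric",
                        residualSd = "numeric", taxaBaseLogits = "numeric",
                        taxaGroupShift = "numeric", librarySizeRange = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (object@fractionUp < 0 || object@fractionDown < 0 ||
      object@fractionUp + object@fractionDown > 1)
    return("fractionUp + fractionDown must lie in [0, 1]")
  if (object@subjectSd < 0 || object@residualSd < 0)
    return("standard deviations must be >= 0")
  if (length(object@taxaBaseLogits) != length(object@taxaGroupShift))
    return("taxaBaseLogits and taxaGroupShift must have equal length")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange < 1L) ||
      object@librarySizeRange[1L] > object@librarySizeRange[2L])
    return("librarySizeRange must be an increasing positive integer pair")
  TRUE
})

#' QValueResult: Storey false-discovery-rate estimates
#'
#' @slot pi0 estimated proportion of true nulls, in (0, 1].
#' @slot qvalues q-values aligned to the input p-values.
#' @slot lambdaGrid tuning grid used for the pi0 smoother.
#' @aliases QValueResult-class
#' @exportClass QValueResult
setClass("QValueResult",
         representation(pi0 = "numeric", qvalues = "numeric", lambdaGrid = "numeric"))

setValidity("QValueResult", function(object) {
  if (object@pi0 <= 0 || object@pi0 > 1) return("pi0 must lie in (0, 1]")
  if (any(object@qvalues < 0 | object@qvalues > 1)) return("q-values must lie in [0, 1]")
  TRUE
})

#' PlsModel: NIPALS partial least squares discriminant model
#'
#' @slot weights p x A matrix of unit-norm X-weights.
#' @slot loadings p x A matrix of X-loadings.
#' @slot scores n x A matrix of X-scores (mutually orthogonal).
#' @slot yloadings length-A vector of y-loadings.
#' @slot ssy per-factor explained sum of squares of the centered y.
#' @slot r2y cumulative fraction of y variance explained per factor.
#' @slot q2 per-factor cross-validated Q2 (NA until \code{kfoldQ2} is run).
#' @slot chosenFactors factor count minimizing root mean PRESS (NA until CV).
#' @slot center,scaleVec column centering/scaling applied to X.
#' @slot yMean mean of the 0/1 group code.
#' @aliases PlsModel-class
#' @exportClass PlsModel
setClass("PlsModel",
         representation(weights = "matrix", loadings = "matrix", scores = "matrix",
                        yloadings = "numeric", ssy = "numeric", r2y = "numeric",
                        q2 = "numeric", chosenFactors = "integer",
                        center = "numeric", scaleVec = "numeric", yMean = "numeric"))

setMethod("show", "StudyDesign", function(object) {
  d <- object@data
  cat("StudyDesign:", nrow(d), "samples,", length(unique(d$subject_id)),
      "subjects (", sum(tapply(d$group, d$subject_id, function(g) g[1L]) == "LRS"),
      "LRS /", sum(tapply(d$group, d$subject_id, function(g) g[1L]) == "HRS"),
      "HRS ), weeks", paste(sort(unique(d$week)), collapse = "/"), "\n")
})

setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@counts), "samples x", ncol(object@counts),
      "taxa;", sum(object@taxonomy$genus != "unknown"), "taxa with known genus\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix (", object@scale, " scale): ", nrow(object@values),
      " samples x ", ncol(object@values), " features; ",
      length(unique(object@featureClass)), " classes\n", sep = "")
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel:", ncol(object@weights), "factors fitted")
  if (!is.na(object@chosenFactors))
    cat(";", object@chosenFactors, "chosen by cross-validation")
  cat("\n  cumulative R2Y:",
      paste(sprintf("%.3f", object@r2y), collapse = " "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@affectedFeatures), "affected features (",
      round(100 * object@fractionUp), "% up /", round(100 * object@fractionDown),
      "% down planted );", length(object@taxaBaseLogits), "taxa\n")
})
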