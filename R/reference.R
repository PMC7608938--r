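# Published group-level summary values from the two-diet feline
# resistant-starch feeding trial the pipeline models, shipped as plain
# TSV under inst/extdata. They serve as simulator targets and as worked
# examples for the deterministic table arithmetic.

refPath <- function(file) {
  p <- system.file("extdata", file, package = "dietRS")
  if (p == "") stop("reference file not found: ", file)
  p
}

#' Reference SCFA group means
#'
#' Per-analyte group means and standard errors (ppm) by week from the
#' feeding trial's targeted short-chain fatty acid panel.
#'
#' @return data.frame with columns \code{analyte}, \code{week},
#'   \code{group}, \code{mean}, \code{se}.
#' @export
referenceScfaMeans <- function() {
  utils::read.delim(refPath("scfa_group_means.tsv"), stringsAsFactors = FALSE)
}

#' Reference alpha-diversity group means
#'
#' Group means and standard errors of the alpha-diversity indices
#' (richness S, expH, invSimp, Pielou's J) by week.
#'
#' @return data.frame with columns \code{index}, \code{week},
#'   \code{group}, \code{mean}, \code{se}.
#' @export
referenceAlphaMeans <- function() {
  utils::read.delim(refPath("alpha_group_means.tsv"), stringsAsFactors = FALSE)
}

#' Reference diet proximate compositions
#'
#' Proximate analysis (percent) of the two study foods.
#'
#' @return Named list of \linkS4class{DietComposition} objects
#'   (\code{LRS}, \code{HRS}).
#' @export
referenceDiets <- function() {
  d <- utils::read.delim(refPath("diet_composition.tsv"),
                         stringsAsFactors = FALSE)
  out <- lapply(GROUP_LEVELS, function(g) {
    r <- d[d$group == g, ]
    dietComposition(moisture = r$moisture, fat = r$fat, protein = r$protein,
                    crudeFiber = r$crude_fiber, ash = r$ash)
  })
  names(out) <- GROUP_LEVELS
  out
}

#' Wide per-week view of the reference SCFA means
#'
#' @param week 3 or 6.
#' @return data.frame with columns \code{analyte}, \code{LRS},
#'   \code{HRS}, ready for \code{\link{scfaMeanTable}}.
#' @export
referenceScfaMeansWide <- function(week) {
  ref <- referenceScfaMeans()
  ref <- ref[ref$week == week, ]
  an <- unique(ref$analyte)
  data.frame(analyte = an,
             LRS = ref$mean[ref$group == "LRS"][match(an, ref$analyte[ref$group == "LRS"])],
             HRS = ref$mean[ref$group == "HRS"][match(an, ref$analyte[ref$group == "HRS"])],
             stringsAsFactors = FALSE)
}

#' Wide per-week view of the reference alpha-diversity means
#'
#' @param week 3 or 6.
#' @return data.frame with columns \code{index}, \code{LRS}, \code{HRS},
#'   ready for \code{\link{groupMeanDeltas}}.
#' @export
referenceAlphaMeansWide <- function(week) {
  ref <- referenceAlphaMeans()
  ref <- ref[ref$week == week, ]
  ix <- unique(ref$index)
  data.frame(index = ix,
             LRS = ref$mean[ref$group == "LRS"][match(ix, ref$index[ref$group == "LRS"])],
             HRS = ref$mean[ref$group == "HRS"][match(ix, ref$index[ref$group == "HRS"])],
             stringsAsFactors = FALSE)
}
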