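# Study-shaped synthetic data with known ground truth.
#
# The generator emulates the design of a two-diet feline feeding trial:
# two groups of cats, fecal collections at weeks 3 and 6 with up to two
# replicate collections per cat and per-collection missingness (stool
# production is unreliable, and in the emulated trial 4 of 40 cats never
# produced a sample), a log-normal metabolome with subject random
# intercepts and a planted fraction of group effects, and genus-level
# counts drawn from a logistic-normal multinomial with group-specific
# composition shifts.

#' Construct a SyntheticTruth parameter set
#'
#' Defaults emulate the study conditions the pipeline targets: 736
#' metabolites of which 36% are planted up and 11% down in the HRS group
#' (so 47% carry effects), subject random-intercept sd 0.3 and residual
#' sd 0.5 on the log2 scale, 252 genus-level taxa with log-normal base
#' abundances, and library sizes between 20,000 and 60,000 reads.
#'
#' @param nFeatures number of metabolome features the effect set refers to.
#' @param fractionUp,fractionDown planted fractions of features increased /
#'   decreased in the HRS group.
#' @param effectSize absolute log2 effect of each affected feature.
#' @param subjectSd,residualSd standard deviations (log2 scale).
#' @param nTaxa number of taxa for the count simulator.
#' @param taxaShiftSd sd of the per-taxon HRS log-fold shift (0 = null).
#' @param librarySizeRange inclusive integer range of sample totals.
#' @param seed seed controlling which features are affected and the taxa
#'   parameters.
#' @return A validated \linkS4class{SyntheticTruth}.
#' @examples
#' tr <- syntheticTruth(nFeatures = 50, seed = 1)
#' length(affectedFeatures(tr))
#' @export
syntheticTruth <- function(nFeatures = 736L, fractionUp = 0.36,
                           fractionDown = 0.11, effectSize = 1,
                           subjectSd = 0.3, residualSd = 0.5,
                           nTaxa = 252L, taxaShiftSd = 0.5,
                           librarySizeRange = c(20000L, 60000L),
                           seed = 1L) {
  stopIfNot(nFeatures >= 1L, "nFeatures must be >= 1")
  stopIfNot(fractionUp >= 0 && fractionDown >= 0 &&
              fractionUp + fractionDown <= 1,
            "fractionUp + fractionDown must lie in [0, 1]")
  stopIfNot(subjectSd >= 0 && residualSd >= 0,
            "standard deviations must be >= 0")
  withSeed(childSeed(seed, 1L), {
    nUp <- round(fractionUp * nFeatures)
    nDown <- round(fractionDown * nFeatures)
    ids <- sprintf("feat_%04d", seq_len(nFeatures))
    hit <- sample(ids, nUp + nDown)
    eff <- setNames(c(rep(effectSize, nUp), rep(-effectSize, nDown)), hit)
    baseLogits <- stats::rnorm(nTaxa, mean = 0, sd = 2)
    shift <- if (taxaShiftSd > 0) stats::rnorm(nTaxa, 0, taxaShiftSd) else numeric(nTaxa)
  })
  new("SyntheticTruth", affectedFeatures = eff, fractionUp = fractionUp,
      fractionDown = fractionDown, subjectSd = subjectSd,
      residualSd = residualSd, taxaBaseLogits = baseLogits,
      taxaGroupShift = shift,
      librarySizeRange = as.integer(librarySizeRange))
}

#' Simulate a repeated-measures study design
#'
#' Builds subjects x {week 3, week 6} x {collection 1, 2} sample rows.
#' Each row is dropped independently with probability \code{missingRate}
#' (a cat failing to produce stool at a visit); subjects that lose every
#' row at both weeks are removed entirely, mirroring trial subjects with
#' no successful collections being excluded from analysis.
#'
#' @param nPerGroup integer pair: subjects in the LRS and HRS groups.
#' @param missingRate per-row drop probability in [0, 1).
#' @param seed RNG seed; identical seeds give identical designs.
#' @return A validated \linkS4class{StudyDesign}.
#' @examples
#' d <- simulateDesign(c(20, 20), missingRate = 0, seed = 1)
#' nrow(designTable(d))  # 160 = 40 subjects x 2 weeks x 2 collections
#' @export
simulateDesign <- function(nPerGroup = c(20L, 20L), missingRate = 0.1, seed = 1L) {
  stopIfNot(length(nPerGroup) == 2L && all(nPerGroup >= 2L),
            "nPerGroup must be a pair of integers >= 2")
  stopIfNot(missingRate >= 0 && missingRate < 1,
            "missingRate must lie in [0, 1)")
  n <- sum(nPerGroup)
  subj <- sprintf("S%02d", seq_len(n))
  grp <- rep(GROUP_LEVELS, times = nPerGroup)
  full <- expand.grid(collection = c(1L, 2L), week = WEEK_LEVELS,
                      idx = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  full <- full[order(full$idx, full$week, full$collection), ]
  d <- data.frame(subject_id = subj[full$idx], group = grp[full$idx],
                  week = full$week, collection = full$collection,
                  stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_w%d_c%d", d$subject_id, d$week, d$collection)
  keep <- withSeed(childSeed(seed, 2L),
                   stats::runif(nrow(d)) >= missingRate)
  d <- d[keep, , drop = FALSE]
  surviving <- unique(d$subject_id)
  d <- d[d$subject_id %in% surviving, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("missingRate removed every sample; no design rows remain")
  studyDesign(d[, c("sample_id", "subject_id", "group", "week", "collection")])
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Simulate genus-level counts (logistic-normal multinomial)
#'
#' Per sample, the composition is
#' \code{softmax(baseLogits + groupShift * 1[HRS] + subject noise +
#' sample noise)} and counts are drawn multinomially with a library size
#' uniform over the truth's range. The logit-scale Gaussian noise plays
#' the overdispersion role of a Dirichlet-multinomial while keeping the
#' generative model aligned with the CLR analysis assumptions.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param truth a \linkS4class{SyntheticTruth} (taxa slots are used).
#' @param nTaxa optional override; must not exceed the truth's taxa count.
#' @param seed RNG seed.
#' @return A validated \linkS4class{CountTable} with synthetic taxonomy
#'   (taxa are assigned round-robin to the phyla Bacteroidetes,
#'   Firmicutes, Proteobacteria, Actinobacteria).
#' @export
simulateCounts <- function(design, truth, nTaxa = NULL, seed = 1L) {
  base <- truth@taxaBaseLogits
  shift <- truth@taxaGroupShift
  if (!is.null(nTaxa)) {
    stopIfNot(nTaxa >= 5L, "nTaxa must be >= 5")
    stopIfNot(nTaxa <= length(base),
              "nTaxa exceeds the taxa parameterized in truth")
    base <- base[seq_len(nTaxa)]
    shift <- shift[seq_len(nTaxa)]
  }
  if (all(!is.finite(base))) stop("degenerate taxa logits (all -Inf)")
  d <- designTable(design)
  p <- length(base)
  taxa <- sprintf("otu_%04d", seq_len(p))
  phyla <- rep(c("Bacteroidetes", "Firmicutes", "Proteobacteria",
                 "Actinobacteria"), length.out = p)
  m <- withSeed(childSeed(seed, 3L), {
    subjects <- unique(d$subject_id)
    subjNoise <- matrix(stats::rnorm(length(subjects) * p, 0, truth@subjectSd),
                        nrow = length(subjects),
                        dimnames = list(subjects, NULL))
    sizes <- seq.int(truth@librarySizeRange[1L], truth@librarySizeRange[2L])
    libs <- if (length(sizes) == 1L) rep(sizes, nrow(d))
            else sample(sizes, nrow(d), replace = TRUE)
    out <- matrix(0, nrow(d), p, dimnames = list(d$sample_id, taxa))
    for (i in seq_len(nrow(d))) {
      logits <- base + (d$group[i] == "HRS") * shift +
        subjNoise[d$subject_id[i], ] +
        stats::rnorm(p, 0, truth@residualSd)
      out[i, ] <- stats::rmultinom(1L, libs[i], softmax(logits))[, 1L]
    }
    out
  })
  # guard against all-zero samples in pathological parameterizations
  zero <- rowSums(m) == 0
  if (any(zero)) m[zero, 1L] <- 1
  countTable(m, taxonomy = data.frame(
    taxon_id = taxa, phylum = phyla, family = "synthetic_family",
    genus = sprintf("genus_%04d", seq_len(p)), stringsAsFactors = FALSE))
}

#' Simulate a metabolome with planted group effects
#'
#' On the log2 scale each value is
#' \code{baseline + effect * 1[HRS] + subject intercept + residual};
#' the exported matrix is on the raw scale (\code{2^value}) as a
#' metabolomics platform would report it. The affected set and its signed
#' effects are those recorded in \code{truth}.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nFeatures number of features to generate (effects are applied to
#'   the truth's affected ids that fall inside this range).
#' @param nClasses number of synthetic biochemical classes features are
#'   spread over (round-robin).
#' @param seed RNG seed.
#' @return A raw-scale \linkS4class{FeatureMatrix}.
#' @export
simulateMetabolome <- function(design, truth, nFeatures = 736L,
                               nClasses = 25L, seed = 1L) {
  stopIfNot(nFeatures >= 10L, "nFeatures must be >= 10")
  stopIfNot(truth@subjectSd >= 0 && truth@residualSd >= 0,
            "standard deviations must be >= 0")
  d <- designTable(design)
  ids <- sprintf("feat_%04d", seq_len(nFeatures))
  eff <- setNames(numeric(nFeatures), ids)
  hit <- intersect(names(truth@affectedFeatures), ids)
  eff[hit] <- truth@affectedFeatures[hit]
  m <- withSeed(childSeed(seed, 4L), {
    baseline <- stats::rnorm(nFeatures, mean = 10, sd = 2)
    subjects <- unique(d$subject_id)
    subjInt <- matrix(stats::rnorm(length(subjects) * nFeatures, 0, truth@subjectSd),
                      nrow = length(subjects),
                      dimnames = list(subjects, NULL))
    isH <- as.numeric(d$group == "HRS")
    log2v <- matrix(baseline, nrow(d), nFeatures, byrow = TRUE) +
      outer(isH, eff) + subjInt[d$subject_id, , drop = FALSE] +
      matrix(stats::rnorm(nrow(d) * nFeatures, 0, truth@residualSd),
             nrow(d), nFeatures)
    dimnames(log2v) <- list(d$sample_id, ids)
    2^log2v
  })
  classes <- setNames(sprintf("class_%02d",
                              rep(seq_len(nClasses), length.out = nFeatures)), ids)
  featureMatrix(m, scale = "raw", featureClass = classes)
}

#' Simulate a targeted SCFA panel
#'
#' Log-normal draws around per-group target means for each analyte; the
#' sample mean of each analyte converges to its target as n grows, and a
#' coefficient of variation of zero reproduces the group means exactly.
#' Default targets are the week-3 group means of a feline
#' resistant-starch feeding trial (ppm).
#'
#' @param design a \linkS4class{StudyDesign} (one panel row per sample).
#' @param groupMeans data.frame with columns \code{analyte}, \code{LRS},
#'   \code{HRS}; defaults to \code{\link{referenceScfaMeans}} at week 3.
#' @param cv coefficient of variation of the log-normal draws (>= 0).
#' @param seed RNG seed.
#' @return A validated \linkS4class{ScfaPanel}.
#' @export
simulateScfa <- function(design, groupMeans = NULL, cv = 0.3, seed = 1L) {
  stopIfNot(cv >= 0, "cv must be >= 0")
  if (is.null(groupMeans)) {
    ref <- referenceScfaMeans()
    ref <- ref[ref$week == 3L, ]
    groupMeans <- data.frame(
      analyte = unique(ref$analyte),
      LRS = ref$mean[ref$group == "LRS"][match(unique(ref$analyte),
                                               ref$analyte[ref$group == "LRS"])],
      HRS = ref$mean[ref$group == "HRS"][match(unique(ref$analyte),
                                               ref$analyte[ref$group == "HRS"])],
      stringsAsFactors = FALSE)
  }
  stopIfNot(all(c("analyte", "LRS", "HRS") %in% names(groupMeans)),
            "groupMeans needs columns analyte, LRS, HRS")
  stopIfNot(all(groupMeans$LRS > 0) && all(groupMeans$HRS > 0),
            "group means must be positive")
  miss <- setdiff(SCFA_ANALYTES, groupMeans$analyte)
  stopIfNot(length(miss) == 0L,
            "groupMeans is missing analytes: ", paste(miss, collapse = ", "))
  d <- designTable(design)
  sdlog <- sqrt(log(1 + cv^2))
  out <- data.frame(sample_id = d$sample_id, stringsAsFactors = FALSE)
  draws <- withSeed(childSeed(seed, 5L), {
    sapply(SCFA_ANALYTES, function(a) {
      mu <- ifelse(d$group == "HRS",
                   groupMeans$HRS[groupMeans$analyte == a],
                   groupMeans$LRS[groupMeans$analyte == a])
      if (cv == 0) mu
      else stats::rlnorm(nrow(d), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    })
  })
  out[SCFA_ANALYTES] <- draws
  scfaPanel(out)
}
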