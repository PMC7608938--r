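# Compositional treatment of count data: count-zero-multiplicative (CZM)
# replacement followed by the centered log-ratio (CLR) transform.

#' Bayesian-multiplicative (CZM) zero replacement
#'
#' For each sample i with total count n_i, every zero cell receives the
#' imputed proportion \code{delta_i = fraction / (n_i + 1)} and the
#' nonzero proportions are multiplied by
#' \code{(1 - sum of imputed mass) / (sum of nonzero proportions)} so the
#' row still sums to one. This is the multiplicative replacement with the
#' count-zero-multiplicative detection limit \code{1/(n_i + 1)}; it
#' preserves the rank order (and all ratios) of the nonzero parts.
#'
#' @param x a \linkS4class{CountTable} or samples-x-taxa count matrix.
#' @param fraction fraction of the detection limit imputed for each zero,
#'   in (0, 1); default 0.65.
#' @return Matrix of strictly positive proportions, rows summing to 1
#'   within 1e-9.
#' @examples
#' czmZeroReplace(matrix(c(0, 5, 5), 1, dimnames = list("s1", letters[1:3])),
#'                fraction = 0.55)  # delta = 0.55/11 = 0.05
#' @export
czmZeroReplace <- function(x, fraction = 0.65) {
  stopIfNot(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  m <- if (is(x, "CountTable")) counts(x) else as.matrix(x)
  stopIfNot(all(m >= 0), "counts must be nonnegative")
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("sample '", rownames(m)[tot <= 0][1L], "' is all zeros")
  out <- m / tot
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    delta <- fraction / (tot[i] + 1)
    replaced <- sum(z) * delta
    if (replaced >= 1)
      stop("replaced zero mass >= 1 for sample '", rownames(m)[i],
           "'; too many zeros for its total count")
    out[i, z] <- delta
    out[i, !z] <- out[i, !z] * (1 - replaced) / sum(out[i, !z])
  }
  out
}

#' Centered log-ratio (CLR) transform
#'
#' Each part is divided by the geometric mean of all parts of its sample
#' and natural-log transformed:
#' \code{clr_ij = ln(p_ij) - mean_j ln(p_ij)}. Rows of the result sum to
#' zero (within 1e-8) and the transform is invariant to rescaling a
#' sample by any positive constant, so it may be applied to proportions
#' or to zero-replaced counts interchangeably.
#'
#' @param comp samples-x-taxa matrix of strictly positive values
#'   (typically the output of \code{\link{czmZeroReplace}}).
#' @return Matrix of CLR values with the same dimnames.
#' @examples
#' clrTransform(matrix(c(0.5, 0.25, 0.25), 1,
#'                     dimnames = list("s1", letters[1:3])))
#' @export
clrTransform <- function(comp) {
  m <- as.matrix(comp)
  if (any(m <= 0))
    stop("CLR requires strictly positive entries; run zero replacement first")
  lg <- log(m)
  sweep(lg, 1L, rowMeans(lg), "-")
}

#' Counts to CLR in one step
#'
#' Convenience composition of \code{\link{czmZeroReplace}} and
#' \code{\link{clrTransform}}, returning a clr-scale
#' \linkS4class{FeatureMatrix} ready for the differential and
#' multivariate stages.
#'
#' @param x a \linkS4class{CountTable}.
#' @param fraction CZM fraction, see \code{\link{czmZeroReplace}}.
#' @param identifiedOnly drop taxa with unknown genus before transforming
#'   (the univariate/multivariate stages use identified taxa; diversity
#'   uses all taxa).
#' @return A \linkS4class{FeatureMatrix} with scale \code{"clr"}; feature
#'   classes are the taxon phyla.
#' @export
countsToClr <- function(x, fraction = 0.65, identifiedOnly = FALSE) {
  stopIfNot(is(x, "CountTable"), "x must be a CountTable")
  tx <- taxonomy(x)
  m <- counts(x)
  if (identifiedOnly) {
    keep <- tx$genus != "unknown"
    stopIfNot(any(keep), "no taxa with identified genus")
    m <- m[, keep, drop = FALSE]
    tx <- tx[keep, , drop = FALSE]
  }
  clr <- clrTransform(czmZeroReplace(m, fraction = fraction))
  featureMatrix(clr, scale = "clr",
                featureClass = setNames(tx$phylum, tx$taxon_id))
}
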