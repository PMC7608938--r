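# Hill-number alpha diversity, diversity profiles over order q, and
# 1-CqN beta-diversity profiles. All diversity work is done on raw
# counts/proportions per sample, never on CLR values.

#' Hill number (effective number of taxa) of order q
#'
#' \code{qD = (sum_i p_i^q)^(1/(1-q))} for q != 1, with zero-abundance
#' entries contributing nothing for q > 0 and counting toward richness
#' only when positive. At q = 0 this is richness S; the q -> 1 limit
#' (used whenever |q - 1| < 1e-9) is exp of the Shannon entropy; q = 2
#' gives the inverse Simpson index. Increasing q weights abundant taxa
#' more heavily, and qD is non-increasing in q.
#'
#' @param p vector of nonnegative proportions summing to 1 (tolerance
#'   1e-6; renormalized internally).
#' @param q nonnegative order (scalar).
#' @return Effective taxa count, a real in [1, S].
#' @examples
#' hillNumber(c(0.8, 0.2), 2)  # 1/(0.64 + 0.04) = 1.4706
#' @export
hillNumber <- function(p, q) {
  stopIfNot(length(q) == 1L && q >= 0, "q must be a nonnegative scalar")
  if (any(p < 0)) stop("negative abundance entry")
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector")
  p <- p[p > 0] / s
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample alpha diversity summary
#'
#' Richness S (q = 0), exponential Shannon expH (q = 1), inverse Simpson
#' invSimp (q = 2), and Pielou's evenness J = H / ln(S) (natural-log
#' Shannon entropy H). J is reported as NA for single-taxon samples,
#' where evenness is undefined.
#'
#' @param x a \linkS4class{CountTable} or samples-x-taxa count matrix.
#' @return data.frame with columns \code{sample_id}, \code{S},
#'   \code{expH}, \code{invSimp}, \code{J}; always
#'   \code{1 <= invSimp <= expH <= S}.
#' @export
alphaSummary <- function(x) {
  m <- if (is(x, "CountTable")) counts(x) else as.matrix(x)
  if (any(rowSums(m) <= 0)) stop("empty sample in count table")
  res <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  res$S <- apply(m, 1L, function(r) hillNumber(r / sum(r), 0))
  res$expH <- apply(m, 1L, function(r) hillNumber(r / sum(r), 1))
  res$invSimp <- apply(m, 1L, function(r) hillNumber(r / sum(r), 2))
  res$J <- ifelse(res$S > 1, log(res$expH) / log(res$S), NA_real_)
  res
}

#' Default order-q grid: 0 < q < 10 at intervals of 0.05
#'
#' @return Numeric vector 0.05, 0.10, ..., 9.95.
#' @export
defaultQGrid <- function() seq(0.05, 9.95, by = 0.05)

#' Per-sample diversity profile over a grid of order q
#'
#' Evaluates \code{\link{hillNumber}} for every sample at every q of the
#' grid. Profiles are monotone non-increasing in q; richness (q = 0) is
#' reported separately by \code{\link{alphaSummary}} since the default
#' grid covers the open interval 0 < q < 10.
#'
#' @param x a \linkS4class{CountTable} or count matrix.
#' @param qGrid strictly increasing grid of positive orders.
#' @return Matrix of effective taxa counts, samples x grid points, with
#'   q values as column names.
#' @export
alphaProfile <- function(x, qGrid = defaultQGrid()) {
  stopIfNot(length(qGrid) >= 1L && all(qGrid > 0) && all(diff(qGrid) > 0),
            "qGrid must be strictly increasing and positive")
  m <- if (is(x, "CountTable")) counts(x) else as.matrix(x)
  props <- m / rowSums(m)
  out <- sapply(qGrid, function(q) apply(props, 1L, hillNumber, q = q))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), formatC(qGrid, format = "f", digits = 2)))
  out
}

# Multi-assemblage decomposition at one order q, equal sample weights.
# Returns beta = gamma/alpha in [1, N].
betaOrderQ <- function(props, q) {
  N <- nrow(props)
  pooled <- colMeans(props)
  gamma <- hillNumber(pooled, q)
  pw <- props / N
  pw <- pw[pw > 0]
  alpha <- if (abs(q - 1) < 1e-9) {
    exp(-sum(pw * log(pw))) / N
  } else {
    sum(pw^q)^(1 / (1 - q)) / N
  }
  gamma / alpha
}

# Chao-type overlap CqN of N assemblages from the beta component.
cqnFromBeta <- function(beta, N, q) {
  if (abs(q - 1) < 1e-9) return(1 - log(beta) / log(N))
  ((1 / beta)^(q - 1) - (1 / N)^(q - 1)) / (1 - (1 / N)^(q - 1))
}

#' Beta-diversity profile: q-beta = 1 - CqN over a grid of order q
#'
#' Pools N assemblages with equal weights. At each q the within-sample
#' proportions p_ij give gamma diversity (Hill number of the pooled mean
#' composition) and alpha diversity
#' \code{(1/N) * (sum_ij (p_ij/N)^q)^(1/(1-q))} (q = 1 analytically);
#' their ratio beta = gamma/alpha lies in [1, N] and is converted to the
#' overlap measure CqN, which generalizes Sorensen (q = 0), Horn (q = 1)
#' and Morisita-Horn (q = 2) similarity. The reported dissimilarity
#' \code{qbeta = 1 - CqN} is 0 for identical assemblages and 1 for
#' complete turnover.
#'
#' @param x a \linkS4class{CountTable} or count matrix holding the N >= 2
#'   samples to pool.
#' @param qGrid strictly increasing grid of positive orders.
#' @param label optional assemblage-group label carried in the output.
#' @return data.frame with columns \code{label}, \code{q}, \code{qbeta},
#'   \code{N}.
#' @export
betaProfile <- function(x, qGrid = defaultQGrid(), label = "all") {
  m <- if (is(x, "CountTable")) counts(x) else as.matrix(x)
  N <- nrow(m)
  if (N < 2L) stop("beta diversity needs at least 2 samples")
  stopIfNot(all(qGrid >= 0) && all(diff(qGrid) > 0),
            "qGrid must be strictly increasing and nonnegative")
  props <- m / rowSums(m)
  qbeta <- vapply(qGrid, function(q) {
    beta <- betaOrderQ(props, q)
    1 - cqnFromBeta(beta, N, q)
  }, numeric(1L))
  qbeta <- pmin(pmax(qbeta, 0), 1)  # clip numerical noise at the bounds
  data.frame(label = label, q = qGrid, qbeta = qbeta, N = N,
             stringsAsFactors = FALSE)
}

#' Per-group beta-diversity profiles
#'
#' Pools the samples of each group (by default separately per week, the
#' finest stratum of the design) and computes \code{\link{betaProfile}}
#' for each stratum.
#'
#' @param x a \linkS4class{CountTable}.
#' @param design a \linkS4class{StudyDesign} covering the samples of x.
#' @param by \code{"group_week"} (default) or \code{"group"}.
#' @param qGrid order grid.
#' @return Row-bound data.frame of profiles, one label per stratum.
#' @export
groupBetaProfiles <- function(x, design, by = c("group_week", "group"),
                              qGrid = defaultQGrid()) {
  by <- match.arg(by)
  d <- designTable(design)
  m <- counts(x)
  d <- d[d$sample_id %in% rownames(m), , drop = FALSE]
  strata <- if (by == "group_week") paste0(d$group, "_w", d$week) else d$group
  out <- lapply(split(d$sample_id, strata), function(ids) NULL)
  parts <- lapply(names(out), function(s) {
    ids <- d$sample_id[strata == s]
    if (length(ids) < 2L) return(NULL)
    betaProfile(m[ids, , drop = FALSE], qGrid = qGrid, label = s)
  })
  do.call(rbind, parts)
}

#' Bacteroidetes:Firmicutes ratio per sample
#'
#' Ratio of summed relative abundances of the two phyla. Samples with no
#' Firmicutes reads get NA (undefined ratio) rather than Inf.
#'
#' @param x a \linkS4class{CountTable} whose taxonomy annotates phylum.
#' @return Named numeric vector, one ratio per sample.
#' @export
bfRatio <- function(x) {
  stopIfNot(is(x, "CountTable"), "x must be a CountTable")
  tx <- taxonomy(x)
  for (ph in c("Bacteroidetes", "Firmicutes"))
    if (!ph %in% tx$phylum)
      stop("phylum '", ph, "' absent from the taxonomy annotation")
  m <- counts(x)
  rel <- m / rowSums(m)
  b <- rowSums(rel[, tx$phylum == "Bacteroidetes", drop = FALSE])
  f <- rowSums(rel[, tx$phylum == "Firmicutes", drop = FALSE])
  ifelse(f > 0, b / f, NA_real_)
}
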