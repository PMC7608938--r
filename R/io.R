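# Readers and writers for the tab-delimited interchange formats.
# All downstream stages consume the validated containers built here;
# no other stage reads files directly.

#' Read a genus-level count table from TSV
#'
#' Tab-delimited counts with a header row. In \code{taxa_by_samples}
#' orientation taxa are rows and taxonomy may be supplied as columns
#' named \code{phylum}, \code{family}, \code{genus} alongside the counts;
#' in \code{samples_by_taxa} orientation taxonomy comes from a sidecar
#' file (\code{taxonomyPath}) with columns \code{taxon_id}, \code{phylum},
#' \code{family}, \code{genus}.
#'
#' @param path TSV file; first column holds row identifiers.
#' @param orientation \code{"samples_by_taxa"} or \code{"taxa_by_samples"}.
#' @param taxonomyPath optional sidecar taxonomy TSV.
#' @return A validated \linkS4class{CountTable}, samples x taxa.
#' @export
readCountTable <- function(path,
                           orientation = c("samples_by_taxa", "taxa_by_samples"),
                           taxonomyPath = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- raw[, -1L, drop = FALSE]

  taxcols <- intersect(c("phylum", "family", "genus"), names(raw))
  taxdf <- NULL
  if (length(taxcols) > 0L) {
    if (orientation != "taxa_by_samples")
      stop("in-table taxonomy columns require taxa_by_samples orientation")
    taxdf <- data.frame(taxon_id = ids, stringsAsFactors = FALSE)
    for (cc in c("phylum", "family", "genus"))
      taxdf[[cc]] <- if (cc %in% taxcols) as.character(raw[[cc]]) else "unknown"
    raw <- raw[, setdiff(names(raw), taxcols), drop = FALSE]
  }

  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw, is.numeric, logical(1L)))[1L]
    stop("non-numeric counts in column '", names(raw)[bad], "' of ", path)
  }
  rownames(m) <- ids
  badCell <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(badCell) > 0L)
    stop("negative or non-integer count at row '", rownames(m)[badCell[1L, 1L]],
         "', column '", colnames(m)[badCell[1L, 2L]], "' in ", path)
  if (orientation == "taxa_by_samples") m <- t(m)

  if (!is.null(taxonomyPath)) {
    tx <- utils::read.delim(taxonomyPath, stringsAsFactors = FALSE)
    need <- c("taxon_id", "phylum", "family", "genus")
    if (!all(need %in% names(tx)))
      stop("taxonomy file needs columns: ", paste(need, collapse = ", "))
    taxdf <- tx[match(colnames(m), tx$taxon_id), need]
    if (anyNA(taxdf$taxon_id))
      stop("taxonomy file is missing taxa: ",
           paste(utils::head(colnames(m)[is.na(taxdf$taxon_id)]), collapse = ", "))
  }
  countTable(m, taxonomy = taxdf)
}

#' Write a CountTable to TSV (taxa as rows, taxonomy columns inline)
#'
#' @param x a \linkS4class{CountTable}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeCountTable <- function(x, path) {
  m <- t(counts(x))
  tx <- taxonomy(x)
  out <- data.frame(taxon_id = rownames(m), phylum = tx$phylum,
                    family = tx$family, genus = tx$genus,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from BIOM-format JSON
#'
#' Thin wrapper over the biomformat package for BIOM 1.0 (JSON) OTU
#' tables; observation metadata rows named phylum/family/genus (or a
#' greengenes-style taxonomy vector) populate the taxonomy annotation.
#'
#' @param path BIOM JSON file.
#' @return A validated \linkS4class{CountTable}.
#' @export
readCountTableBiom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("readCountTableBiom requires the biomformat package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  storage.mode(m) <- "double"
  countTable(t(m))
}

#' Read per-sample study metadata from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{subject_id},
#'   \code{group} (\code{LRS}/\code{HRS}), \code{week} (3/6),
#'   \code{collection} (1/2).
#' @return A validated \linkS4class{StudyDesign}.
#' @export
readMetadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group", "week", "collection")
  if (!all(need %in% names(d)))
    stop("metadata file needs columns: ", paste(need, collapse = ", "))
  studyDesign(d)
}

#' Write a StudyDesign to TSV
#'
#' @param x a \linkS4class{StudyDesign}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeMetadata <- function(x, path) {
  utils::write.table(designTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix (metabolome) from TSV
#'
#' Features are rows, samples are columns; an optional sidecar maps
#' feature ids to biochemical classes.
#'
#' @param path TSV; first column is the feature id.
#' @param classPath optional TSV with columns \code{feature_id},
#'   \code{class}.
#' @param scale scale tag of the stored values.
#' @return A validated \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path, classPath = NULL,
                              scale = c("raw", "log2", "clr")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  m <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(m) <- ids
  fc <- NULL
  if (!is.null(classPath)) {
    cl <- utils::read.delim(classPath, stringsAsFactors = FALSE)
    if (!all(c("feature_id", "class") %in% names(cl)))
      stop("class file needs columns feature_id, class")
    fc <- setNames(as.character(cl$class), cl$feature_id)
  }
  featureMatrix(m, scale = scale, featureClass = fc)
}

#' Write a FeatureMatrix to TSV (features as rows)
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(x, path) {
  m <- t(featureValues(x))
  out <- data.frame(feature_id = rownames(m),
                    apply(m, 2L, num12),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("feature", "class", "log2FC_w3", "p_w3", "log2FC_w6",
                    "p_w6", "log2FC_pooled", "p_mixed", "q", "VIP_w3",
                    "VIP_w6", "significant")

#' Write per-feature differential results to TSV
#'
#' Serializes the cascade's main output record (fold changes, p-values,
#' q-values, VIP scores and the dual-criterion flag) with 12 significant
#' digits so a read-back reproduces the written values.
#'
#' @param results data.frame of feature results (see
#'   \code{\link{differentialCascade}}).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data.frame")
  miss <- setdiff(RESULT_COLUMNS, names(results))
  if (length(miss) > 0L)
    stop("results are missing columns: ", paste(miss, collapse = ", "))
  out <- results[, RESULT_COLUMNS]
  for (cc in setdiff(RESULT_COLUMNS, c("feature", "class", "significant")))
    out[[cc]] <- num12(out[[cc]])
  out$significant <- ifelse(results$significant, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a differential results TSV
#'
#' @param path file written by \code{\link{writeResults}}.
#' @return data.frame with the standard result columns.
#' @export
readResults <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(RESULT_COLUMNS, names(d))
  if (length(miss) > 0L)
    stop("result file is missing columns: ", paste(miss, collapse = ", "))
  for (cc in setdiff(RESULT_COLUMNS, c("feature", "class", "significant")))
    d[[cc]] <- as.numeric(d[[cc]])
  d$significant <- as.logical(d$significant)
  d
}
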