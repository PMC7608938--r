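#' Accessor generics
#'
#' Small accessor family for the pipeline's containers: sample and feature
#' identifiers, count/value matrices, taxonomy and class annotation, and
#' the design table.
#'
#' @param object a dietRS container object.
#' @return The requested component (see the methods for each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))

#' @rdname accessors
#' @export
setGeneric("featureScale", function(object) standardGeneric("featureScale"))

#' @rdname accessors
#' @export
setGeneric("featureClasses", function(object) standardGeneric("featureClasses"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setGeneric("subjectGroups", function(object) standardGeneric("subjectGroups"))

#' @rdname accessors
#' @export
setGeneric("panelData", function(object) standardGeneric("panelData"))

#' @rdname accessors
#' @export
setGeneric("affectedFeatures", function(object) standardGeneric("affectedFeatures"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "StudyDesign", function(object) object@data$sample_id)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "CountTable", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "FeatureMatrix", function(object) rownames(object@values))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ScfaPanel", function(object) object@data$sample_id)

#' @rdname accessors
#' @export
setMethod("counts", "CountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("taxonomy", "CountTable", function(object) object@taxonomy)

#' @rdname accessors
#' @export
setMethod("taxonIDs", "CountTable", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("featureIDs", "FeatureMatrix", function(object) colnames(object@values))

#' @rdname accessors
#' @export
setMethod("featureScale", "FeatureMatrix", function(object) object@scale)

#' @rdname accessors
#' @export
setMethod("featureClasses", "FeatureMatrix", function(object) object@featureClass)

#' @rdname accessors
#' @export
setMethod("designTable", "StudyDesign", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("subjectGroups", "StudyDesign", function(object) {
  d <- object@data
  vapply(split(d$group, d$subject_id), `[`, character(1L), 1L)
})

#' @rdname accessors
#' @export
setMethod("panelData", "ScfaPanel", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("affectedFeatures", "SyntheticTruth", function(object) object@affectedFeatures)
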