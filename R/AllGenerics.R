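#' Accessor generics
#'
#' Accessors for the capture-level records, trapping-effort totals, species
#' metadata and filter provenance of a [SurveyDataset-class], and for the
#' counts, presence/absence and site table of a [CommunityMatrix-class].
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot content: a `data.frame` for `records`, `efforts`,
#'   `speciesMeta` and `siteData`; a character vector for `provenance`;
#'   a numeric matrix for `counts`; a logical matrix for `incidence`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("efforts", function(x) standardGeneric("efforts"))

#' @rdname accessors
#' @export
setGeneric("speciesMeta", function(x) standardGeneric("speciesMeta"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("incidence", function(x, ...) standardGeneric("incidence"))

#' @rdname accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @rdname filterRecords
#' @export
setGeneric("filterRecords", function(x, ...) standardGeneric("filterRecords"))

#' @rdname buildAbundanceMatrix
#' @export
setGeneric("buildAbundanceMatrix",
           function(x, ...) standardGeneric("buildAbundanceMatrix"))

#' @rdname trapSuccess
#' @export
setGeneric("trapSuccess", function(x, ...) standardGeneric("trapSuccess"))

#' @rdname accumulationCurve
#' @export
setGeneric("accumulationCurve",
           function(x, ...) standardGeneric("accumulationCurve"))

#' @rdname diversityProfile
#' @export
setGeneric("diversityProfile",
           function(x, ...) standardGeneric("diversityProfile"))

#' @rdname pairwisePartition
#' @export
setGeneric("pairwisePartition",
           function(x, ...) standardGeneric("pairwisePartition"))

#' @rdname multisitePartition
#' @export
setGeneric("multisitePartition",
           function(x, ...) standardGeneric("multisitePartition"))

#' @rdname endemismProfile
#' @export
setGeneric("endemismProfile",
           function(x, meta, ...) standardGeneric("endemismProfile"))

#' @rdname bootstrapEnvelope
#' @export
setGeneric("bootstrapEnvelope",
           function(x, meta, ...) standardGeneric("bootstrapEnvelope"))

#' @rdname endemicRemovalTest
#' @export
setGeneric("endemicRemovalTest",
           function(x, meta, ...) standardGeneric("endemicRemovalTest"))
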