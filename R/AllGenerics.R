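#' @rdname VariantCallSet-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname VariantCallSet-accessors
#' @export
setGeneric("variantType", function(x) standardGeneric("variantType"))

#' @rdname VariantCallSet-accessors
#' @export
setGeneric("filterStatus", function(x) standardGeneric("filterStatus"))

#' @rdname VariantCallSet-accessors
#' @export
setGeneric("regionType", function(x) standardGeneric("regionType"))

#' @rdname VariantCallSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname VariantCallSet-accessors
#' @export
setGeneric("sampleSeries", function(x) standardGeneric("sampleSeries"))

#' Classify binary fixation patterns
#'
#' Dispatches on pattern strings, call matrices or a whole
#' [VariantCallSet-class]; see [classifyPatterns,character-method] and
#' friends.
#'
#' @param x pattern strings, a calls matrix, or a `VariantCallSet`.
#' @param ... passed to methods (`nCold`, `nHot` where needed).
#' @export
setGeneric("classifyPatterns", function(x, ...) standardGeneric("classifyPatterns"))

#' Encode per-sample calls as condition-partitioned pattern strings
#'
#' @param x a calls matrix or a [VariantCallSet-class].
#' @param ... passed to methods (`nCold` for the matrix method).
#' @export
setGeneric("encodePatterns", function(x, ...) standardGeneric("encodePatterns"))
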