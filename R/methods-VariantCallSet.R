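#' Accessors for VariantCallSet
#'
#' `calls()` returns the variants x samples 0/1/NA call matrix;
#' `variantType()`, `filterStatus()`, `regionType()` and `geneIds()` return
#' the corresponding row annotations; `sampleSeries()` reconstructs the
#' [SampleSeries-class] from the column data.
#'
#' @param x a [VariantCallSet-class].
#' @return See each accessor's description.
#' @name VariantCallSet-accessors
#' @aliases calls variantType filterStatus regionType geneIds sampleSeries
NULL

#' @rdname VariantCallSet-accessors
#' @export
setMethod("calls", "VariantCallSet", function(x) assay(x, "calls"))

#' @rdname VariantCallSet-accessors
#' @export
setMethod("variantType", "VariantCallSet", function(x) rowData(x)$variantType)

#' @rdname VariantCallSet-accessors
#' @export
setMethod("filterStatus", "VariantCallSet", function(x) rowData(x)$filterStatus)

#' @rdname VariantCallSet-accessors
#' @export
setMethod("regionType", "VariantCallSet", function(x) rowData(x)$region)

#' @rdname VariantCallSet-accessors
#' @export
setMethod("geneIds", "VariantCallSet", function(x) rowData(x)$geneIds)

#' @rdname VariantCallSet-accessors
#' @export
setMethod("sampleSeries", "VariantCallSet", function(x) {
    gen <- metadata(x)$generations
    if (is.null(gen)) gen <- c(cold = NA_real_, hot = NA_real_)
    SampleSeries(rownames(colData(x)), colData(x)$condition,
                 colData(x)$timeIndex, gen)
})

setMethod("show", "VariantCallSet", function(object) {
    cat("VariantCallSet:", nrow(object), "variants x", ncol(object),
        "samples\n")
    lay <- table(factor(colData(object)$condition, c("cold", "hot")))
    cat("  layout:", lay[["cold"]], "cold |", lay[["hot"]], "hot\n")
    cat("  types:", sum(variantType(object) == "SNP"), "SNP /",
        sum(variantType(object) == "InDel"), "InDel\n")
    fs <- table(factor(filterStatus(object),
                       c("PASS", "FAIL", "UNEVALUATED")))
    cat("  filter:", paste(names(fs), fs, sep = "=", collapse = " "), "\n")
    if (!all(is.na(regionType(object)))) {
        rg <- table(factor(regionType(object), c("genic", "intergenic")))
        cat("  region:", paste(names(rg), rg, sep = "=", collapse = " "), "\n")
    }
    if (!is.null(rowData(object)$patternClass)) {
        pc <- table(rowData(object)$patternClass)
        cat("  classes:", paste(names(pc), pc, sep = "=", collapse = " "), "\n")
    }
})

setMethod("show", "SampleSeries", function(object) {
    lay <- seriesLayout(object)
    cat("SampleSeries:", lay[["cold"]], "cold +", lay[["hot"]], "hot samples\n")
    cat("  ids:", paste(object@sampleId, collapse = " "), "\n")
    cat("  generations: cold =", object@generations[["cold"]],
        ", hot =", object@generations[["hot"]], "\n")
})

setMethod("show", "FilterSpec", function(object) {
    fmt <- function(df) paste(df$annotation, df$comparator, df$threshold,
                              collapse = " || ")
    cat("FilterSpec\n  SNP:  ", fmt(object@snp), "\n  InDel:",
        fmt(object@indel), "\n")
})

#' Export a VariantCallSet as a flat table
#'
#' One row per variant: position, alleles, type, filter status, region,
#' overlapped genes (comma separated), pattern string and class when
#' [classifyPatterns()] has been run.
#'
#' @param x a [VariantCallSet-class].
#' @param row.names,optional ignored (S3 signature compatibility).
#' @param ... ignored.
#' @return A `data.frame`.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.VariantCallSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    rd <- rowData(x)
    df <- data.frame(
        contig = as.character(seqnames(x)),
        pos = start(x),
        ref = rd$ref,
        alt = rd$alt,
        variantType = rd$variantType,
        filterStatus = rd$filterStatus,
        region = rd$region,
        geneIds = vapply(rd$geneIds, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    for (col in c("pattern", "patternClass", "gainAmbiguous"))
        if (!is.null(rd[[col]])) df[[col]] <- rd[[col]]
    df
}
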