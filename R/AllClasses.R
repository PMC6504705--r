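#' Sample series of a two-condition serial-sampling experiment
#'
#' Describes the ordered samples of the experiment: the cold-condition block
#' first, then the hot-condition block, each ordered by sampling time, plus
#' the number of generations elapsed per condition. The default layout
#' mirrors a design with six cold and four hot samples.
#'
#' @slot sampleId character, unique sample identifiers in series order.
#' @slot condition character, `"cold"` or `"hot"` per sample; all cold
#'   samples precede all hot samples.
#' @slot timeIndex integer, sampling time index (>= 1), strictly increasing
#'   within each condition.
#' @slot generations named numeric of length 2 (`cold`, `hot`): generations
#'   elapsed over the experiment in each condition.
#'
#' @seealso [SampleSeries()], [defaultSampleSeries()]
#' @exportClass SampleSeries
setClass("SampleSeries",
    representation(
        sampleId = "character",
        condition = "character",
        timeIndex = "integer",
        generations = "numeric"
    )
)

setValidity("SampleSeries", function(object) {
    msg <- character()
    n <- length(object@sampleId)
    if (length(object@condition) != n || length(object@timeIndex) != n)
        msg <- c(msg, "sampleId, condition and timeIndex must have equal length")
    if (anyDuplicated(object@sampleId))
        msg <- c(msg, "sample ids must be unique")
    if (!all(object@condition %in% c("cold", "hot")))
        msg <- c(msg, "condition must be 'cold' or 'hot'")
    cold <- object@condition == "cold"
    if (any(cold) && any(!cold) && max(which(cold)) > min(which(!cold)))
        msg <- c(msg, "cold-block samples must precede hot-block samples")
    for (cc in c("cold", "hot")) {
        ti <- object@timeIndex[object@condition == cc]
        if (length(ti) && (any(ti < 1L) || any(diff(ti) <= 0)))
            msg <- c(msg, sprintf(
                "time indices must be >= 1 and strictly increasing within '%s'", cc))
    }
    if (!all(c("cold", "hot") %in% names(object@generations)))
        msg <- c(msg, "generations must be named with 'cold' and 'hot'")
    else if (any(object@generations[c("cold", "hot")] <= 0))
        msg <- c(msg, "generation counts must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SampleSeries
#'
#' @param sampleId character vector of unique sample ids, cold block first.
#' @param condition character vector (`"cold"`/`"hot"`), parallel to
#'   `sampleId`.
#' @param timeIndex integer sampling time indices, strictly increasing
#'   within each condition.
#' @param generations named numeric, generations elapsed per condition,
#'   e.g. `c(cold = 102, hot = 181)`.
#'
#' @return A [SampleSeries-class] object.
#' @examples
#' SampleSeries(c("c1", "c2", "h1"), c("cold", "cold", "hot"),
#'              c(1L, 2L, 1L), c(cold = 100, hot = 170))
#' @export
SampleSeries <- function(sampleId, condition, timeIndex, generations) {
    new("SampleSeries",
        sampleId = as.character(sampleId),
        condition = as.character(condition),
        timeIndex = as.integer(timeIndex),
        generations = generations)
}

#' Default 6 cold + 4 hot sample series
#'
#' Convenience constructor for the canonical experiment layout: six
#' cold-condition samples and four hot-condition samples, with per-condition
#' generation counts defaulting to 102 (cold) and 181 (hot).
#'
#' @param nCold,nHot number of cold / hot samples.
#' @param generations named numeric of generations per condition.
#' @return A [SampleSeries-class] object.
#' @examples
#' defaultSampleSeries()
#' @export
defaultSampleSeries <- function(nCold = 6L, nHot = 4L,
                                generations = c(cold = 102, hot = 181)) {
    SampleSeries(
        sampleId = c(paste0("cold", seq_len(nCold)), paste0("hot", seq_len(nHot))),
        condition = rep(c("cold", "hot"), c(nCold, nHot)),
        timeIndex = c(seq_len(nCold), seq_len(nHot)),
        generations = generations)
}

#' Number of cold/hot samples in a series
#' @param series a [SampleSeries-class].
#' @return Named integer vector with elements `cold` and `hot`.
#' @export
seriesLayout <- function(series) {
    stopifnot(is(series, "SampleSeries"))
    c(cold = sum(series@condition == "cold"),
      hot = sum(series@condition == "hot"))
}

#' Hard-filter specification for SNPs and InDels
#'
#' A set of OR-combined exclusion clauses per variant type. A record fails
#' if at least one clause evaluated on its filter annotations is true;
#' clauses whose annotation is absent are skipped.
#'
#' @slot snp data.frame with columns `annotation`, `comparator`
#'   (`"<"`/`">"`), `threshold`; clauses applied to SNP records.
#' @slot indel same structure, applied to InDel records.
#'
#' @seealso [FilterSpec()], [gatkFilterSpec()], [applyHardFilters()]
#' @exportClass FilterSpec
setClass("FilterSpec",
    representation(snp = "data.frame", indel = "data.frame"))

setValidity("FilterSpec", function(object) {
    chk <- function(df, what) {
        msg <- character()
        need <- c("annotation", "comparator", "threshold")
        if (!all(need %in% names(df)))
            return(sprintf("%s clauses need columns %s", what,
                           paste(need, collapse = ", ")))
        if (!all(df$comparator %in% c("<", ">")))
            msg <- c(msg, sprintf("%s comparators must be '<' or '>'", what))
        if (!all(is.finite(df$threshold)))
            msg <- c(msg, sprintf("%s thresholds must be finite", what))
        msg
    }
    msg <- c(chk(object@snp, "SNP"), chk(object@indel, "InDel"))
    if (length(msg)) msg else TRUE
})

#' Construct a FilterSpec
#'
#' @param snp,indel data.frames with columns `annotation`, `comparator`
#'   (`"<"` or `">"`) and `threshold`, one row per exclusion clause.
#' @return A [FilterSpec-class] object.
#' @seealso [gatkFilterSpec()] for the standard hard-filter thresholds.
#' @export
FilterSpec <- function(snp, indel) {
    new("FilterSpec", snp = as.data.frame(snp), indel = as.data.frame(indel))
}

#' Standard GATK-style hard-filter thresholds
#'
#' The conventional hard-filter expressions for haploid short-read calls,
#' applied separately per variant type:
#' SNPs fail on `QD < 1.0 || FS > 30.0 || MQ < 45.0 || SOR > 9 ||
#' MQRankSum < -4.0 || ReadPosRankSum < -10.0`; InDels fail on
#' `QD < 1.0 || FS > 200.0 || MQ < 45.0 || MQRankSum < -6.5 ||
#' ReadPosRankSum < -10.0`.
#'
#' @return A [FilterSpec-class] object.
#' @examples
#' gatkFilterSpec()
#' @export
gatkFilterSpec <- function() {
    FilterSpec(
        snp = data.frame(
            annotation = c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum"),
            comparator = c("<", ">", "<", ">", "<", "<"),
            threshold = c(1.0, 30.0, 45.0, 9, -4.0, -10.0)),
        indel = data.frame(
            annotation = c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
            comparator = c("<", ">", "<", "<", "<"),
            threshold = c(1.0, 200.0, 45.0, -6.5, -10.0)))
}

#' Container for multi-sample haploid variant calls
#'
#' Extends `RangedSummarizedExperiment`. The single assay `"calls"` is an
#' integer matrix (variants x samples) over `{0, 1, NA}`: 0 = reference
#' haplotype, 1 = any variant haplotype, NA = missing call. Row ranges hold
#' the VCF position (1-based) with metadata columns `ref`, `alt` (comma
#' collapsed for multi-allelic sites), `variantType` (`"SNP"`/`"InDel"`),
#' the six filter annotations (`QD`, `FS`, `MQ`, `SOR`, `MQRankSum`,
#' `ReadPosRankSum`), `filterStatus` (`PASS`/`FAIL`/`UNEVALUATED`) and,
#' after [classifyRegion()], `region` (`genic`/`intergenic`) and `geneIds`.
#' Column data mirror the [SampleSeries-class]; per-condition generation
#' counts live in `metadata(x)$generations`.
#'
#' @seealso [readVariants()], [VariantCallSet()], [applyHardFilters()],
#'   [classifyRegion()], [classifyPatterns()]
#' @exportClass VariantCallSet
setClass("VariantCallSet", contains = "RangedSummarizedExperiment")

setValidity("VariantCallSet", function(object) {
    msg <- character()
    if (!"calls" %in% assayNames(object))
        return("assay 'calls' is required")
    m <- assay(object, "calls")
    if (!all(m %in% c(0L, 1L, NA)))
        msg <- c(msg, "calls must be 0, 1 or NA")
    need <- c("ref", "alt", "variantType", "filterStatus")
    miss <- setdiff(need, names(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing rowData column(s):",
                            paste(miss, collapse = ", ")))
    if (!all(c("condition", "timeIndex") %in% names(colData(object))))
        msg <- c(msg, "colData needs 'condition' and 'timeIndex'")
    if (length(msg)) msg else TRUE
})

#' Construct a VariantCallSet
#'
#' @param gr `GRanges` of variant positions (width = reference allele
#'   length) with at least metadata columns `ref`, `alt`; `variantType` is
#'   derived from allele lengths when absent (SNP iff the reference and
#'   every alternate allele have length 1).
#' @param calls integer matrix (variants x samples) over `{0, 1, NA}`.
#' @param series a [SampleSeries-class]; its sample ids must match
#'   `colnames(calls)` (calls are reordered to series order).
#' @return A [VariantCallSet-class].
#' @export
VariantCallSet <- function(gr, calls, series) {
    stopifnot(is(gr, "GRanges"), is(series, "SampleSeries"))
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(colnames(calls)))
        colnames(calls) <- series@sampleId
    if (!all(series@sampleId %in% colnames(calls)))
        stop("calls matrix lacks sample(s): ",
             paste(setdiff(series@sampleId, colnames(calls)), collapse = ", "))
    calls <- calls[, series@sampleId, drop = FALSE]
    rownames(calls) <- NULL
    md <- mcols(gr)
    if (is.null(md$variantType)) {
        altLens <- vapply(strsplit(as.character(md$alt), ",", fixed = TRUE),
                          function(a) max(nchar(a)), integer(1))
        md$variantType <- ifelse(nchar(md$ref) == 1L & altLens == 1L,
                                 "SNP", "InDel")
    }
    for (f in filterAnnotationNames())
        if (is.null(md[[f]])) md[[f]] <- NA_real_
    if (is.null(md$filterStatus)) md$filterStatus <- "UNEVALUATED"
    if (is.null(md$region)) md$region <- NA_character_
    if (is.null(md$geneIds))
        md$geneIds <- CharacterList(rep(list(character()), length(gr)))
    mcols(gr) <- md
    se <- SummarizedExperiment(
        assays = list(calls = calls),
        rowRanges = gr,
        colData = DataFrame(condition = series@condition,
                            timeIndex = series@timeIndex,
                            row.names = series@sampleId),
        metadata = list(generations = series@generations))
    new("VariantCallSet", se)
}

filterAnnotationNames <- function() {
    c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")
}
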