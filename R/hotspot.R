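#' Count variants per gene
#'
#' Tallies how many records overlap each gene, using the per-record
#' `geneIds` assignment from [classifyRegion()]: a variant overlapping two
#' genes increments both. Which records to count (e.g. non-background
#' PASS records) is the caller's subsetting choice.
#'
#' @param x a [VariantCallSet-class] with `geneIds` set, or a
#'   `CharacterList`/list of per-record gene id vectors.
#' @param genes optional annotation `GRanges` (with `gene_id`); required
#'   when `includeZero = TRUE` to enumerate unaffected genes.
#' @param includeZero include genes with zero variants (count 0 rows).
#' @return `data.frame` with columns `gene_id` and `n`, ordered by
#'   decreasing count.
#' @export
countVariantsPerGene <- function(x, genes = NULL, includeZero = FALSE) {
    ids <- if (is(x, "VariantCallSet")) geneIds(x) else x
    flat <- unlist(as.list(ids), use.names = FALSE)
    tab <- table(flat)
    df <- data.frame(gene_id = as.character(names(tab)),
                     n = as.integer(tab), stringsAsFactors = FALSE)
    if (includeZero) {
        if (is.null(genes))
            stop("includeZero = TRUE requires the 'genes' annotation")
        zero <- setdiff(mcols(genes)$gene_id, df$gene_id)
        if (length(zero))
            df <- rbind(df, data.frame(gene_id = zero, n = 0L))
    }
    if (nrow(df) == 0L) return(df)
    df[base::order(-df$n, df$gene_id), , drop = FALSE]
}

#' Call variant hotspots by Z-score
#'
#' Standardises per-gene variant counts, `z = (n - mean(n)) / sd(n)`, and
#' flags genes with `z` strictly above `zThreshold` (default 2.575, the
#' upper 0.5% quantile of the standard normal, i.e. the 99th percentile of
#' a two-sided band). With zero count variance no gene can be an outlier:
#' all z are reported as 0 with a warning and nothing is flagged.
#'
#' @param counts `data.frame` from [countVariantsPerGene()] (columns
#'   `gene_id`, `n`); needs at least two genes.
#' @param zThreshold hotspot calling threshold on z (strict `>`).
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return `data.frame` with columns `gene_id`, `n`, `z`, `hotspot`,
#'   ordered by decreasing z.
#' @examples
#' callHotspots(data.frame(gene_id = letters[1:5], n = c(1, 2, 3, 4, 10)))
#' @export
callHotspots <- function(counts, zThreshold = 2.575,
                         sdType = c("sample", "population")) {
    sdType <- match.arg(sdType)
    if (nrow(counts) < 2L) stop("insufficient genes (need >= 2)")
    n <- counts$n
    s <- sd(n)
    if (sdType == "population")
        s <- sqrt(mean((n - mean(n))^2))
    if (is.na(s) || s == 0) {
        warning("zero variance in per-gene counts; no hotspots callable")
        z <- rep(0, length(n))
    } else {
        z <- (n - mean(n)) / s
    }
    out <- data.frame(gene_id = counts$gene_id, n = n, z = z,
                      hotspot = z > zThreshold, stringsAsFactors = FALSE)
    out[order(-out$z, out$gene_id), , drop = FALSE]
}
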