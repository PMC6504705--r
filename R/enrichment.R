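#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric computation. With the table
#' \preformatted{ a b   (focal & affected,  focal & unaffected)
#'  c d   (other & affected,  other & unaffected)}
#' the one-sided p is the hypergeometric tail at or beyond `a`; the
#' two-sided p sums the point masses of all outcomes whose probability does
#' not exceed that of the observed table (within relative tolerance 1e-7),
#' the same convention as `stats::fisher.test`.
#'
#' @param x 2x2 matrix of non-negative counts, or numeric of length 4 in
#'   row-major order `(a, b, c, d)`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (w.r.t. the focal-and-affected cell `a`).
#' @return The p value.
#' @examples
#' fisherExactTest(c(2, 0, 0, 2))            # 1/3
#' fisherExactTest(c(3, 1, 1, 3), "greater") # 17/70
#' @export
fisherExactTest <- function(x, alternative = c("two.sided", "greater",
                                               "less")) {
    alternative <- match.arg(alternative)
    x <- as.vector(t(x))
    if (length(x) != 4L) stop("need a 2x2 table")
    if (any(x < 0)) stop("negative cell count")
    if (any(x != round(x))) stop("cell counts must be integers")
    a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
    m <- a + b
    n <- cc + d
    k <- a + cc
    if (m + n == 0) stop("empty table")
    support <- max(0, k - n):min(k, m)
    p <- dhyper(support, m, n, k)
    switch(alternative,
        greater = sum(p[support >= a]),
        less = sum(p[support <= a]),
        two.sided = {
            pObs <- p[support == a]
            min(1, sum(p[p <= pObs * (1 + 1e-7)]))
        })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: `q_(i) = min_(j>=i) p_(j) * m / j`
#' clipped to 1, mapped back to input order (`stats::p.adjust`,
#' method "BH").
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Adjusted q values, same order as input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' GO-term enrichment of variant-bearing genes
#'
#' For each GO term `g` annotated to at least one variant-bearing gene, a
#' 2x2 table compares how often `g` is affected by variants against its
#' unaffected occurrences, versus the background of all other gene-GO
#' associations: `a` = variant genes annotated with `g`, `b` = non-variant
#' genes annotated with `g`, `c` = gene-GO associations of variant genes
#' excluding `g`, `d` = associations of non-variant genes excluding `g`.
#' Terms seen fewer than `minCount` times among the variant genes are
#' excluded before testing; Fisher p values are BH-adjusted over the tested
#' terms.
#'
#' @param geneGo named list/`CharacterList`: gene id -> GO ids (the gene
#'   universe).
#' @param variantGenes character vector of variant-bearing gene ids; ids
#'   absent from `geneGo` are dropped with a warning.
#' @param minCount minimum occurrences of a term among variant genes
#'   (default 2).
#' @param alpha significance level on the adjusted q (default 0.05).
#' @param weights optional named numeric per gene (e.g. variant counts);
#'   when given, each variant gene contributes its weight to `a` and `c`
#'   instead of 1.
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return `data.frame`: `go_id`, `a`, `b`, `c`, `d`, `p`, `q`,
#'   `significant`, ordered by q.
#' @export
goEnrichment <- function(geneGo, variantGenes, minCount = 2, alpha = 0.05,
                         weights = NULL,
                         alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    geneGo <- as.list(geneGo)
    if (!length(geneGo)) stop("empty gene -> GO mapping")
    variantGenes <- unique(as.character(variantGenes))
    unknown <- setdiff(variantGenes, names(geneGo))
    if (length(unknown)) {
        warning("dropping ", length(unknown),
                " variant gene(s) absent from the GO mapping")
        variantGenes <- setdiff(variantGenes, unknown)
    }
    if (!length(variantGenes))
        return(data.frame(go_id = character(), a = numeric(),
                          b = numeric(), c = numeric(), d = numeric(),
                          p = numeric(), q = numeric(),
                          significant = logical()))
    w <- setNames(rep(1, length(variantGenes)), variantGenes)
    if (!is.null(weights)) {
        hit <- intersect(names(weights), variantGenes)
        w[hit] <- weights[hit]
    }
    isVar <- names(geneGo) %in% variantGenes
    goVar <- geneGo[isVar]
    goOther <- geneGo[!isVar]
    # weighted occurrences of each term among variant genes
    aTab <- tapply(rep(w[names(goVar)], lengths(goVar)),
                   unlist(goVar, use.names = FALSE), sum)
    bTabAll <- table(unlist(goOther, use.names = FALSE))
    totalVarAssoc <- sum(rep(w[names(goVar)], lengths(goVar)))
    totalOtherAssoc <- sum(lengths(goOther))
    keep <- names(aTab)[aTab >= minCount]
    if (!length(keep))
        return(data.frame(go_id = character(), a = numeric(),
                          b = numeric(), c = numeric(), d = numeric(),
                          p = numeric(), q = numeric(),
                          significant = logical()))
    a <- as.numeric(aTab[keep])
    b <- as.numeric(bTabAll[keep])
    b[is.na(b)] <- 0
    cN <- totalVarAssoc - a
    d <- totalOtherAssoc - b
    p <- vapply(seq_along(keep), function(i)
        fisherExactTest(c(a[i], b[i], cN[i], d[i]), alternative),
        numeric(1))
    q <- bhAdjust(p)
    out <- data.frame(go_id = keep, a = a, b = b, c = cN, d = d, p = p,
                      q = q, significant = q <= alpha,
                      stringsAsFactors = FALSE)
    out[order(out$q, out$p, out$go_id), , drop = FALSE]
}

#' Count k-mer occurrences split by variant overlap
#'
#' Every overlapping window on the forward strand of each sequence is one
#' occurrence of its k-mer; an occurrence is variant-overlapping iff the
#' window contains at least one variant position. Windows containing a
#' non-ACGT character are skipped. Sequences shorter than `k` contribute
#' nothing at that `k`.
#'
#' @param seqs character vector or `DNAStringSet` of (intergenic)
#'   sequences.
#' @param variantPos list (parallel to `seqs`) of 1-based variant
#'   positions within each sequence; defaults to none.
#' @param kMin,kMax range of k-mer lengths (default 1..10).
#' @return `data.frame`: `k`, `kmer`, `variant`, `nonvariant` occurrence
#'   counts.
#' @examples
#' kmerScan("ACGCG", list(3L), kMin = 2, kMax = 2)
#' @export
kmerScan <- function(seqs, variantPos = NULL, kMin = 1L, kMax = 10L) {
    seqs <- toupper(as.character(seqs))
    if (is.null(variantPos)) variantPos <- vector("list", length(seqs))
    stopifnot(length(variantPos) == length(seqs), kMin >= 1L,
              kMax >= kMin)
    acc <- new.env(parent = emptyenv())
    for (i in seq_along(seqs)) {
        s <- seqs[[i]]
        L <- nchar(s)
        if (L == 0L) next
        vp <- variantPos[[i]]
        if (length(vp) && (any(vp < 1L) || any(vp > L)))
            stop("variant position out of sequence bounds")
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        cumBad <- cumsum(!(ch %in% c("A", "C", "G", "T")))
        vmark <- logical(L)
        vmark[vp] <- TRUE
        cumVar <- cumsum(vmark)
        for (k in kMin:kMax) {
            if (k > L) next
            starts <- seq_len(L - k + 1L)
            ends <- starts + k - 1L
            before <- c(0L, cumBad)[starts]
            valid <- (cumBad[ends] - before) == 0L
            if (!any(valid)) next
            hasVar <- (cumVar[ends] - c(0L, cumVar)[starts]) > 0L
            kmers <- substring(s, starts, ends)[valid]
            hv <- hasVar[valid]
            key <- as.character(k)
            prev <- if (!is.null(acc[[key]])) acc[[key]]
                    else list(kmer = character(), hv = logical())
            acc[[key]] <- list(kmer = c(prev$kmer, kmers),
                               hv = c(prev$hv, hv))
        }
    }
    ks <- sort(as.integer(ls(acc)))
    if (length(setdiff(kMin:kMax, ks)))
        message("no informative windows at k = ",
                paste(setdiff(kMin:kMax, ks), collapse = ", "))
    res <- lapply(ks, function(k) {
        e <- acc[[as.character(k)]]
        f <- factor(e$kmer)
        v <- as.integer(rowsum(as.integer(e$hv), f))
        tot <- as.integer(table(f))
        data.frame(k = k, kmer = levels(f), variant = v,
                   nonvariant = tot - v, stringsAsFactors = FALSE)
    })
    if (!length(res))
        return(data.frame(k = integer(), kmer = character(),
                          variant = integer(), nonvariant = integer()))
    do.call(rbind, res)
}

#' k-mer variant-enrichment testing
#'
#' Within each k-mer length separately, each k-mer's
#' (variant, non-variant) occurrence counts are tested against the summed
#' occurrences of all other k-mers of the same length (Fisher's exact
#' test), followed by BH adjustment within the length group. Groups with a
#' single k-mer are untestable and skipped with a warning; k-mers with
#' zero total occurrences are excluded.
#'
#' @param counts `data.frame` from [kmerScan()].
#' @param alpha significance level on q (default 0.05).
#' @param scope `"per_k"` (default): BH within each k-mer length;
#'   `"global"`: one BH family over all lengths.
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return `data.frame`: `k`, `kmer`, `variant`, `nonvariant`,
#'   `otherVariant`, `otherNonvariant`, `p`, `q`, `significant`.
#' @export
kmerEnrichment <- function(counts, alpha = 0.05,
                           scope = c("per_k", "global"),
                           alternative = c("two.sided", "greater",
                                           "less")) {
    scope <- match.arg(scope)
    alternative <- match.arg(alternative)
    counts <- counts[counts$variant + counts$nonvariant > 0L, ,
                     drop = FALSE]
    res <- lapply(split(counts, counts$k), function(g) {
        if (nrow(g) < 2L) {
            warning("k = ", g$k[1L],
                    ": single k-mer in group, untestable; skipped")
            return(NULL)
        }
        totV <- sum(g$variant)
        totN <- sum(g$nonvariant)
        g$otherVariant <- totV - g$variant
        g$otherNonvariant <- totN - g$nonvariant
        g$p <- vapply(seq_len(nrow(g)), function(i)
            fisherExactTest(c(g$variant[i], g$nonvariant[i],
                              g$otherVariant[i], g$otherNonvariant[i]),
                            alternative), numeric(1))
        g
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        return(data.frame(k = integer(), kmer = character(),
                          variant = integer(), nonvariant = integer(),
                          otherVariant = integer(),
                          otherNonvariant = integer(), p = numeric(),
                          q = numeric(), significant = logical()))
    res$q <- if (scope == "global") bhAdjust(res$p)
             else unsplit(lapply(split(res$p, res$k), bhAdjust), res$k)
    res$significant <- res$q <= alpha
    rownames(res) <- NULL
    res[order(res$k, res$q, res$kmer), , drop = FALSE]
}

#' Read a cis-regulatory motif table
#'
#' @param path TSV with columns `name`, `sequence` (uppercase IUPAC) and
#'   optionally `description`.
#' @return `data.frame` with columns `name`, `sequence`, `description`.
#' @export
readMotifTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "sequence") %in% names(df)))
        stop("motif table needs columns 'name' and 'sequence'")
    if (is.null(df$description)) df$description <- NA_character_
    df$sequence <- toupper(df$sequence)
    if (any(!nzchar(df$sequence))) stop("empty motif sequence")
    df[, c("name", "sequence", "description")]
}

#' Annotate k-mers against cis-regulatory motifs
#'
#' A k-mer annotates to every motif whose sequence contains it as a
#' substring, with IUPAC ambiguity codes in the motif matching their
#' nucleotide sets (e.g. `N` matches any base). Hits from k-mers shorter
#' than `confidentMinLen` are partial matches too short to be trusted and
#' are flagged low-confidence.
#'
#' @param enriched `data.frame` with a `kmer` column (typically the
#'   significant rows of [kmerEnrichment()]).
#' @param motifs `data.frame` from [readMotifTable()].
#' @param confidentMinLen minimum k-mer length for a confident hit
#'   (default 6, i.e. length > 5).
#' @return `data.frame`: `kmer`, `motif`, `motifSequence`, `description`,
#'   `confident`; zero rows when nothing matches.
#' @export
annotateMotifs <- function(enriched, motifs, confidentMinLen = 6L) {
    kmers <- unique(as.character(enriched$kmer))
    motifSeqs <- lapply(motifs$sequence, DNAString)
    rows <- list()
    for (km in kmers) {
        hit <- vapply(motifSeqs, function(ms)
            countPattern(km, ms, fixed = "pattern") > 0L, logical(1))
        if (any(hit))
            rows[[km]] <- data.frame(
                kmer = km, motif = motifs$name[hit],
                motifSequence = motifs$sequence[hit],
                description = motifs$description[hit],
                confident = nchar(km) >= confidentMinLen,
                stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(kmer = character(), motif = character(),
                          motifSequence = character(),
                          description = character(),
                          confident = logical()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Read differential-expression flags
#'
#' @param path TSV with columns `gene_id` and `de` (0/1 or logical).
#' @return Named logical vector.
#' @export
readDeFlags <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "de") %in% names(df)))
        stop("DE table needs columns 'gene_id' and 'de'")
    setNames(as.logical(df$de), df$gene_id)
}

#' Overlap of variant-bearing genes with differential expression
#'
#' Builds the 2x2 table of variant-bearing vs differentially-expressed
#' over the genes present in `deFlags` (variant genes outside that
#' universe are dropped with a warning) and returns the two-sided Fisher
#' p.
#'
#' @param variantGenes character vector of variant-bearing gene ids.
#' @param deFlags named logical from [readDeFlags()] (the gene universe).
#' @return List: `table` (2x2 matrix), `p.value`, `n` (genes used).
#' @export
deOverlapTest <- function(variantGenes, deFlags) {
    variantGenes <- unique(as.character(variantGenes))
    if (!length(variantGenes)) stop("empty variant gene set")
    universe <- names(deFlags)
    dropped <- setdiff(variantGenes, universe)
    if (length(dropped))
        warning("dropping ", length(dropped),
                " variant gene(s) absent from the DE universe")
    variantGenes <- intersect(variantGenes, universe)
    if (!length(variantGenes))
        stop("no variant genes in the DE universe")
    isVar <- universe %in% variantGenes
    tab <- matrix(c(sum(isVar & deFlags), sum(isVar & !deFlags),
                    sum(!isVar & deFlags), sum(!isVar & !deFlags)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("variant", "noVariant"),
                                  c("DE", "notDE")))
    list(table = tab, p.value = fisherExactTest(tab),
         n = length(universe))
}

#' Intergenic ranges of a genome
#'
#' The complement of the gene spans over each contig.
#'
#' @param genome `DNAStringSet` from [readGenome()].
#' @param genes annotation `GRanges`.
#' @return `GRanges` of intergenic intervals.
#' @export
intergenicRanges <- function(genome, genes) {
    si <- Seqinfo(names(genome), width(genome))
    g <- GRanges(seqnames(genes), ranges(genes), seqinfo = si)
    gaps <- gaps(reduce(g, ignore.strand = TRUE))
    gaps[strand(gaps) == "*"]
}

#' Extract region sequences and map variants into them
#'
#' Prepares the input of [kmerScan()]: the sequence of each region and the
#' 1-based within-region positions of the variants falling inside it.
#'
#' @param genome `DNAStringSet`.
#' @param regions `GRanges` (e.g. from [intergenicRanges()]).
#' @param vcs optional [VariantCallSet-class]; its record positions are
#'   mapped into the regions.
#' @return List with `seqs` (character) and `variantPos` (list of integer
#'   vectors, parallel to `seqs`).
#' @export
regionSequences <- function(genome, regions, vcs = NULL) {
    seqs <- vapply(seq_along(regions), function(i) {
        ctg <- as.character(seqnames(regions)[i])
        as.character(subseq(genome[[ctg]], start(regions)[i],
                            end(regions)[i]))
    }, character(1))
    vp <- rep(list(integer()), length(regions))
    if (!is.null(vcs) && nrow(vcs) > 0L) {
        pos <- GRanges(seqnames(vcs), IRanges(start(vcs), width = 1L))
        hits <- findOverlaps(pos, regions, ignore.strand = TRUE)
        for (h in seq_along(hits)) {
            i <- subjectHits(hits)[h]
            vp[[i]] <- c(vp[[i]],
                         start(pos)[queryHits(hits)[h]] -
                             start(regions)[i] + 1L)
        }
    }
    list(seqs = seqs, variantPos = vp)
}
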