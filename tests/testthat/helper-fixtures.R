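# Fixture builders; everything is generated in code at test time.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
    library(IRanges)
})

# Minimal pattern-string parser (kept independent of the package's).
patternsToCalls <- function(patterns) {
    rows <- lapply(patterns, function(s) {
        ch <- strsplit(gsub("|", "", s, fixed = TRUE), "")[[1]]
        ch[ch == "."] <- NA_character_
        as.integer(ch)
    })
    do.call(rbind, rows)
}

# VariantCallSet with one record per pattern string, consecutive positions
# on one contig.
makeVcs <- function(patterns, nCold = 6L, nHot = 4L,
                    series = defaultSampleSeries(nCold, nHot),
                    contig = "chr1") {
    m <- patternsToCalls(patterns)
    colnames(m) <- series@sampleId
    gr <- GRanges(contig, IRanges(seq_along(patterns) * 10L, width = 1L))
    mcols(gr)$ref <- rep("A", length(patterns))
    mcols(gr)$alt <- rep("T", length(patterns))
    VariantCallSet(gr, m, series)
}

# Hand-written multi-sample haploid VCF (independent of writeVariantVcf).
writeTestVcf <- function(path, sampleIds, rows) {
    header <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
        "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
        "##contig=<ID=ctg1>",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds), collapse = "\t"))
    writeLines(c(header, rows), path)
    path
}

vcfRow <- function(pos, ref, alt, info, gts, contig = "ctg1") {
    paste(c(contig, pos, ".", ref, alt, "50", ".", info, "GT", gts),
          collapse = "\t")
}

writeTestGff <- function(path, df) {
    lines <- c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       df$contig, df$start, df$end, df$strand, df$id))
    writeLines(lines, path)
    path
}

writeTestFasta <- function(path, seqs) {
    writeLines(unlist(lapply(names(seqs), function(nm)
        c(paste0(">", nm), seqs[[nm]]))), path)
    path
}
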