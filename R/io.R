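#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`; contig ids are the first whitespace
#'   token of each header. `sum(width(x))` is the genome length.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    genome <- readDNAStringSet(path)
    if (length(genome) == 0L) stop("no sequences in ", path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (anyDuplicated(names(genome)))
        stop("duplicate contig id(s): ",
             paste(unique(names(genome)[duplicated(names(genome))]),
                   collapse = ", "))
    genome
}

#' Read a gene -> GO mapping table
#'
#' @param path TSV with columns `gene_id` and `go_id`, one association per
#'   row.
#' @return A named `CharacterList`, one element of GO ids per gene.
#' @export
readGoMap <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "go_id") %in% names(df)))
        stop("GO map needs columns 'gene_id' and 'go_id'")
    CharacterList(split(df$go_id, df$gene_id))
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) coordinates are
#' both normalised to the 1-based closed `GRanges` convention on read. For
#' GFF3, only features of type `gene` are kept when a `type` column is
#' present. GO terms from `goMap` are attached as a `CharacterList` column
#' `go`.
#'
#' @param path GFF3 or BED file (format detected from the extension by
#'   `rtracklayer`).
#' @param goMap optional named `CharacterList` from [readGoMap()].
#' @param genome optional `DNAStringSet`; annotations on contigs absent
#'   from the genome are dropped with a warning, and coordinates beyond the
#'   contig end are an error.
#' @return `GRanges` with metadata columns `gene_id` and `go`.
#' @export
readAnnotation <- function(path, goMap = NULL, genome = NULL) {
    gr <- import(path)
    md <- mcols(gr)
    if (!is.null(md$type) && any(md$type == "gene"))
        gr <- gr[md$type == "gene"]
    ids <- mcols(gr)$ID
    if (is.null(ids)) ids <- mcols(gr)$name
    if (is.null(ids)) ids <- mcols(gr)$Name
    if (is.null(ids) || anyNA(ids))
        stop("annotation features must carry an ID (GFF3 'ID' / BED name)")
    if (anyDuplicated(ids))
        stop("duplicate gene id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (!is.null(genome)) {
        known <- as.character(seqnames(gr)) %in% names(genome)
        if (!all(known)) {
            warning("dropping ", sum(!known),
                    " feature(s) on contig(s) absent from the genome")
            gr <- gr[known]
            ids <- ids[known]
        }
        lens <- width(genome)[match(as.character(seqnames(gr)), names(genome))]
        if (any(end(gr) > lens))
            stop("annotation coordinates exceed contig length")
    }
    out <- granges(gr)
    mcols(out)$gene_id <- as.character(ids)
    go <- CharacterList(rep(list(character()), length(out)))
    if (!is.null(goMap)) {
        hit <- match(mcols(out)$gene_id, names(goMap))
        go[!is.na(hit)] <- goMap[hit[!is.na(hit)]]
    }
    mcols(out)$go <- go
    out
}

#' Read a sample series definition
#'
#' @param path TSV with columns `sample_id`, `condition` (`cold`/`hot`)
#'   and `time_index`.
#' @param generations named numeric, generations per condition.
#' @return A [SampleSeries-class].
#' @export
readSampleSeries <- function(path, generations = c(cold = 102, hot = 181)) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "time_index")
    if (!all(need %in% names(df)))
        stop("series table needs columns ", paste(need, collapse = ", "))
    SampleSeries(df$sample_id, df$condition, df$time_index, generations)
}

#' Read multi-sample haploid variant calls from VCF
#'
#' Haploid genotypes are mapped to a binary presence/absence code: allele
#' index 0 (reference) becomes 0, any non-reference allele index becomes 1
#' (multi-allelic sites collapse to a single presence record), and missing
#' genotypes (`.`) become NA. Filter annotations `QD`, `FS`, `MQ`, `SOR`,
#' `MQRankSum` and `ReadPosRankSum` are taken from the INFO field where
#' present. Records in which no sample carries the variant are dropped.
#'
#' @param path VCF file (v4.x, one GT entry per sample).
#' @param series a [SampleSeries-class]; every series sample must be a VCF
#'   sample column.
#' @return A [VariantCallSet-class] with samples in series order.
#' @export
readVariants <- function(path, series) {
    stopifnot(is(series, "SampleSeries"))
    vcf <- readVcf(path, genome = "unknown")
    gt <- geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT genotype field")
    missing <- setdiff(series@sampleId, colnames(gt))
    if (length(missing))
        stop("sample(s) absent from VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, series@sampleId, drop = FALSE]
    if (any(grepl("[/|]", gt)))
        stop("expected haploid calls, found diploid genotype(s)")
    callMatrix <- matrix(NA_integer_, nrow(gt), ncol(gt),
                         dimnames = dimnames(gt))
    callMatrix[gt == "0"] <- 0L
    idx <- suppressWarnings(as.integer(gt))
    callMatrix[!is.na(idx) & idx > 0L] <- 1L
    bad <- !(gt %in% c(".", "")) & is.na(idx)
    if (any(bad)) stop("unparseable genotype value(s): ",
                       paste(unique(gt[bad]), collapse = ", "))

    gr <- granges(rowRanges(vcf), use.mcols = FALSE)
    names(gr) <- NULL
    mcols(gr)$ref <- as.character(ref(vcf))
    mcols(gr)$alt <- vapply(as(alt(vcf), "CharacterList"), paste,
                            character(1), collapse = ",")
    infoDf <- info(vcf)
    for (f in filterAnnotationNames()) {
        v <- infoDf[[f]]
        mcols(gr)[[f]] <- if (is.null(v)) NA_real_ else as.numeric(v)
    }
    vcs <- VariantCallSet(gr, callMatrix, series)
    carried <- rowSums(calls(vcs) == 1L, na.rm = TRUE) > 0L
    if (!all(carried)) {
        message("dropping ", sum(!carried),
                " record(s) with no variant-carrying sample")
        vcs <- vcs[carried, ]
    }
    vcs
}

#' Write a VariantCallSet as VCF
#'
#' Emits a minimal VCF v4.2 with the binary haploid GT codes and any
#' non-missing filter annotations in INFO. Re-reading the file with
#' [readVariants()] reproduces positions, alleles and calls exactly.
#'
#' @param vcs a [VariantCallSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(vcs, path) {
    stopifnot(is(vcs, "VariantCallSet"))
    samples <- colnames(vcs)
    hdr <- VCFHeader(samples = samples)
    meta(hdr) <- DataFrameList(fileformat = DataFrame(
        Value = "VCFv4.2", row.names = "fileformat"))
    geno(hdr) <- DataFrame(Number = "1", Type = "String",
                           Description = "Genotype", row.names = "GT")
    info(hdr) <- DataFrame(
        Number = rep("1", 6), Type = rep("Float", 6),
        Description = c("Quality by depth", "Fisher strand bias",
                        "RMS mapping quality", "Symmetric odds ratio",
                        "Mapping quality rank sum",
                        "Read position rank sum"),
        row.names = filterAnnotationNames())
    gtChar <- matrix(as.character(calls(vcs)), nrow = nrow(vcs),
                     dimnames = list(NULL, samples))
    gtChar[is.na(gtChar)] <- "."
    rd <- rowData(vcs)
    infoDf <- DataFrame(row.names = seq_len(nrow(vcs)))
    for (f in filterAnnotationNames())
        infoDf[[f]] <- as.numeric(rd[[f]])
    vcf <- VCF(
        rowRanges = granges(rowRanges(vcs), use.mcols = FALSE),
        colData = DataFrame(Samples = seq_along(samples),
                            row.names = samples),
        fixed = DataFrame(
            REF = DNAStringSet(rd$ref),
            ALT = DNAStringSetList(strsplit(rd$alt, ",", fixed = TRUE)),
            QUAL = rep(NA_real_, nrow(vcs)),
            FILTER = rep(".", nrow(vcs))),
        info = infoDf,
        geno = SimpleList(GT = gtChar))
    metadata(vcf)$header <- hdr
    writeVcf(vcf, path)
    invisible(path)
}

#' Apply per-type hard filters
#'
#' Each record is evaluated against the clause set of its variant type. A
#' record fails if at least one clause is true; clauses whose annotation is
#' missing on the record are skipped; a record on which every clause was
#' skipped is marked `UNEVALUATED`.
#'
#' @param vcs a [VariantCallSet-class].
#' @param spec a [FilterSpec-class]; defaults to [gatkFilterSpec()].
#' @return `vcs` with `filterStatus` set to `PASS`, `FAIL` or
#'   `UNEVALUATED`.
#' @export
applyHardFilters <- function(vcs, spec = gatkFilterSpec()) {
    stopifnot(is(vcs, "VariantCallSet"), is(spec, "FilterSpec"))
    rd <- rowData(vcs)
    status <- rep("UNEVALUATED", nrow(vcs))
    nSkipped <- 0L
    for (type in c("SNP", "InDel")) {
        rows <- which(rd$variantType == type)
        if (!length(rows)) next
        clauses <- if (type == "SNP") spec@snp else spec@indel
        anyFail <- rep(FALSE, length(rows))
        anyEval <- rep(FALSE, length(rows))
        for (i in seq_len(nrow(clauses))) {
            v <- as.numeric(rd[[clauses$annotation[i]]][rows])
            hit <- if (clauses$comparator[i] == "<") v < clauses$threshold[i]
                   else v > clauses$threshold[i]
            present <- !is.na(v)
            nSkipped <- nSkipped + sum(!present)
            anyEval <- anyEval | present
            anyFail <- anyFail | (present & hit)
        }
        status[rows[anyFail]] <- "FAIL"
        status[rows[anyEval & !anyFail]] <- "PASS"
    }
    if (nSkipped > 0L)
        message(nSkipped, " clause evaluation(s) skipped (annotation absent)")
    rowData(vcs)$filterStatus <- status
    vcs
}

#' Assign variants to genic or intergenic space
#'
#' A variant is genic iff its VCF position (the first reference base; the
#' deleted span of an InDel is not considered) falls inside at least one
#' gene span; all overlapped gene ids are recorded. Gene spans include
#' UTRs and introns by construction (full gene ranges).
#'
#' @param vcs a [VariantCallSet-class].
#' @param genes `GRanges` from [readAnnotation()] (or any `GRanges` with a
#'   `gene_id` column).
#' @return `vcs` with `region` and `geneIds` row annotations set.
#' @export
classifyRegion <- function(vcs, genes) {
    stopifnot(is(vcs, "VariantCallSet"), is(genes, "GRanges"))
    pos <- GRanges(seqnames(vcs), IRanges(start(vcs), width = 1L))
    hits <- findOverlaps(pos, genes, ignore.strand = TRUE)
    ids <- CharacterList(rep(list(character()), nrow(vcs)))
    if (length(hits)) {
        byQuery <- split(mcols(genes)$gene_id[subjectHits(hits)],
                         factor(queryHits(hits), levels = seq_len(nrow(vcs))))
        ids <- CharacterList(byQuery)
        names(ids) <- NULL
    }
    rowData(vcs)$geneIds <- ids
    rowData(vcs)$region <- ifelse(unname(lengths(ids)) > 0L,
                                  "genic", "intergenic")
    vcs
}
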