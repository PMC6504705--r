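#' Simulation configuration
#'
#' Parameters of the synthetic experiment generator. Defaults emulate a
#' desk-scale version of the study design: a compact haploid genome with a
#' roughly 64% genic fraction and CpG-dense intergenic islands, sampled as
#' 6 cold + 4 hot ordered clones over 102 / 181 generations, with planted
#' trajectory classes at the magnitudes of the real experiment's
#' non-background classes.
#'
#' @slot seed integer master seed; the genome, variant and growth stages
#'   derive their own streams from it (seed, seed+1, seed+2).
#' @slot contigLengths numeric vector of contig lengths (bp).
#' @slot nGenes total gene count, distributed over contigs by length.
#' @slot geneLength mean gene length (bp); individual lengths jitter
#'   +/-20%.
#' @slot islandFraction fraction of intergenic space covered by CpG
#'   islands.
#' @slot islandCgProb probability that an island dinucleotide is "CG".
#' @slot backgroundGc background GC content.
#' @slot goPoolSize number of distinct GO ids in the annotation pool.
#' @slot goPerGene integer range (min, max) of GO terms per gene.
#' @slot nCold,nHot sample layout.
#' @slot generations named numeric: generations per condition.
#' @slot classCounts named numeric of planted class counts (`Background`,
#'   `ColdFixed`, `HotFixed`, `Random`); when empty, counts are drawn from
#'   `mutationRates`.
#' @slot mutationRates named numeric per-base per-generation rates
#'   (`cold`, `hot`) used when `classCounts` is empty.
#' @slot fixationFraction fraction of rate-drawn variants per condition
#'   that are planted as fixed (the rest are random with that condition of
#'   origin).
#' @slot backgroundCount background (reference-error) records planted in
#'   rate-driven mode.
#' @slot snpFraction fraction of planted variants that are SNPs (the rest
#'   are 1-10 bp InDels).
#' @slot cgBias sampling weight multiplier for intergenic positions lying
#'   on a CG dinucleotide (1 = uniform placement).
#' @slot hotspotVariants extra variants planted into one randomly chosen
#'   hotspot gene (0 = none).
#' @slot genicPlacement `"uniform"` (anywhere) or `"per_gene"` (each
#'   non-hotspot variant goes into a distinct gene - the planted design
#'   for hotspot recovery tests).
#' @slot td named numeric mean doubling time in days per condition.
#' @slot tdDrift named numeric relative linear drift of the doubling time
#'   across the series (e.g. -0.3 = 30% faster by the end), centred so the
#'   series mean stays `td`.
#' @slot noiseSd lognormal sd of the multiplicative OD noise.
#' @slot nReplate named numeric: re-plating events per condition.
#' @slot inoculum cells streaked per plate.
#' @slot cellsPerOd OD750 calibration (cells per OD unit).
#' @slot odTarget harvest OD750.
#' @seealso [simulationConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        seed = "integer", contigLengths = "numeric", nGenes = "integer",
        geneLength = "numeric", islandFraction = "numeric",
        islandCgProb = "numeric", backgroundGc = "numeric",
        goPoolSize = "integer", goPerGene = "integer",
        nCold = "integer", nHot = "integer", generations = "numeric",
        classCounts = "numeric", mutationRates = "numeric",
        fixationFraction = "numeric", backgroundCount = "integer",
        snpFraction = "numeric", cgBias = "numeric",
        hotspotVariants = "integer", genicPlacement = "character",
        td = "numeric", tdDrift = "numeric", noiseSd = "numeric",
        nReplate = "numeric", inoculum = "numeric",
        cellsPerOd = "numeric", odTarget = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    probs <- c(object@islandFraction, object@islandCgProb,
               object@backgroundGc, object@snpFraction,
               object@fixationFraction)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(object@contigLengths < 1000))
        msg <- c(msg, "contigs must be at least 1 kb")
    if (length(object@classCounts) &&
        !all(names(object@classCounts) %in%
             c("Background", "ColdFixed", "HotFixed", "Random")))
        msg <- c(msg, "classCounts names must be trajectory classes")
    if (any(object@classCounts < 0)) msg <- c(msg, "counts must be >= 0")
    if (!all(c("cold", "hot") %in% names(object@generations)) ||
        any(object@generations <= 0))
        msg <- c(msg, "generations must be positive and named cold/hot")
    if (any(object@td <= 0)) msg <- c(msg, "doubling times must be positive")
    if (object@cgBias < 0) msg <- c(msg, "cgBias must be >= 0")
    if (!object@genicPlacement %in% c("uniform", "per_gene"))
        msg <- c(msg, "genicPlacement must be 'uniform' or 'per_gene'")
    if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' @param seed master seed.
#' @param contigLengths,nGenes,geneLength genome geometry.
#' @param islandFraction,islandCgProb,backgroundGc sequence composition.
#' @param goPoolSize,goPerGene GO annotation richness.
#' @param nCold,nHot,generations sample layout and generation counts.
#' @param classCounts planted class counts; `NULL` switches to rate-driven
#'   planting.
#' @param mutationRates,fixationFraction,backgroundCount rate-driven mode
#'   parameters.
#' @param snpFraction,cgBias,hotspotVariants,genicPlacement variant
#'   placement.
#' @param td,tdDrift,noiseSd,nReplate,inoculum,cellsPerOd,odTarget growth
#'   series parameters.
#' @return A [SimulationConfig-class].
#' @examples
#' simulationConfig(seed = 1)
#' @export
simulationConfig <- function(
        seed = 1L,
        contigLengths = c(60000, 40000),
        nGenes = 64L,
        geneLength = 1000,
        islandFraction = 0.2,
        islandCgProb = 0.35,
        backgroundGc = 0.4,
        goPoolSize = 150L,
        goPerGene = c(2L, 8L),
        nCold = 6L,
        nHot = 4L,
        generations = c(cold = 102, hot = 181),
        classCounts = c(Background = 100, ColdFixed = 23, HotFixed = 18,
                        Random = 1000),
        mutationRates = c(cold = 2.17e-06, hot = 1.10e-06),
        fixationFraction = 0.035,
        backgroundCount = 100L,
        snpFraction = 0.48,
        cgBias = 1,
        hotspotVariants = 0L,
        genicPlacement = "uniform",
        td = c(cold = 2.70, hot = 1.32),
        tdDrift = c(cold = -0.30, hot = 0),
        noiseSd = 0.1,
        nReplate = c(cold = 6, hot = 10),
        inoculum = 1000,
        cellsPerOd = 1e7,
        odTarget = 0.5) {
    if (is.null(classCounts)) classCounts <- numeric(0)
    new("SimulationConfig",
        seed = as.integer(seed), contigLengths = contigLengths,
        nGenes = as.integer(nGenes), geneLength = geneLength,
        islandFraction = islandFraction, islandCgProb = islandCgProb,
        backgroundGc = backgroundGc, goPoolSize = as.integer(goPoolSize),
        goPerGene = as.integer(goPerGene), nCold = as.integer(nCold),
        nHot = as.integer(nHot), generations = generations,
        classCounts = classCounts, mutationRates = mutationRates,
        fixationFraction = fixationFraction,
        backgroundCount = as.integer(backgroundCount),
        snpFraction = snpFraction, cgBias = cgBias,
        hotspotVariants = as.integer(hotspotVariants),
        genicPlacement = genicPlacement, td = td, tdDrift = tdDrift,
        noiseSd = noiseSd, nReplate = nReplate, inoculum = inoculum,
        cellsPerOd = cellsPerOd, odTarget = odTarget)
}

randomSequence <- function(n, gc) {
    if (n == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# CpG-dense sequence: emit dinucleotides, "CG" with probability cgProb
islandSequence <- function(n, cgProb, gc) {
    pairs <- ceiling(n / 2)
    isCg <- runif(pairs) < cgProb
    out <- character(pairs)
    out[isCg] <- "CG"
    if (any(!isCg))
        out[!isCg] <- vapply(seq_len(sum(!isCg)),
                             function(i) randomSequence(2L, gc),
                             character(1))
    substr(paste(out, collapse = ""), 1L, n)
}

#' Simulate a compact annotated genome
#'
#' Generates random contig sequences with non-overlapping gene spans and
#' CpG-dense islands placed only in intergenic space, plus a gene -> GO
#' annotation. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SimulationConfig-class].
#' @return List: `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id`, `go`), `islands` (`GRanges`), `goMap` (`CharacterList`).
#' @export
simulateGenome <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed)
    nContig <- length(cfg@contigLengths)
    contigIds <- sprintf("ctg%02d", seq_len(nContig))
    genesPer <- round(cfg@nGenes * cfg@contigLengths /
                          sum(cfg@contigLengths))
    genesPer[nContig] <- cfg@nGenes - sum(genesPer[-nContig])
    seqs <- character(nContig)
    geneRows <- list()
    islandRows <- list()
    gid <- 0L
    for (ci in seq_len(nContig)) {
        L <- cfg@contigLengths[ci]
        ng <- genesPer[ci]
        glens <- round(cfg@geneLength * runif(ng, 0.8, 1.2))
        if (sum(glens) + 20 * (ng + 1) > L)
            stop("genes cannot fit on contig ", contigIds[ci],
                 "; reduce nGenes or geneLength, or lengthen contigs")
        gapTotal <- L - sum(glens)
        gaps <- 20L + as.vector(rmultinom(1L, gapTotal - 20L * (ng + 1L),
                                          rep(1, ng + 1L)))
        starts <- integer(ng)
        at <- 1L
        for (gi in seq_len(ng)) {
            at <- at + gaps[gi]
            starts[gi] <- at
            at <- at + glens[gi]
        }
        # islands: carve the central part of randomly chosen gaps
        islandBudget <- round(cfg@islandFraction * gapTotal)
        gapStarts <- c(1L, starts + glens)
        gapEnds <- c(starts - 1L, L)
        ord <- sample(seq_along(gaps))
        isl <- list()
        for (gi in ord) {
            if (islandBudget <= 0) break
            gw <- gapEnds[gi] - gapStarts[gi] + 1L
            if (gw < 100L) next
            w <- min(islandBudget, round(0.6 * gw))
            off <- gapStarts[gi] + floor((gw - w) / 2)
            isl[[length(isl) + 1L]] <- c(off, off + w - 1L)
            islandBudget <- islandBudget - w
        }
        seq <- randomSequence(L, cfg@backgroundGc)
        for (iv in isl)
            substr(seq, iv[1L], iv[2L]) <-
                islandSequence(iv[2L] - iv[1L] + 1L, cfg@islandCgProb,
                               cfg@backgroundGc)
        seqs[ci] <- seq
        if (ng > 0L)
            geneRows[[ci]] <- data.frame(
                contig = contigIds[ci], start = starts,
                end = starts + glens - 1L,
                gene_id = sprintf("g%04d", gid + seq_len(ng)),
                strand = sample(c("+", "-"), ng, replace = TRUE))
        gid <- gid + ng
        if (length(isl))
            islandRows[[ci]] <- data.frame(
                contig = contigIds[ci],
                start = vapply(isl, `[`, numeric(1), 1L),
                end = vapply(isl, `[`, numeric(1), 2L))
    }
    genome <- DNAStringSet(setNames(seqs, contigIds))
    gdf <- do.call(rbind, geneRows)
    genes <- GRanges(gdf$contig, IRanges(gdf$start, gdf$end),
                     strand = gdf$strand,
                     seqinfo = Seqinfo(contigIds, cfg@contigLengths))
    mcols(genes)$gene_id <- gdf$gene_id
    goPool <- sprintf("GO:%07d", seq_len(cfg@goPoolSize))
    goMap <- CharacterList(lapply(seq_len(cfg@nGenes), function(i)
        sample(goPool, sample(cfg@goPerGene[1L]:cfg@goPerGene[2L], 1L))))
    names(goMap) <- gdf$gene_id
    mcols(genes)$go <- goMap
    idf <- do.call(rbind, islandRows)
    islands <- if (is.null(idf)) GRanges() else
        GRanges(idf$contig, IRanges(idf$start, idf$end))
    list(genome = genome, genes = genes, islands = islands, goMap = goMap)
}

randomClassPatterns <- function(nCold, nHot, n, origin = NULL) {
    all <- enumeratePatterns(nCold, nHot)
    cls <- classifyPatterns(all)
    eligible <- all[cls$patternClass == "Random"]
    if (!is.null(origin))
        eligible <- eligible[conditionOfOrigin(eligible) == origin]
    sample(eligible, n, replace = TRUE)
}

fixedPattern <- function(nCold, nHot, gain, condition) {
    block <- paste(c(rep("0", gain - 1L),
                     rep("1", (if (condition == "cold") nCold else nHot) -
                             gain + 1L)), collapse = "")
    zeros <- function(n) paste(rep("0", n), collapse = "")
    if (condition == "cold") paste0(block, "|", zeros(nHot))
    else paste0(zeros(nCold), "|", block)
}

#' Simulate a multi-sample variant table with planted trajectories
#'
#' Plants variants at unique genome positions with known trajectory
#' classes: `Background` records are all-1 (reference errors), fixed
#' variants get a uniformly drawn gain time and stay 1 through the rest of
#' their condition block (the other block all 0), and `Random` records are
#' drawn uniformly from the eligible non-fixed, non-background, non-zero
#' patterns. Placement can be biased toward intergenic CG dinucleotides
#' (`cfg@cgBias`), concentrated one-per-gene (`cfg@genicPlacement =
#' "per_gene"`), and a hotspot gene can receive `cfg@hotspotVariants`
#' extra variants. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SimulationConfig-class].
#' @param sim output of [simulateGenome()].
#' @return List: `vcs` (a [VariantCallSet-class], position sorted),
#'   `ledger` (`data.frame` of planted ground truth: contig, pos, type,
#'   class, gainIndex, origin, region, hotspotGene), `series`.
#' @export
simulateSeriesVariants <- function(cfg, sim) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 1L)
    series <- SampleSeries(
        c(paste0("cold", seq_len(cfg@nCold)),
          paste0("hot", seq_len(cfg@nHot))),
        rep(c("cold", "hot"), c(cfg@nCold, cfg@nHot)),
        c(seq_len(cfg@nCold), seq_len(cfg@nHot)),
        cfg@generations)
    L <- sum(cfg@contigLengths)

    # planted pattern per record
    if (length(cfg@classCounts)) {
        cc <- cfg@classCounts
        get <- function(nm) if (nm %in% names(cc)) cc[[nm]] else 0
        pats <- c(
            rep(paste(paste(rep("1", cfg@nCold), collapse = ""),
                      paste(rep("1", cfg@nHot), collapse = ""), sep = "|"),
                get("Background")),
            vapply(seq_len(get("ColdFixed")), function(i)
                fixedPattern(cfg@nCold, cfg@nHot,
                             sample(cfg@nCold, 1L), "cold"), character(1)),
            vapply(seq_len(get("HotFixed")), function(i)
                fixedPattern(cfg@nCold, cfg@nHot,
                             sample(cfg@nHot, 1L), "hot"), character(1)),
            randomClassPatterns(cfg@nCold, cfg@nHot, get("Random")))
    } else {
        nCold <- rpois(1L, cfg@mutationRates[["cold"]] * L *
                           cfg@generations[["cold"]])
        nHot <- rpois(1L, cfg@mutationRates[["hot"]] * L *
                          cfg@generations[["hot"]])
        mkCond <- function(n, cond) {
            if (n == 0L) return(character(0))
            nFix <- rbinom(1L, n, cfg@fixationFraction)
            nBlock <- if (cond == "cold") cfg@nCold else cfg@nHot
            c(vapply(seq_len(nFix), function(i)
                  fixedPattern(cfg@nCold, cfg@nHot, sample(nBlock, 1L),
                               cond), character(1)),
              randomClassPatterns(cfg@nCold, cfg@nHot, n - nFix,
                                  origin = cond))
        }
        pats <- c(
            rep(paste(paste(rep("1", cfg@nCold), collapse = ""),
                      paste(rep("1", cfg@nHot), collapse = ""), sep = "|"),
                cfg@backgroundCount),
            mkCond(nCold, "cold"), mkCond(nHot, "hot"))
    }
    nVar <- length(pats) + cfg@hotspotVariants
    if (nVar > 0.5 * L)
        stop("requested variant count exceeds available positions")

    # genome-wide position weights: intergenic CG dinucleotide bases get
    # weight cfg@cgBias, everything else 1
    contigIds <- names(sim$genome)
    offsets <- c(0, cumsum(cfg@contigLengths))[seq_along(contigIds)]
    names(offsets) <- contigIds
    hotspotGene <- NA_character_
    hotspotPos <- integer(0)
    if (cfg@hotspotVariants > 0L) {
        gi <- sample(length(sim$genes), 1L)
        hotspotGene <- mcols(sim$genes)$gene_id[gi]
        hotspotPos <- offsets[[as.character(seqnames(sim$genes)[gi])]] +
            sample(start(sim$genes)[gi]:end(sim$genes)[gi],
                   cfg@hotspotVariants)
    }
    nPlain <- length(pats)
    if (cfg@genicPlacement == "per_gene") {
        pool <- setdiff(seq_along(sim$genes),
                        match(hotspotGene, mcols(sim$genes)$gene_id))
        if (nPlain > length(pool))
            stop("per_gene placement needs at least as many genes as ",
                 "variants")
        gsel <- sample(pool, nPlain)
        plainPos <- vapply(gsel, function(gi)
            offsets[[as.character(seqnames(sim$genes)[gi])]] +
                sample(start(sim$genes)[gi]:end(sim$genes)[gi], 1L),
            numeric(1))
    } else {
        w <- rep(1, L)
        if (cfg@cgBias != 1) {
            ig <- intergenicRanges(sim$genome, sim$genes)
            for (ctg in contigIds) {
                hits <- matchPattern("CG", sim$genome[[ctg]])
                cgStarts <- start(hits)
                igc <- ig[as.character(seqnames(ig)) == ctg]
                inIg <- rep(FALSE, width(sim$genome)[match(ctg, contigIds)])
                for (j in seq_along(igc))
                    inIg[start(igc)[j]:end(igc)[j]] <- TRUE
                keep <- cgStarts[inIg[cgStarts]]
                w[offsets[[ctg]] + c(keep, keep + 1L)] <- cfg@cgBias
            }
        }
        avail <- setdiff(seq_len(L), hotspotPos)
        plainPos <- sample(avail, nPlain, prob = w[avail])
    }
    gpos <- c(plainPos, hotspotPos)
    pats <- c(pats, rep(randomClassPatterns(cfg@nCold, cfg@nHot,
                                            max(1L, cfg@hotspotVariants)),
                        length.out = cfg@hotspotVariants))

    ctgIdx <- findInterval(gpos, c(0, cumsum(cfg@contigLengths)),
                           left.open = TRUE)
    contig <- contigIds[ctgIdx]
    pos <- as.integer(gpos - offsets[contig])

    # alleles
    isSnp <- runif(nVar) < cfg@snpFraction
    ctgLen <- setNames(cfg@contigLengths, contigIds)
    ref <- character(nVar)
    alt <- character(nVar)
    for (i in seq_len(nVar)) {
        base <- as.character(subseq(sim$genome[[contig[i]]], pos[i],
                                    pos[i]))
        if (base == "N") base <- "A"
        if (isSnp[i]) {
            ref[i] <- base
            alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        } else if (runif(1) < 0.5 ||
                   pos[i] + 10L > ctgLen[[contig[i]]]) {  # insertion
            ref[i] <- base
            ins <- paste(sample(c("A", "C", "G", "T"),
                                sample(10L, 1L), replace = TRUE),
                         collapse = "")
            alt[i] <- paste0(base, ins)
        } else {  # deletion
            dl <- sample(10L, 1L)
            ref[i] <- as.character(subseq(sim$genome[[contig[i]]], pos[i],
                                          pos[i] + dl))
            alt[i] <- base
        }
    }

    callsM <- patternStringsToMatrix(pats)
    colnames(callsM) <- series@sampleId
    gr <- GRanges(contig, IRanges(pos, width = nchar(ref)),
                  seqinfo = Seqinfo(contigIds, cfg@contigLengths))
    mcols(gr)$ref <- ref
    mcols(gr)$alt <- alt
    mcols(gr)$QD <- round(runif(nVar, 5, 30), 2)
    mcols(gr)$FS <- round(runif(nVar, 0, 10), 2)
    mcols(gr)$MQ <- round(runif(nVar, 50, 60), 2)
    mcols(gr)$SOR <- round(runif(nVar, 0.5, 3), 2)
    mcols(gr)$MQRankSum <- round(rnorm(nVar), 2)
    mcols(gr)$ReadPosRankSum <- round(rnorm(nVar), 2)
    vcs <- VariantCallSet(gr, callsM, series)
    vcs <- classifyRegion(vcs, sim$genes)
    vcs <- classifyPatterns(vcs)

    ord <- order(match(contig, contigIds), pos)
    vcs <- vcs[ord, ]
    rd <- rowData(vcs)
    ledger <- data.frame(
        contig = as.character(seqnames(vcs)),
        pos = start(vcs),
        type = rd$variantType,
        class = as.character(rd$patternClass),
        gainIndex = rd$gainIndex,
        origin = as.character(conditionOfOrigin(rd$pattern)),
        region = rd$region,
        inHotspotGene = vapply(rd$geneIds, function(g)
            !is.na(hotspotGene) && hotspotGene %in% g, logical(1)),
        stringsAsFactors = FALSE)
    attr(ledger, "hotspotGene") <- hotspotGene
    attr(ledger, "seed") <- cfg@seed
    list(vcs = vcs, ledger = ledger, series = series)
}

#' Simulate a plating growth series
#'
#' Each condition is re-plated `cfg@nReplate` times; the true doubling
#' time drifts linearly by `cfg@tdDrift` across the series around the mean
#' `cfg@td`. Harvest OD values carry multiplicative lognormal noise
#' (`cfg@noiseSd`); with zero noise, [doublingTime()] inverts the
#' generator exactly. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SimulationConfig-class].
#' @return `data.frame`: `condition`, `day`, `od750`, `inoculum`,
#'   `true_td`.
#' @export
simulateGrowth <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 2L)
    rows <- lapply(c("cold", "hot"), function(cond) {
        n <- cfg@nReplate[[cond]]
        frac <- if (n > 1L) (seq_len(n) - 1) / (n - 1) - 0.5 else 0
        tdi <- cfg@td[[cond]] * (1 + cfg@tdDrift[[cond]] * frac)
        doublings <- log2(cfg@odTarget * cfg@cellsPerOd / cfg@inoculum)
        dt <- tdi * doublings
        data.frame(
            condition = cond, day = cumsum(dt),
            od750 = cfg@odTarget * exp(rnorm(n, 0, cfg@noiseSd)),
            inoculum = cfg@inoculum, true_td = tdi,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Run the full generator
#'
#' @param cfg a [SimulationConfig-class].
#' @return List with `genome`, `genes`, `islands`, `goMap` (from
#'   [simulateGenome()]), `vcs`, `ledger`, `series` (from
#'   [simulateSeriesVariants()]) and `growth` (from [simulateGrowth()]).
#' @export
simulateExperiment <- function(cfg) {
    sim <- simulateGenome(cfg)
    sv <- simulateSeriesVariants(cfg, sim)
    c(sim, sv, list(growth = simulateGrowth(cfg)))
}

#' Write a simulated experiment to standard formats
#'
#' Emits FASTA (genome), GFF3 (genes), VCF (variants), the ground-truth
#' ledger TSV, the growth TSV, the GO map TSV, the series TSV and a
#' key=value echo of the configuration.
#'
#' @param sim output of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @param cfg the [SimulationConfig-class] used (for the config echo).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, cfg = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    genes <- sim$genes
    mcols(genes)$ID <- mcols(genes)$gene_id
    mcols(genes)$type <- "gene"
    mcols(genes)$go <- NULL
    export(genes, file.path(dir, "genes.gff3"), format = "gff3")
    writeVariantVcf(sim$vcs, file.path(dir, "variants.vcf"))
    write.table(sim$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$growth, file.path(dir, "growth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    goDf <- data.frame(
        gene_id = rep(names(sim$goMap), lengths(sim$goMap)),
        go_id = unlist(sim$goMap, use.names = FALSE))
    write.table(goDf, file.path(dir, "go_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ser <- sim$series
    write.table(
        data.frame(sample_id = ser@sampleId, condition = ser@condition,
                   time_index = ser@timeIndex),
        file.path(dir, "series.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(cfg)) {
        sl <- slotNames(cfg)
        vals <- vapply(sl, function(s)
            paste(slot(cfg, s), collapse = ","), character(1))
        writeLines(paste0(sl, "=", vals), file.path(dir, "config.txt"))
    }
    invisible(dir)
}
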