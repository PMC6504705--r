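smallCfg <- function(seed = 5L, ...) {
    simulationConfig(
        seed = seed, contigLengths = c(30000, 20000), nGenes = 30L,
        classCounts = c(Background = 15, ColdFixed = 5, HotFixed = 4,
                        Random = 50), ...)
}

test_that("the generator is deterministic given the seed", {
    cfg <- smallCfg()
    a <- simulateExperiment(cfg)
    b <- simulateExperiment(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$ledger, b$ledger)
    expect_identical(a$growth, b$growth)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeSimulation(a, d1, cfg)
    writeSimulation(b, d2, cfg)
    for (f in c("genome.fa", "genes.gff3", "growth.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    # a different seed changes the genome
    expect_false(identical(
        as.character(simulateGenome(smallCfg(seed = 6L))$genome),
        as.character(a$genome)))
})

test_that("simulated genomes have the requested geometry", {
    cfg <- simulationConfig(seed = 2L, contigLengths = 100000,
                            nGenes = 50L, geneLength = 1000,
                            classCounts = c(Random = 10))
    sim <- simulateGenome(cfg)
    expect_equal(sum(width(sim$genome)), 100000L)
    expect_equal(length(sim$genes), 50L)
    genicFrac <- sum(width(sim$genes)) / sum(width(sim$genome))
    expect_gt(genicFrac, 0.4)
    expect_lt(genicFrac, 0.6)
    # genes do not overlap and stay within the contig
    expect_equal(length(reduce(sim$genes, ignore.strand = TRUE)), 50L)
    expect_true(all(end(sim$genes) <= 100000L))
    # islands are intergenic only
    expect_equal(length(findOverlaps(sim$islands, sim$genes)), 0L)
    expect_error(
        simulateGenome(simulationConfig(contigLengths = 10000,
                                        nGenes = 50L)),
        "cannot fit")
})

test_that("CpG islands are CG-dense relative to background", {
    cfg <- simulationConfig(seed = 3L, contigLengths = 80000,
                            nGenes = 40L, islandCgProb = 0.4)
    sim <- simulateGenome(cfg)
    cgDensity <- function(s) {
        ch <- strsplit(s, "")[[1]]
        mean(ch[-length(ch)] == "C" & ch[-1] == "G")
    }
    ctg <- as.character(sim$genome[[1]])
    islandSeqs <- vapply(seq_along(sim$islands), function(i)
        substr(ctg, start(sim$islands)[i], end(sim$islands)[i]),
        character(1))
    expect_gt(mean(vapply(islandSeqs, cgDensity, numeric(1))),
              2 * cgDensity(ctg))
})

test_that("planted trajectory classes are recovered exactly", {
    cfg <- smallCfg()
    sim <- simulateExperiment(cfg)
    expect_equal(as.integer(table(sim$ledger$class)[
        c("Background", "ColdFixed", "HotFixed", "Random")]),
        c(15L, 5L, 4L, 50L))
    # the classifier re-derives the planted class from the calls alone
    rederived <- classifyPatterns(calls(sim$vcs), nCold = 6L, nHot = 4L)
    expect_equal(as.character(rederived$patternClass), sim$ledger$class)
    # positions unique and sorted within contigs
    key <- paste(sim$ledger$contig, sim$ledger$pos)
    expect_false(any(duplicated(key)))
    expect_false(is.unsorted(order(sim$ledger$contig, sim$ledger$pos)))
})

test_that("absent classes stay absent", {
    cfg <- simulationConfig(
        seed = 9L, contigLengths = 30000, nGenes = 20L,
        classCounts = c(Background = 10, HotFixed = 5, Random = 30))
    sim <- simulateExperiment(cfg)
    expect_false("ColdFixed" %in% sim$ledger$class)
})

test_that("rate-driven planting matches the configured mutation rates", {
    cfg <- simulationConfig(
        seed = 13L, contigLengths = c(120000, 80000), nGenes = 100L,
        classCounts = NULL,
        mutationRates = c(cold = 2.17e-05, hot = 1.10e-05))
    sim <- simulateSeriesVariants(cfg, simulateGenome(cfg))
    L <- 200000
    led <- sim$ledger[sim$ledger$class != "Background", ]
    for (cond in c("cold", "hot")) {
        lambda <- cfg@mutationRates[[cond]] * L *
            cfg@generations[[cond]]
        got <- sum(led$origin == cond, na.rm = TRUE)
        expect_lt(abs(got - lambda), 3 * sqrt(lambda) + 1)
        rate <- estimateMutationRate(got, L, cfg@generations[[cond]])
        expect_equal(rate, cfg@mutationRates[[cond]],
                     tolerance = 3 * sqrt(lambda) / lambda)
    }
})

test_that("a planted hotspot gene is the unique Z-score outlier", {
    cfg <- simulationConfig(
        seed = 17L, contigLengths = c(120000, 80000), nGenes = 170L,
        geneLength = 1000,
        classCounts = c(Background = 20, ColdFixed = 5, HotFixed = 5,
                        Random = 120),
        hotspotVariants = 9L, genicPlacement = "per_gene")
    sim <- simulateExperiment(cfg)
    hotspotGene <- attr(sim$ledger, "hotspotGene")
    keep <- sim$ledger$class %in% c("ColdFixed", "HotFixed", "Random")
    counts <- countVariantsPerGene(sim$vcs[keep, ])
    called <- callHotspots(counts)
    expect_equal(called$gene_id[called$hotspot], hotspotGene)
})

test_that("noise-free growth series invert to the configured doubling times", {
    cfg <- simulationConfig(seed = 4L, noiseSd = 0,
                            classCounts = c(Random = 1))
    growth <- simulateGrowth(cfg)
    for (cond in c("cold", "hot")) {
        g <- growth[growth$condition == cond, ]
        dt <- doublingTime(g$day, g$od750, g$inoculum,
                           cellsPerOd = cfg@cellsPerOd)
        expect_equal(dt$intervals$td, g$true_td, tolerance = 1e-9)
        expect_equal(dt$meanTd, cfg@td[[cond]], tolerance = 1e-9)
    }
})

test_that("a 30% doubling-time drift is detected as a trend with high power", {
    reps <- 500
    hits <- 0
    for (i in seq_len(reps)) {
        cfg <- simulationConfig(seed = 1000L + i, noiseSd = 0.1,
                                classCounts = c(Random = 1))
        g <- simulateGrowth(cfg)
        g <- g[g$condition == "cold", ]
        td <- suppressWarnings(
            doublingTime(g$day, g$od750, g$inoculum,
                         cellsPerOd = cfg@cellsPerOd)$intervals$td)
        td <- td[!is.na(td)]
        p <- jonckheereTerpstra(as.list(td), alternative = "decreasing",
                                method = "normal")$p.value
        if (p <= 0.05) hits <- hits + 1
    }
    expect_gt(hits / reps, 0.8)
})

test_that("simulation output files are consumable by the readers", {
    cfg <- smallCfg(seed = 23L)
    sim <- simulateExperiment(cfg)
    dir <- withr::local_tempdir()
    writeSimulation(sim, dir, cfg)
    genome <- readGenome(file.path(dir, "genome.fa"))
    expect_equal(sum(width(genome)), 50000L)
    ann <- readAnnotation(file.path(dir, "genes.gff3"),
                          goMap = readGoMap(file.path(dir, "go_map.tsv")),
                          genome = genome)
    expect_equal(length(ann), 30L)
    expect_true(all(lengths(ann$go) >= 2L))
    series <- readSampleSeries(file.path(dir, "series.tsv"))
    vcs <- readVariants(file.path(dir, "variants.vcf"), series)
    expect_equal(nrow(vcs), nrow(sim$vcs))
    growth <- readGrowthTable(file.path(dir, "growth.tsv"))
    expect_equal(nrow(growth), 16L)
})
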