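test_that("Fisher's exact test reproduces hand-enumerated tables", {
    expect_equal(fisherExactTest(c(2, 0, 0, 2)), 1 / 3, tolerance = 1e-12)
    expect_equal(fisherExactTest(c(3, 1, 1, 3), "greater"), 17 / 70,
                 tolerance = 1e-12)
    # zero margin: only one table is possible
    expect_equal(fisherExactTest(c(0, 0, 3, 5)), 1)
    expect_equal(fisherExactTest(c(2, 3, 0, 0)), 1)
    expect_error(fisherExactTest(c(-1, 2, 3, 4)), "negative")
    expect_error(fisherExactTest(c(1.5, 2, 3, 4)), "integer")
})

test_that("Fisher p agrees with stats::fisher.test across alternatives", {
    set.seed(5)
    for (i in 1:200) {
        tab <- matrix(rpois(4, 6), 2)
        for (alt in c("two.sided", "greater", "less")) {
            ours <- fisherExactTest(tab, alt)
            ref <- stats::fisher.test(tab, alternative = alt)$p.value
            expect_equal(ours, ref, tolerance = 1e-9)
        }
    }
})

test_that("BH adjustment matches the step-up construction", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.037), 0.037)
    set.seed(8)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # permutation invariance
    perm <- sample(50)
    expect_equal(bhAdjust(p[perm]), q[perm])
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GO enrichment flags a term concentrated in variant genes", {
    set.seed(21)
    genes <- sprintf("g%03d", 1:100)
    goPool <- sprintf("GO:%07d", 1:40)
    geneGo <- setNames(lapply(genes, function(g) sample(goPool, 5)), genes)
    variant <- genes[1:3]
    # plant a term in all three variant genes and nowhere else
    for (g in variant) geneGo[[g]] <- union(geneGo[[g]], "GO:9999999")
    for (g in setdiff(genes, variant))
        geneGo[[g]] <- setdiff(geneGo[[g]], "GO:9999999")
    res <- goEnrichment(geneGo, variant)
    row <- res[res$go_id == "GO:9999999", ]
    expect_equal(row$a, 3)
    expect_equal(row$b, 0)
    expect_true(row$significant)
    # the Fisher input is reconstructed correctly
    expect_equal(row$p, fisherExactTest(c(row$a, row$b, row$c, row$d)),
                 tolerance = 1e-12)
})

test_that("GO terms below the minimum variant count are excluded", {
    geneGo <- list(g1 = c("GO:1", "GO:2"), g2 = c("GO:1"),
                   g3 = c("GO:2", "GO:3"), g4 = c("GO:3"))
    res <- goEnrichment(geneGo, c("g1", "g2"), minCount = 2)
    expect_equal(res$go_id, "GO:1")  # GO:2 seen once among variant genes
    res1 <- goEnrichment(geneGo, c("g1", "g2"), minCount = 1)
    expect_setequal(res1$go_id, c("GO:1", "GO:2"))
    expect_warning(none <- goEnrichment(geneGo, "gX"), "absent")
    expect_equal(nrow(none), 0L)
    expect_error(goEnrichment(list(), "g1"), "empty")
})

test_that("k-mer windows split by variant overlap as enumerated by hand", {
    got <- kmerScan("ACGCG", list(3L), kMin = 2, kMax = 2)
    expect_equal(got, data.frame(k = 2L, kmer = c("AC", "CG", "GC"),
                                 variant = c(0L, 1L, 1L),
                                 nonvariant = c(1L, 1L, 0L)))
    # no variant positions: everything is non-variant
    quiet <- kmerScan("ACGCG", kMin = 2, kMax = 2)
    expect_equal(sum(quiet$variant), 0L)
    expect_equal(sum(quiet$nonvariant), 4L)
})

test_that("k-mer occurrence totals are conserved and non-ACGT windows skip", {
    set.seed(12)
    seqs <- c(paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                    collapse = ""),
              paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                    collapse = ""))
    vp <- list(sort(sample(300, 10)), sort(sample(150, 5)))
    counts <- kmerScan(seqs, vp, kMin = 1, kMax = 4)
    for (k in 1:4) {
        sub <- counts[counts$k == k, ]
        expect_equal(sum(sub$variant + sub$nonvariant),
                     (300 - k + 1) + (150 - k + 1))
    }
    withN <- kmerScan("ACGNACG", kMin = 2, kMax = 2)
    # windows GN and NA are dropped: AC, CG (x2), GN, NA, AC -> 4 valid
    expect_equal(sum(withN$variant + withN$nonvariant), 4L)
    expect_message(kmerScan("ACG", kMin = 5, kMax = 5), "no informative")
})

test_that("k-mer enrichment recovers a planted CG mutation bias", {
    set.seed(33)
    seq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    ch <- strsplit(seq, "")[[1]]
    cg <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
    w <- rep(1, nchar(seq))
    w[c(cg, cg + 1L)] <- 10      # ten-fold placement bias on CG bases
    vp <- sample(nchar(seq), 300, prob = w)
    res <- kmerEnrichment(kmerScan(seq, list(vp), kMin = 2, kMax = 2))
    row <- res[res$kmer == "CG", ]
    expect_true(row$significant)
    expect_equal(row$p,
                 fisherExactTest(c(row$variant, row$nonvariant,
                                   row$otherVariant, row$otherNonvariant)),
                 tolerance = 1e-12)
})

test_that("palindromic k-mer counts are strand-choice invariant", {
    set.seed(55)
    L <- 2000L
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    vp <- sort(sample(L, 40))
    rc <- as.character(Biostrings::reverseComplement(DNAString(seq)))
    fwd <- kmerScan(seq, list(vp), kMin = 2, kMax = 2)
    rev <- kmerScan(rc, list(L - vp + 1L), kMin = 2, kMax = 2)
    for (col in c("variant", "nonvariant"))
        expect_equal(fwd[fwd$kmer == "CG", col],
                     rev[rev$kmer == "CG", col])
})

test_that("degenerate k-mer groups are skipped", {
    one <- data.frame(k = 5L, kmer = "AAAAA", variant = 2L,
                      nonvariant = 10L)
    expect_warning(res <- kmerEnrichment(one), "untestable")
    expect_equal(nrow(res), 0L)
    zero <- data.frame(k = 1L, kmer = c("A", "C", "G"),
                       variant = c(2L, 1L, 0L),
                       nonvariant = c(10L, 12L, 0L))
    res2 <- kmerEnrichment(zero)
    expect_setequal(res2$kmer, c("A", "C"))
})

test_that("motif annotation honours substring and IUPAC matching", {
    motifs <- data.frame(
        name = c("RE1", "OCT", "AmbigBox"),
        sequence = c("GGGCGCGGAACAAGG", "CGCGGATC", "ANTCG"),
        description = c("repressor element", "octamer", "test"))
    hits <- annotateMotifs(data.frame(kmer = "CGCGG"), motifs)
    expect_setequal(hits$motif, c("RE1", "OCT"))
    expect_false(any(hits$confident))  # 5-mer: below the confident length
    hits6 <- annotateMotifs(data.frame(kmer = "CGCGGA"), motifs)
    expect_true(all(hits6$confident))
    # N in the motif matches any base
    amb <- annotateMotifs(data.frame(kmer = "AGTCG"), motifs)
    expect_equal(amb$motif, "AmbigBox")
    expect_equal(nrow(annotateMotifs(data.frame(kmer = "TTTTTTTT"),
                                     motifs)), 0L)
})

test_that("DE overlap builds the right table and detects dependence", {
    # deterministic extreme: all variant genes DE, nothing else DE
    genes <- sprintf("g%02d", 1:20)
    de <- setNames(genes %in% genes[1:5], genes)
    res <- deOverlapTest(genes[1:5], de)
    expect_equal(unname(res$table), matrix(c(5, 0, 0, 15), 2,
                                           byrow = TRUE))
    expect_equal(res$p.value, fisherExactTest(res$table),
                 tolerance = 1e-12)
    expect_lt(res$p.value, 0.05)

    # independent planted sets: no association expected
    set.seed(77)
    genes <- sprintf("g%04d", 1:1000)
    de <- setNames(runif(1000) < 0.10, genes)
    variant <- sample(genes, 100)
    pNull <- deOverlapTest(variant, de)$p.value
    expect_gt(pNull, 0.05)

    expect_error(deOverlapTest(character(0), de), "empty")
    expect_warning(deOverlapTest(c(variant[1], "missing"), de),
                   "dropping")
})
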