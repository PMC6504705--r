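test_that("canonical trajectory strings classify as documented", {
    got <- classifyPatterns(c(
        "110011|0000", "000000|0101", "011010|0101",  # fuzzy gain/loss
        "111111|0000", "000000|0111",                 # fixed trajectories
        "111111|1111", "000000|0000",                 # degenerate
        "000001|0000", "000011|0000",                 # late cold fixation
        "000000|0001", "000000|0011",                 # late hot fixation
        "000000|1111", "0.0000|1111"))
    expect_equal(got$patternClass[1:3], factor(rep("Random", 3),
                 levels = patternClassLevels()), ignore_attr = FALSE)
    expect_equal(as.character(got$patternClass),
                 c("Random", "Random", "Random", "ColdFixed", "HotFixed",
                   "Background", "NoVariant", "ColdFixed", "ColdFixed",
                   "HotFixed", "HotFixed", "HotFixed", "Unresolved"))
    # gain before the first sample point cannot be dated
    expect_equal(got$gainAmbiguous,
                 c(rep(FALSE, 3), TRUE, rep(FALSE, 7), TRUE, FALSE))
    expect_equal(got$gainIndex[c(4, 5, 8, 9)], c(1L, 2L, 6L, 5L))
})

test_that("mixed-condition fixation is Random (condition exclusivity)", {
    got <- classifyPatterns(c("011111|0011", "111111|1110", "000001|0001"))
    expect_equal(as.character(got$patternClass), rep("Random", 3))
})

test_that("the 6|4 layout enumerates to the expected class census", {
    pats <- enumeratePatterns(6, 4)
    expect_length(pats, 1024L)
    tab <- table(classifyPatterns(pats)$patternClass)
    expect_equal(tab[["ColdFixed"]], 6L)
    expect_equal(tab[["HotFixed"]], 4L)
    expect_equal(tab[["Background"]], 1L)
    expect_equal(tab[["NoVariant"]], 1L)
    expect_equal(tab[["Random"]], 1012L)
})

test_that("class totals are conserved and swapping blocks swaps the fixed labels", {
    set.seed(7)
    for (rep in 1:5) {
        nCold <- sample(2:6, 1)
        nHot <- sample(2:6, 1)
        m <- matrix(sample(c(0L, 1L), 50 * (nCold + nHot), replace = TRUE),
                    nrow = 50)
        cls <- classifyPatterns(m, nCold = nCold, nHot = nHot)
        expect_equal(sum(table(cls$patternClass)), 50L)
        swapped <- cbind(m[, nCold + seq_len(nHot), drop = FALSE],
                         m[, seq_len(nCold), drop = FALSE])
        cls2 <- classifyPatterns(swapped, nCold = nHot, nHot = nCold)
        map <- c(Background = "Background", ColdFixed = "HotFixed",
                 HotFixed = "ColdFixed", Random = "Random",
                 NoVariant = "NoVariant", Unresolved = "Unresolved")
        expect_equal(as.character(cls2$patternClass),
                     unname(map[as.character(cls$patternClass)]))
    }
})

test_that("encoding orders calls cold-block-first and renders missing as '.'", {
    series <- defaultSampleSeries()
    vcs <- makeVcs(c("110011|0000", "000000|0101", "1.1111|0000"))
    expect_equal(encodePatterns(vcs),
                 c("110011|0000", "000000|0101", "1.1111|0000"))
    m <- patternsToCalls("010101|1010")
    expect_equal(encodePatterns(m, nCold = 6L), "010101|1010")
})

test_that("pattern summaries use explicit denominators", {
    s <- summarizePatterns(rep(c("Background", "ColdFixed", "HotFixed",
                                 "Random"), c(10, 3, 2, 5)))
    expect_equal(s$backgroundPct, 50)
    expect_equal(s$counts[["ColdFixed"]], 3L)
    expect_equal(unname(s$classPct["ColdFixed"]), 30)

    # study-scale worked example: 2578 background of 3896 filtered
    big <- summarizePatterns(rep(c("Background", "Random"), c(2578, 1318)))
    expect_equal(round(big$backgroundPct, 2), 66.17)

    # non-background percentages over the 1243 interpretable records
    nb <- summarizePatterns(rep(c("ColdFixed", "HotFixed", "Random"),
                                c(23, 18, 1202)))
    expect_equal(round(unname(nb$classPct["Random"]), 1), 96.7)
    expect_equal(round(unname(nb$classPct["ColdFixed"]), 2), 1.85)
    expect_equal(round(unname(nb$classPct["HotFixed"]), 2), 1.45)

    empty <- summarizePatterns(character(0))
    expect_true(is.na(empty$backgroundPct))
    expect_true(all(is.na(empty$classPct)))
    expect_equal(sum(empty$counts), 0L)
})

test_that("unresolved records are excluded from percentage denominators", {
    s <- summarizePatterns(c("Background", "Random", "Unresolved"))
    expect_equal(s$nClassified, 2L)
    expect_equal(s$backgroundPct, 50)
    expect_equal(s$nUnresolved, 1L)
})

test_that("condition of origin follows the first variant-carrying sample", {
    expect_equal(as.character(conditionOfOrigin(
        c("000001|0000", "000000|0101", "010000|0100", "111111|1111",
          "000000|0000"))),
        c("cold", "hot", "cold", NA, NA))
})

test_that("mutation rate is count over length times generations", {
    expect_equal(estimateMutationRate(0, 1e6, 100), 0)
    expect_equal(estimateMutationRate(100, 1e6, 100), 1e-6)
    expect_equal(estimateMutationRate(1400, 1.4e7, 100), 1e-6)
    expect_error(estimateMutationRate(10, 0, 100), "genomeLength")
    expect_error(estimateMutationRate(10, 1e6, -1), "generations")
    expect_error(estimateMutationRate(-1, 1e6, 100), "non-negative")
})
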