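# Independent reference implementations used to cross-check the package.
# These deliberately use different mechanics from the package code paths
# (regex classification, lchoose-based hypergeometric enumeration, full
# permutation enumeration).

# Trajectory classification by regular expressions on the pattern string.
oraclePatternClass <- function(p) {
    vapply(p, function(s) {
        if (grepl(".", s, fixed = TRUE)) return("Unresolved")
        if (grepl("^1+\\|1+$", s)) return("Background")
        if (grepl("^0+\\|0+$", s)) return("NoVariant")
        if (grepl("^0*1+\\|0+$", s)) return("ColdFixed")
        if (grepl("^0+\\|0*1+$", s)) return("HotFixed")
        "Random"
    }, character(1), USE.NAMES = FALSE)
}

# Fisher p by explicit enumeration of the conditional table distribution
# using binomial coefficients (normalised, never calls dhyper).
fisherEnumOracle <- function(a, b, c, d,
                             alternative = "two.sided") {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    logw <- lchoose(m, support) + lchoose(n, k - support)
    w <- exp(logw - max(logw))
    pr <- w / sum(w)
    obs <- pr[support == a]
    switch(alternative,
        greater = sum(pr[support >= a]),
        less = sum(pr[support <= a]),
        two.sided = min(1, sum(pr[pr <= obs * (1 + 1e-7)])))
}

# All permutations of seq_len(n), as a matrix with one row per permutation.
allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- allPermutations(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    r <- 0L
    for (pos in seq_len(n)) {
        block <- cbind(sub, n)[, append(seq_len(n - 1L), n, pos - 1L),
                               drop = FALSE]
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}

# Jonckheere-Terpstra one-sided p by exhaustive permutation of the pooled
# values over the group layout (feasible up to pooled n = 8).
jtOracle <- function(groups, alternative = "increasing") {
    pool <- unlist(groups)
    sizes <- lengths(groups)
    lab <- rep(seq_along(sizes), sizes)
    labLess <- outer(lab, lab, "<")
    jstat <- function(v) {
        sum(outer(v, v, "<") & labLess) +
            0.5 * sum(outer(v, v, "==") & labLess)
    }
    jobs <- jstat(pool)
    perms <- allPermutations(length(pool))
    jall <- apply(perms, 1L, function(ix) jstat(pool[ix]))
    eps <- 1e-9
    if (alternative == "increasing") mean(jall >= jobs - eps)
    else mean(jall <= jobs + eps)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group
# splits (tie-free inputs only), following the W > / < / = mu convention.
wilcoxOracle <- function(x, y, alternative = "two.sided") {
    pool <- c(x, y)
    nx <- length(x)
    splits <- combn(length(pool), nx)
    wOf <- function(ix) sum(outer(pool[ix], pool[-ix], ">"))
    wobs <- wOf(seq_len(nx))
    wall <- apply(splits, 2L, wOf)
    mu <- nx * length(y) / 2
    switch(alternative,
        greater = mean(wall >= wobs),
        less = mean(wall <= wobs),
        two.sided = {
            if (wobs > mu) min(1, 2 * mean(wall >= wobs))
            else if (wobs < mu) min(1, 2 * mean(wall <= wobs))
            else 1
        })
}
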