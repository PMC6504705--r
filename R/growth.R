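#' Read a plating growth table
#'
#' @param path TSV with columns `condition` (`cold`/`hot`), `day` (time of
#'   harvest, days since the experiment start), `od750` (optical density
#'   of the harvested cell suspension) and `inoculum` (cells streaked at
#'   the start of the interval).
#' @return `data.frame`.
#' @export
readGrowthTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("condition", "day", "od750", "inoculum")
    if (!all(need %in% names(df)))
        stop("growth table needs columns ", paste(need, collapse = ", "))
    df
}

#' Doubling times and growth rates from a plating series
#'
#' Each re-plating event closes one growth interval: a plate inoculated
#' with `inoculum` cells at the end of the previous event (day 0 for the
#' first) and harvested at `day` with optical density `od750`. With
#' `N_end = od750 * cellsPerOd`, the interval doubling time is
#' `Td = dt * ln(2) / ln(N_end / N_start)`. Intervals with no net growth
#' (`N_end <= N_start`) are flagged, excluded from the means and reported
#' with `td = NA`. Because the pairing of a mean doubling time with a
#' single "growth rate per day" is convention-dependent, both conventions
#' are reported: doublings per day (`1/Td`) and the exponential rate
#' (`ln(2)/Td`).
#'
#' @param day strictly increasing harvest days.
#' @param od750 optical densities at harvest (> 0).
#' @param inoculum cells inoculated per interval (scalar or vector).
#' @param cellsPerOd calibration: cells per OD750 unit in the measured
#'   suspension volume (default 1e7).
#' @return List: `intervals` (`data.frame` with `start`, `end`, `dt`,
#'   `nStart`, `nEnd`, `td`, `excluded`), `meanTd`, `meanDoublingsPerDay`,
#'   `meanExpRate`.
#' @examples
#' doublingTime(day = 2, od750 = 4000 / 1e7, inoculum = 1000)$meanTd # 1
#' @export
doublingTime <- function(day, od750, inoculum, cellsPerOd = 1e7) {
    n <- length(day)
    if (n < 1L) stop("need at least one interval")
    if (any(diff(day) <= 0)) stop("days must be strictly increasing")
    if (any(od750 <= 0)) stop("od750 must be positive")
    inoculum <- rep_len(inoculum, n)
    start <- c(0, day[-n])
    dt <- day - start
    if (any(dt <= 0)) stop("non-positive interval duration")
    nEnd <- od750 * cellsPerOd
    ratio <- nEnd / inoculum
    excluded <- ratio <= 1
    if (any(excluded))
        warning(sum(excluded), " interval(s) with no net growth excluded")
    td <- ifelse(excluded, NA_real_, dt * log(2) / log(ratio))
    list(
        intervals = data.frame(start = start, end = day, dt = dt,
                               nStart = inoculum, nEnd = nEnd, td = td,
                               excluded = excluded),
        meanTd = mean(td[!excluded]),
        meanDoublingsPerDay = mean(1 / td[!excluded]),
        meanExpRate = mean(log(2) / td[!excluded]))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample location test: exact enumeration when the combined sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction (and continuity correction), as
#' implemented by `stats::wilcox.test`.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `statistic` (the Mann-Whitney W of `x` vs `y`),
#'   `p.value`, `method` (`"exact"` or `"normal-approx"`).
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p.value # 1/3
#' @export
wilcoxonRankSum <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less")) {
    alternative <- match.arg(alternative)
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- (length(x) + length(y) <= 20L) && !ties
    wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                       exact = exact))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # all observations tied: zero null variance
    list(statistic = unname(wt$statistic), p.value = p,
         method = if (exact) "exact" else "normal-approx")
}

jtStatistic <- function(groups) {
    k <- length(groups)
    J <- 0
    for (i in seq_len(k - 1L))
        for (j in (i + 1L):k) {
            J <- J + sum(outer(groups[[i]], groups[[j]], "<")) +
                0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
        }
    J
}

# all ways to deal the pooled values into groups of the given sizes
jtEnumerate <- function(pool, sizes) {
    out <- numeric(0)
    recurse <- function(idx, sizes) {
        if (length(sizes) == 1L)
            return(list(list(pool[idx])))
        picks <- combn(idx, sizes[1L], simplify = FALSE)
        res <- list()
        for (p in picks) {
            rest <- recurse(setdiff(idx, p), sizes[-1L])
            for (r in rest)
                res[[length(res) + 1L]] <- c(list(pool[p]), r)
        }
        res
    }
    assignments <- recurse(seq_along(pool), sizes)
    vapply(assignments, jtStatistic, numeric(1))
}

#' Jonckheere-Terpstra test for an ordered trend
#'
#' Tests for a monotone location trend across ordered groups. The
#' statistic is `J = sum over group pairs i < j of
#' #\{a < b : a in group i, b in group j\} + ties/2` (for two groups this
#' is the Mann-Whitney U). The p value comes from exhaustive enumeration
#' of all group-label assignments when the pooled size is at most 12
#' (method `"exact"`), from the standard normal approximation with tie
#' correction (`"normal"`), or from Monte-Carlo permutation
#' (`"montecarlo"`, `nperm` draws, seeded by the caller); `"auto"` picks
#' exact for pooled n <= 12 and normal otherwise.
#'
#' @param groups list of non-empty numeric vectors in hypothesised order;
#'   at least 3 groups support a trend claim (2 degrade to Mann-Whitney).
#' @param alternative `"increasing"` (default), `"decreasing"` or
#'   `"two.sided"`.
#' @param method `"auto"`, `"exact"`, `"normal"` or `"montecarlo"`.
#' @param nperm Monte-Carlo permutations (default 10000).
#' @return List: `statistic` (J), `p.value`, `method`, `nPerGroup`,
#'   `alternative`.
#' @examples
#' jonckheereTerpstra(list(1, 2, 3))$p.value # 1/6
#' @export
jonckheereTerpstra <- function(groups,
                               alternative = c("increasing", "decreasing",
                                               "two.sided"),
                               method = c("auto", "exact", "normal",
                                          "montecarlo"),
                               nperm = 10000L) {
    alternative <- match.arg(alternative)
    method <- match.arg(method)
    if (!is.list(groups) || length(groups) < 2L)
        stop("need a list of at least two groups")
    if (any(lengths(groups) == 0L)) stop("empty group")
    groups <- lapply(groups, as.numeric)
    sizes <- lengths(groups)
    N <- sum(sizes)
    if (method == "auto") method <- if (N <= 12L) "exact" else "normal"
    J <- jtStatistic(groups)
    pool <- unlist(groups, use.names = FALSE)
    eps <- sqrt(.Machine$double.eps)
    pInc <- pDec <- NA_real_
    if (method == "exact") {
        Jall <- jtEnumerate(pool, sizes)
        pInc <- mean(Jall >= J - eps)
        pDec <- mean(Jall <= J + eps)
    } else if (method == "montecarlo") {
        Jperm <- vapply(seq_len(nperm), function(i) {
            shuffled <- sample(pool)
            jtStatistic(split(shuffled, rep(seq_along(sizes), sizes)))
        }, numeric(1))
        pInc <- (1 + sum(Jperm >= J - eps)) / (nperm + 1)
        pDec <- (1 + sum(Jperm <= J + eps)) / (nperm + 1)
    } else {
        mu <- (N^2 - sum(sizes^2)) / 4
        tieSizes <- as.numeric(table(pool))
        v <- (N * (N - 1) * (2 * N + 5) -
                  sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
                  sum(tieSizes * (tieSizes - 1) * (2 * tieSizes + 5))) / 72
        if (N > 2)
            v <- v + sum(sizes * (sizes - 1) * (sizes - 2)) *
                sum(tieSizes * (tieSizes - 1) * (tieSizes - 2)) /
                (36 * N * (N - 1) * (N - 2))
        v <- v + sum(sizes * (sizes - 1)) * sum(tieSizes * (tieSizes - 1)) /
            (8 * N * (N - 1))
        if (v <= 0) {
            pInc <- pDec <- 1
        } else {
            z <- (J - mu) / sqrt(v)
            pInc <- pnorm(z, lower.tail = FALSE)
            pDec <- pnorm(z, lower.tail = TRUE)
        }
    }
    p <- switch(alternative,
        increasing = pInc,
        decreasing = pDec,
        two.sided = min(1, 2 * min(pInc, pDec)))
    list(statistic = J, p.value = p, method = method,
         nPerGroup = as.integer(sizes), alternative = alternative)
}

#' Ordinary least-squares trend line
#'
#' @param t times (at least two distinct values).
#' @param y responses.
#' @return List: `slope`, `intercept`.
#' @examples
#' olsTrend(0:2, c(0, 2, 4))$slope # 2
#' @export
olsTrend <- function(t, y) {
    if (length(unique(t)) < 2L) stop("need at least two distinct times")
    fit <- lm(y ~ t)
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}
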