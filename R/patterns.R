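#' @include AllGenerics.R AllClasses.R
NULL

# Parse "110011|0000"-style strings into a calls matrix; "." = missing.
patternStringsToMatrix <- function(x) {
    parts <- strsplit(x, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("patterns must contain exactly one '|' separator")
    nCold <- unique(nchar(vapply(parts, `[`, character(1), 1L)))
    nHot <- unique(nchar(vapply(parts, `[`, character(1), 2L)))
    if (length(nCold) != 1L || length(nHot) != 1L)
        stop("all patterns must share one cold|hot layout")
    chars <- strsplit(gsub("|", "", x, fixed = TRUE), "")
    bad <- !vapply(chars, function(ch) all(ch %in% c("0", "1", ".")),
                   logical(1))
    if (any(bad)) stop("patterns may contain only 0, 1, '.' and '|'")
    m <- matrix(NA_integer_, length(x), nCold + nHot)
    for (i in seq_along(x)) {
        ch <- chars[[i]]
        ch[ch == "."] <- NA_character_
        m[i, ] <- as.integer(ch)
    }
    attr(m, "nCold") <- nCold
    m
}

callsToPatternStrings <- function(m, nCold) {
    ch <- matrix(as.character(m), nrow(m))
    ch[is.na(ch)] <- "."
    cold <- apply(ch[, seq_len(nCold), drop = FALSE], 1L, paste,
                  collapse = "")
    hot <- apply(ch[, -seq_len(nCold), drop = FALSE], 1L, paste,
                 collapse = "")
    paste(cold, hot, sep = "|")
}

# Vectorised trajectory classification of a 0/1/NA calls matrix.
classifyCallsMatrix <- function(m, nCold, nHot) {
    stopifnot(ncol(m) == nCold + nHot, nCold >= 1L, nHot >= 1L)
    cold <- m[, seq_len(nCold), drop = FALSE]
    hot <- m[, nCold + seq_len(nHot), drop = FALSE]
    hasNA <- rowSums(is.na(m)) > 0L
    ones <- rowSums(m == 1L)
    coldOnes <- rowSums(cold == 1L)
    hotOnes <- rowSums(hot == 1L)
    # TRUE when the block is 0^a 1^b (non-decreasing along time)
    stepUp <- function(b) {
        if (ncol(b) == 1L) return(rep(TRUE, nrow(b)))
        rowSums(b[, -1L, drop = FALSE] < b[, -ncol(b), drop = FALSE]) == 0L
    }
    coldFixed <- !hasNA & coldOnes > 0L & hotOnes == 0L & stepUp(cold)
    hotFixed <- !hasNA & hotOnes > 0L & coldOnes == 0L & stepUp(hot)
    coldFixed[is.na(coldFixed)] <- FALSE
    hotFixed[is.na(hotFixed)] <- FALSE
    label <- rep("Random", nrow(m))
    label[coldFixed] <- "ColdFixed"
    label[hotFixed] <- "HotFixed"
    label[!hasNA & ones == ncol(m)] <- "Background"
    label[!hasNA & ones == 0L] <- "NoVariant"
    label[hasNA] <- "Unresolved"
    # all-ones condition block: the gain predates the first sampling point,
    # so the condition of gain cannot be determined
    ambiguous <- (coldFixed & coldOnes == nCold) |
        (hotFixed & hotOnes == nHot)
    gain <- rep(NA_integer_, nrow(m))
    gain[coldFixed] <- nCold - coldOnes[coldFixed] + 1L
    gain[hotFixed] <- nHot - hotOnes[hotFixed] + 1L
    data.frame(
        patternClass = factor(label, levels = patternClassLevels()),
        gainAmbiguous = ambiguous,
        gainIndex = gain)
}

#' Trajectory class labels
#'
#' @return Character vector of the six pattern classes in canonical order:
#'   `Background` (all samples disagree with the reference assembly, i.e. a
#'   reference error), `ColdFixed` / `HotFixed` (gained once and kept in
#'   every subsequent sample of that condition, the other condition all
#'   reference), `Random` (any other gain/loss pattern), `NoVariant` (all
#'   reference) and `Unresolved` (at least one missing call).
#' @export
patternClassLevels <- function() {
    c("Background", "ColdFixed", "HotFixed", "Random", "NoVariant",
      "Unresolved")
}

#' @describeIn classifyPatterns classify `"cccccc|hhhh"` pattern strings
#'   (digits 0/1, `.` for missing). Returns a `data.frame` with columns
#'   `pattern`, `patternClass`, `gainAmbiguous` and `gainIndex` (the
#'   time index within the fixed condition at which the variant first
#'   appears; 1 with `gainAmbiguous = TRUE` when the gain predates the
#'   first sample).
#' @examples
#' classifyPatterns(c("111111|1111", "111111|0000", "000000|0111",
#'                    "110011|0000", "000000|0000"))
#' @export
setMethod("classifyPatterns", "character", function(x, ...) {
    m <- patternStringsToMatrix(x)
    nCold <- attr(m, "nCold")
    out <- classifyCallsMatrix(m, nCold, ncol(m) - nCold)
    cbind(pattern = x, out, stringsAsFactors = FALSE)
})

#' @describeIn classifyPatterns classify a 0/1/NA calls matrix whose first
#'   `nCold` columns are the cold block.
#' @param nCold,nHot numbers of cold / hot samples (matrix method).
#' @export
setMethod("classifyPatterns", "matrix", function(x, nCold, nHot, ...) {
    out <- classifyCallsMatrix(x, nCold, nHot)
    cbind(pattern = callsToPatternStrings(x, nCold), out,
          stringsAsFactors = FALSE)
})

#' @describeIn classifyPatterns classify every record of a
#'   [VariantCallSet-class]; returns the set with row annotations
#'   `pattern`, `patternClass`, `gainAmbiguous` and `gainIndex` added.
#' @export
setMethod("classifyPatterns", "VariantCallSet", function(x, ...) {
    lay <- seriesLayout(sampleSeries(x))
    out <- classifyCallsMatrix(calls(x), lay[["cold"]], lay[["hot"]])
    rowData(x)$pattern <- callsToPatternStrings(calls(x), lay[["cold"]])
    rowData(x)$patternClass <- out$patternClass
    rowData(x)$gainAmbiguous <- out$gainAmbiguous
    rowData(x)$gainIndex <- out$gainIndex
    x
})

#' @describeIn encodePatterns encode a calls matrix (first `nCold` columns
#'   = cold block) as pattern strings.
#' @param nCold number of cold samples (matrix method).
#' @export
setMethod("encodePatterns", "matrix", function(x, nCold, ...) {
    callsToPatternStrings(x, nCold)
})

#' @describeIn encodePatterns encode every record of a
#'   [VariantCallSet-class].
#' @export
setMethod("encodePatterns", "VariantCallSet", function(x, ...) {
    lay <- seriesLayout(sampleSeries(x))
    callsToPatternStrings(calls(x), lay[["cold"]])
})

#' Enumerate all binary patterns of a layout
#'
#' @param nCold,nHot block sizes.
#' @return Character vector of all `2^(nCold+nHot)` pattern strings.
#' @examples
#' length(enumeratePatterns(2, 2))
#' @export
enumeratePatterns <- function(nCold, nHot) {
    n <- nCold + nHot
    stopifnot(n <= 24)
    m <- matrix(0L, 2L^n, n)
    for (j in seq_len(n))
        m[, j] <- rep(rep(0:1, each = 2L^(n - j)), length.out = 2L^n)
    callsToPatternStrings(m, nCold)
}

#' Condition of origin of a variant trajectory
#'
#' The condition owning the first sample (in series order, cold block
#' before hot block) that carries the variant. Background and all-zero
#' patterns get `NA`.
#'
#' @param m calls matrix, or a `data.frame` from [classifyPatterns()] with
#'   a `pattern` column, or pattern strings.
#' @param nCold number of cold samples (matrix input).
#' @return Factor with levels `cold`, `hot`.
#' @export
conditionOfOrigin <- function(m, nCold = NULL) {
    if (is.character(m)) m <- patternStringsToMatrix(m)
    if (is.data.frame(m)) m <- patternStringsToMatrix(m$pattern)
    if (is.null(nCold)) nCold <- attr(m, "nCold")
    stopifnot(!is.null(nCold))
    ones <- rowSums(m == 1L, na.rm = TRUE)
    coldOnes <- rowSums(m[, seq_len(nCold), drop = FALSE] == 1L,
                        na.rm = TRUE)
    origin <- rep(NA_character_, nrow(m))
    isBg <- ones == ncol(m)
    origin[!isBg & coldOnes > 0L] <- "cold"
    origin[!isBg & coldOnes == 0L & ones > 0L] <- "hot"
    factor(origin, levels = c("cold", "hot"))
}

#' Summarise trajectory classes
#'
#' Counts and percentages per class, with the denominators made explicit:
#' the `Background` percentage is reported over all classified records
#' (reference errors among everything that passed filtering), while the
#' `ColdFixed`, `HotFixed`, `Random` and `NoVariant` percentages are
#' reported over the non-background records (the set in which trajectories
#' are interpretable). `Unresolved` records (missing calls) are excluded
#' from both denominators. Percentages over an empty denominator are `NA`,
#' not 0.
#'
#' @param class factor/character of pattern classes, or a
#'   [VariantCallSet-class] processed by [classifyPatterns()].
#' @param variantType optional per-record type (`SNP`/`InDel`) for the
#'   by-type breakdown (taken from the object for a `VariantCallSet`).
#' @param region optional per-record region (`genic`/`intergenic`).
#' @return A `PatternSummary` list: `counts`, `nClassified`,
#'   `nNonBackground`, `nUnresolved`, `backgroundPct`, `classPct`,
#'   `byType`, `byRegion`.
#' @examples
#' summarizePatterns(rep(c("Background", "ColdFixed", "HotFixed", "Random"),
#'                       c(10, 3, 2, 5)))
#' @export
summarizePatterns <- function(class, variantType = NULL, region = NULL) {
    if (is(class, "VariantCallSet")) {
        vcs <- class
        if (is.null(rowData(vcs)$patternClass))
            vcs <- classifyPatterns(vcs)
        variantType <- variantType(vcs)
        region <- regionType(vcs)
        class <- rowData(vcs)$patternClass
    }
    class <- factor(as.character(class), levels = patternClassLevels())
    if (anyNA(class)) stop("unknown pattern class label(s)")
    counts <- table(class)
    nUnresolved <- counts[["Unresolved"]]
    nClassified <- sum(counts) - nUnresolved
    nBackground <- counts[["Background"]]
    nNonBackground <- nClassified - nBackground
    backgroundPct <- if (nClassified > 0) 100 * nBackground / nClassified
                     else NA_real_
    nonBgLevels <- c("ColdFixed", "HotFixed", "Random", "NoVariant")
    classPct <- if (nNonBackground > 0)
        100 * counts[nonBgLevels] / nNonBackground
    else setNames(rep(NA_real_, 4L), nonBgLevels)
    byType <- if (!is.null(variantType)) table(class, type = variantType)
    byRegion <- if (!is.null(region)) table(class, region = region)
    structure(
        list(counts = counts, nClassified = nClassified,
             nNonBackground = nNonBackground, nUnresolved = nUnresolved,
             backgroundPct = backgroundPct,
             classPct = as.numeric(classPct) |> setNames(nonBgLevels),
             byType = byType, byRegion = byRegion),
        class = "PatternSummary")
}

#' @export
print.PatternSummary <- function(x, ...) {
    cat("Pattern summary:", x$nClassified, "classified records (",
        x$nUnresolved, "unresolved )\n")
    print(x$counts)
    cat(sprintf("Background: %.2f%% of %d classified\n",
                x$backgroundPct, x$nClassified))
    for (lab in names(x$classPct))
        cat(sprintf("  %-9s %.2f%% of %d non-background\n", lab,
                    x$classPct[[lab]], x$nNonBackground))
    invisible(x)
}

#' Per-base per-generation mutation rate
#'
#' `rate = variantCount / (genomeLength * generations)`. The attribution of
#' variants to a condition (e.g. by [conditionOfOrigin()]) and the choice
#' of generation count are the caller's, made explicit because different
#' conventions are in use.
#'
#' @param variantCount non-negative number of condition-attributed
#'   variants.
#' @param genomeLength genome length in bp (> 0).
#' @param generations generations elapsed (> 0).
#' @return Rate per base per generation.
#' @examples
#' estimateMutationRate(100, 1e6, 100) # 1e-6
#' @export
estimateMutationRate <- function(variantCount, genomeLength, generations) {
    if (genomeLength <= 0) stop("genomeLength must be positive")
    if (generations <= 0) stop("generations must be positive")
    if (variantCount < 0) stop("variantCount must be non-negative")
    variantCount / (genomeLength * generations)
}
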