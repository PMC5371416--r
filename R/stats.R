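#' @include AttCSite-class.R
NULL

#' Nucleotide skews of a strand
#'
#' GC skew = (G - C)/(G + C) and AT skew = (A - T)/(A + T), computed on the
#' sequence exactly as written (the convention is to pass the top strand).
#' Negative skews correspond to purine enrichment on the bottom strand.
#'
#' @param seq character(1) or \code{DNAString}.
#' @param strandLabel \code{"top"} or \code{"bottom"}, recorded in the
#'   result.
#' @return list with \code{gc_skew}, \code{at_skew} (NA when the
#'   denominator is 0, flagged via \code{gc_defined}/\code{at_defined})
#'   and \code{strand}.
#' @examples
#' skews("GACT")
#' @export
skews <- function(seq, strandLabel = "top") {
    chars <- .checkAlphabet(toupper(as.character(seq)))
    nG <- sum(chars == "G"); nC <- sum(chars == "C")
    nA <- sum(chars == "A"); nT <- sum(chars == "T")
    gc <- if (nG + nC > 0L) (nG - nC) / (nG + nC) else NA_real_
    at <- if (nA + nT > 0L) (nA - nT) / (nA + nT) else NA_real_
    list(gc_skew = gc, at_skew = at,
         gc_defined = nG + nC > 0L, at_defined = nA + nT > 0L,
         strand = strandLabel)
}

#' Percent identity from a global end-to-end alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch; default scoring
#' match +1, mismatch -1, gap opening -2, gap extension -1) and reports
#' 100 x matches / alignment columns (gap columns included in the
#' denominator).  Rounding to the nearest integer happens only at report
#' time via \code{round}.
#'
#' @param a,b character(1) or \code{DNAString}, non-empty.
#' @param match,mismatch,gapOpening,gapExtension scoring parameters.
#' @return numeric(1) percent identity (unrounded).
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGA")
#' @export
pairwiseIdentity <- function(a, b, match = 1, mismatch = -1,
                             gapOpening = 2, gapExtension = 1) {
    a <- Biostrings::DNAString(toupper(as.character(a)))
    b <- Biostrings::DNAString(toupper(as.character(b)))
    if (length(a) == 0L || length(b) == 0L)
        stop("sequences must be non-empty", call. = FALSE)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = gapOpening,
                                         gapExtension = gapExtension)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Maximal exact direct repeats shared by two sequences
#'
#' All maximal exact common substrings of length >= \code{minLen}, with
#' 1-based coordinates in both inputs, sorted by decreasing length.  Used
#' to examine replication-slippage substrates between neighbouring attC
#' sites.
#'
#' @param a,b character(1) or \code{DNAString}.
#' @param minLen minimal repeat length (>= 4).
#' @return data.frame with columns \code{seq}, \code{start_a},
#'   \code{start_b}, \code{length}.
#' @examples
#' directRepeats("AAGTTAGGCAA", "CCGTTAGGCTT", minLen = 4)
#' @export
directRepeats <- function(a, b, minLen = 8L) {
    if (minLen < 4L) stop("minLen must be >= 4", call. = FALSE)
    x <- strsplit(toupper(as.character(a)), "")[[1L]]
    y <- strsplit(toupper(as.character(b)), "")[[1L]]
    n <- length(x); m <- length(y)
    # suffix-extension DP: d[i, j] = length of common substring ending at
    # (i, j); maximal hits are those not extendable to the right
    prev <- integer(m)
    hits <- list()
    for (i in seq_len(n)) {
        cur <- integer(m)
        for (j in seq_len(m)) {
            if (x[i] == y[j]) {
                cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
                ext <- i < n && j < m && x[i + 1L] == y[j + 1L]
                if (cur[j] >= minLen && !ext) {
                    hits[[length(hits) + 1L]] <-
                        c(i - cur[j] + 1L, j - cur[j] + 1L, cur[j])
                }
            }
        }
        prev <- cur
    }
    if (!length(hits))
        return(data.frame(seq = character(), start_a = integer(),
                          start_b = integer(), length = integer()))
    tab <- do.call(rbind, hits)
    out <- data.frame(
        seq = vapply(seq_len(nrow(tab)), function(r)
            paste(x[tab[r, 1L] + seq_len(tab[r, 3L]) - 1L], collapse = ""),
            ""),
        start_a = tab[, 1L], start_b = tab[, 2L], length = tab[, 3L])
    out[order(-out$length, out$start_a, out$start_b), , drop = FALSE]
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 12 and
#' the data are tie-free; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with \code{statistic} (Mann-Whitney W for \code{x}),
#'   \code{p_two_sided}, \code{n_x}, \code{n_y} and \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(10, 11, 12))
#' @export
rankSumTest <- function(x, y) {
    stopifnot(length(x) >= 1L, length(y) >= 1L)
    if (length(unique(c(x, y))) == 1L) {
        return(list(statistic = length(x) * length(y) / 2, p_two_sided = 1,
                    n_x = length(x), n_y = length(y),
                    method = "degenerate"))
    }
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- (length(x) + length(y)) <= 12L && !ties
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                       alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_two_sided = wt$p.value,
         n_x = length(x), n_y = length(y),
         method = if (exact) "exact" else "normal_approximation")
}

#' Ordinary least-squares fit with slope test
#'
#' Simple linear regression with the slope's two-sided p-value from the t
#' distribution on n - 2 degrees of freedom, as reported alongside the
#' coefficient of determination for trend analyses of site properties.
#'
#' @param x,y numeric vectors (n >= 3, \code{var(x) > 0}).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_slope}, \code{n}.
#' @examples
#' linearFit(1:5, 2 * (1:5) + 1)
#' @export
linearFit <- function(x, y) {
    if (length(x) < 3L || length(x) != length(y))
        stop("need n >= 3 paired observations", call. = FALSE)
    if (stats::var(x) == 0)
        stop("zero variance in x", call. = FALSE)
    if (stats::var(y) == 0) {
        # flat response: slope 0 and no variance explained
        return(list(slope = 0, intercept = y[1L], r_squared = 0,
                    p_slope = 1, n = length(x)))
    }
    fit <- lm(y ~ x)
    sm <- suppressWarnings(summary(fit))   # quiet on numerically perfect fits
    co <- coef(sm)
    p <- if (nrow(co) < 2L || sm$sigma == 0) {
        # perfect fit: slope exactly determined
        if (abs(coef(fit)[2L]) > 0) 0 else 1
    } else co["x", "Pr(>|t|)"]
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = sm$r.squared, p_slope = unname(p), n = length(x))
}

#' Per-group summaries of attC site properties
#'
#' Summarises a per-site metrics table (as produced by
#' \code{\link{runSiteMetrics}}) by group: median site length, proportion
#' of sites with pfold above a threshold (strict inequality; default 0.1),
#' proportion with pfold in a low band (closed interval, default
#' [1e-7, 1e-5]), mean bottom-minus-top stability gap and median skews.
#'
#' @param siteTable data.frame with columns \code{pfold}, \code{length},
#'   and optionally \code{gap}, \code{gc_skew}, \code{at_skew}.
#' @param grouping factor/character vector (one value per row).
#' @param pfoldThreshold numeric(1), default 0.1.
#' @param lowBand numeric(2) closed interval, default \code{c(1e-7, 1e-5)}.
#' @return data.frame, one row per non-empty group; empty groups are
#'   dropped with a warning.
#' @examples
#' tab <- data.frame(pfold = c(.2, .5, .05, .01), length = c(60, 70, 80, 90))
#' cohortSummary(tab, rep("MI", 4))
#' @export
cohortSummary <- function(siteTable, grouping, pfoldThreshold = 0.1,
                          lowBand = c(1e-7, 1e-5)) {
    grouping <- as.character(grouping)
    stopifnot(length(grouping) == nrow(siteTable))
    empty <- setdiff(unique(grouping), grouping[seq_len(nrow(siteTable))])
    groups <- unique(grouping)
    rows <- lapply(groups, function(g) {
        d <- siteTable[grouping == g, , drop = FALSE]
        if (!nrow(d)) return(NULL)
        getcol <- function(nm) if (nm %in% names(d)) d[[nm]] else NA_real_
        data.frame(
            group = g, n = nrow(d),
            median_length = median(d$length, na.rm = TRUE),
            prop_pfold_above = mean(d$pfold > pfoldThreshold, na.rm = TRUE),
            prop_pfold_low_band = mean(d$pfold >= lowBand[1L] &
                                           d$pfold <= lowBand[2L],
                                       na.rm = TRUE),
            mean_gap = mean(getcol("gap"), na.rm = TRUE),
            median_gc_skew = median(getcol("gc_skew"), na.rm = TRUE),
            median_at_skew = median(getcol("at_skew"), na.rm = TRUE))
    })
    keep <- !vapply(rows, is.null, TRUE)
    if (any(!keep)) warning("empty group(s) omitted", call. = FALSE)
    do.call(rbind, rows[keep])
}
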