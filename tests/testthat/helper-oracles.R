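# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# naive reverse complement: complement base-by-base, then reverse
naiveRevComp <- function(seq) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
              H = "D", V = "B", N = "N")
    chars <- strsplit(toupper(seq), "")[[1]]
    paste(rev(unname(comp[chars])), collapse = "")
}

# independent structure counter: leftmost-base decomposition (the package
# enumerator splits on the rightmost base), memoized
countStructuresOracle <- function(seq, minloop = 3L) {
    chars <- strsplit(toupper(seq), "")[[1]]
    wc <- function(a, b) (a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "C" && b == "G") || (a == "G" && b == "C") ||
        (a == "G" && b == "T") || (a == "T" && b == "G")
    memo <- new.env()
    cnt <- function(i, j) {
        if (i >= j) return(1)
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        total <- cnt(i + 1L, j)         # i unpaired
        for (k in (i + 1L):j) {
            if (k - i - 1L >= minloop && wc(chars[i], chars[k]))
                total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
        }
        memo[[key]] <- total
        total
    }
    cnt(1L, length(chars))
}

# partition function / MFE from the package's exhaustive enumerator (the
# designated brute-force reference for the DP)
enumThermo <- function(seq, model = referenceEnergyModel(),
                       constraints = NULL) {
    en <- enumerateStructures(seq, model, constraints)
    rt <- 1.98717e-3 * model@temperature
    if (!nrow(en)) return(list(Z = 0, mfe = NA_real_, Eens = NA_real_))
    Z <- sum(exp(-en$energy / rt))
    list(Z = Z, mfe = min(en$energy), Eens = -rt * log(Z), n = nrow(en))
}

# exact two-sided rank-sum p by enumeration of all group assignments
exactRankSumP <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combos <- utils::combn(nx + ny, nx)
    ws <- apply(combos, 2, function(id) sum(r[id]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# a fixed MI-like site used by several tests
toySite <- function(seed = 1, ...) generateAttc(attcParams(...), seed = seed)
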