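#' @include constraints.R
NULL

# All start positions (1-based) where the IUPAC motif matches the sequence
# characters exactly (degenerate codes on either side).
.motifHits <- function(chars, motif) {
    m <- strsplit(motif, "")[[1L]]
    n <- length(chars) - length(m) + 1L
    if (n < 1L) return(integer())
    hits <- integer()
    for (p in seq_len(n)) {
        if (all(.iupacMatches(chars[p + seq_along(m) - 1L], m)))
            hits <- c(hits, p)
    }
    hits
}

#' Heuristic location of attC boxes
#'
#' Best-effort annotation of the R''/L''/L'/R' boxes of an attC site from
#' its top-strand sequence alone.  The search runs on the bottom strand: it
#' anchors candidate 7-bp R boxes on the conserved motifs (5'-GTTR-3'
#' opening R'' and 5'-YAAC-3' closing R'), then scans stem placements where
#' L' reverse-complements L'' with at most \code{maxMismatch} mismatches,
#' and returns the highest-scoring assignment.  Explicit user-supplied
#' annotation (e.g. from \code{\link{readBoxAnnotations}}) always overrides
#' this heuristic.
#'
#' @param topStrand character(1) or \code{DNAString}: site top strand,
#'   length >= 40.
#' @param maxMismatch maximum number of non-complementary positions
#'   tolerated between L' and L'' (default 2).
#' @param minStem,maxStem bounds on the L-box width scanned (default 4-24).
#' @param maxSpacer1,maxSpacer2 maximal unpaired spacer scanned between R''
#'   and L'' (the UCS side) and between L' and R' (defaults 12 and 8).
#' @param minVTS minimal number of unpaired bases between L'' and L'
#'   (default 3, the smallest natural variable terminal structure).
#'
#' @return A \linkS4class{BoxAnnotation} in top-strand coordinates.
#'
#' @details Candidates are scored by (matches - mismatches) of the L'/L''
#' pairing; ties prefer longer stems, then shorter spacers.  When no
#' GTTR/YAAC anchor pair leaves room for a stem the site is reported as
#' unannotatable and the caller is instructed to supply explicit boxes.
#'
#' @examples
#' site <- generateAttc(attcParams(), seed = 7)$site
#' locateBoxes(topStrand(site))
#' @export
locateBoxes <- function(topStrand, maxMismatch = 2L, minStem = 4L,
                        maxStem = 24L, maxSpacer1 = 12L, maxSpacer2 = 8L,
                        minVTS = 3L) {
    seq <- toupper(as.character(topStrand))
    chars <- .checkAlphabet(seq)
    L <- length(chars)
    if (L < 40L)
        stop("sequence too short to annotate (< 40 nt)", call. = FALSE)
    bs <- strsplit(bottomStrand(seq), "")[[1L]]

    # bottom strand layout: R''(GTTR...)  ...L''...VTS...L'...  (...YAAC)R'
    gttr <- .motifHits(bs, "GTTR")
    yaac <- .motifHits(bs, "YAAC")
    gttr <- gttr[gttr + 6L <= L]          # R'' = [p, p+6]
    yaac <- yaac[yaac - 3L >= 1L]         # R' = [q-3, q+3]
    if (!length(gttr) || !length(yaac))
        stop("unannotatable: no GTTR/YAAC anchor pair found; ",
             "supply explicit box annotation", call. = FALSE)

    comp <- unname(.IUPAC_COMP[bs])
    best <- NULL
    for (p in gttr) {
        for (q in yaac) {
            rpS <- q - 3L
            if (rpS - p - 7L < 2L * minStem + minVTS) next
            for (u in 0:maxSpacer1) {
                ldsS <- p + 7L + u
                for (s2 in 0:maxSpacer2) {
                    lpE <- rpS - 1L - s2
                    lmax <- min(maxStem, (lpE - ldsS + 1L - minVTS) %/% 2L)
                    if (lmax < minStem) next
                    for (l in minStem:lmax) {
                        i <- ldsS + seq_len(l) - 1L
                        j <- lpE - seq_len(l) + 1L
                        matches <- sum(.iupacMatchesFast(comp[i], bs[j]))
                        mis <- l - matches
                        if (mis > maxMismatch) next
                        score <- matches - 2L * mis
                        cand <- list(score = score, l = l, u = u, s2 = s2,
                                     p = p, q = q)
                        # ties prefer outermost R boxes, then longer stems,
                        # then tighter spacers
                        better <- is.null(best) || score > best$score ||
                            (score == best$score &&
                             (p < best$p || (p == best$p &&
                              (q > best$q || (q == best$q &&
                               (l > best$l || (l == best$l &&
                                (u + s2) < (best$u + best$s2))))))))
                        if (better) best <- cand
                    }
                }
            }
        }
    }
    if (is.null(best))
        stop("unannotatable: no L'/L'' stem consistent with the R-box ",
             "anchors (<= ", maxMismatch, " mismatches); supply explicit ",
             "box annotation", call. = FALSE)

    # bottom-strand intervals
    rdp <- IRanges::IRanges(best$p, best$p + 6L)
    ldp <- IRanges::IRanges(best$p + 7L + best$u,
                            best$p + 7L + best$u + best$l - 1L)
    rp <- IRanges::IRanges(best$q - 3L, best$q + 3L)
    lp <- IRanges::IRanges(best$q - 4L - best$s2 - best$l + 1L,
                           best$q - 4L - best$s2)
    boxAnnotation(rDPrime = .flipRange(rdp, L), lDPrime = .flipRange(ldp, L),
                  lPrime = .flipRange(lp, L), rPrime = .flipRange(rp, L))
}

#' Read explicit box annotations from a TSV file
#'
#' Reads a tab-separated table with columns \code{site_id}, \code{box},
#' \code{start}, \code{end} (1-based inclusive, top-strand coordinates;
#' box names \code{r_dprime}, \code{l_dprime}, \code{l_prime},
#' \code{r_prime}) and returns one \linkS4class{BoxAnnotation} per site.
#'
#' @param path file path; lines starting with \code{#} are comments.
#' @return Named list of \code{BoxAnnotation} objects.
#' @export
readBoxAnnotations <- function(path) {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("site_id", "box", "start", "end")
    if (!all(need %in% names(tab)))
        stop("box annotation table must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    out <- lapply(split(tab, tab$site_id), function(d) {
        get <- function(nm) {
            row <- d[d$box == nm, , drop = FALSE]
            if (nrow(row) != 1L)
                stop("site '", d$site_id[1L], "': need exactly one '", nm,
                     "' box", call. = FALSE)
            IRanges::IRanges(row$start, row$end)
        }
        boxAnnotation(rDPrime = get("r_dprime"), lDPrime = get("l_dprime"),
                      lPrime = get("l_prime"), rPrime = get("r_prime"))
    })
    out
}
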