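#' @include AttCSite-class.R
NULL

#' Hard folding constraints: the recombinogenic pair set
#'
#' A \code{ConstraintSet} is a set of base pairs that a secondary structure
#' is required to contain, expressed as 1-based indices on one designated
#' strand of an attC site.  Constrained folding (\code{\link{foldSequence}},
#' \code{\link{pfold}}) restricts the ensemble to structures containing
#' every forced pair.
#'
#' @param pairs integer matrix with two columns (i, j), i < j; may have
#'   zero rows (empty constraint set).
#' @param strandLabel \code{"bottom"} or \code{"top"}: the strand on which
#'   the indices live.
#' @param x a \code{ConstraintSet}.
#'
#' @return \code{constraintSet} returns a \code{ConstraintSet};
#'   \code{forcedPairs} returns the pair matrix, \code{strandLabel} the
#'   strand designation.
#'
#' @details Validity requires pairs to be non-crossing (nested or
#' side-by-side) and each index to appear at most once.
#'
#' @examples
#' cs <- constraintSet(cbind(c(1L, 2L), c(10L, 9L)), "bottom")
#' forcedPairs(cs)
#' @name constraintSet
#' @aliases ConstraintSet-class forcedPairs strandLabel
#' @export constraintSet
#' @exportClass ConstraintSet
setClass("ConstraintSet",
    representation(pairs = "matrix", strandLabel = "character"))

setValidity("ConstraintSet", function(object) {
    p <- object@pairs
    if (!is.numeric(p) || ncol(p) != 2L)
        return("pairs must be a two-column integer matrix")
    if (!object@strandLabel %in% c("bottom", "top"))
        return("strandLabel must be 'bottom' or 'top'")
    if (nrow(p) == 0L)
        return(TRUE)
    if (any(p < 1L) || any(p[, 1L] >= p[, 2L]))
        return("pairs must satisfy 1 <= i < j")
    idx <- c(p[, 1L], p[, 2L])
    if (anyDuplicated(idx))
        return("each index may be used in at most one forced pair")
    o <- order(p[, 1L])
    p <- p[o, , drop = FALSE]
    if (nrow(p) > 1L) {
        for (a in seq_len(nrow(p) - 1L)) {
            for (b in seq((a + 1L), nrow(p))) {
                # crossing: i_a < i_b < j_a < j_b
                if (p[b, 1L] < p[a, 2L] && p[b, 2L] > p[a, 2L])
                    return("forced pairs must be non-crossing")
            }
        }
    }
    TRUE
})

constraintSet <- function(pairs = matrix(integer(), ncol = 2L),
                          strandLabel = "bottom") {
    storage.mode(pairs) <- "integer"
    if (is.null(dim(pairs)))
        pairs <- matrix(pairs, ncol = 2L)
    new("ConstraintSet", pairs = pairs, strandLabel = strandLabel)
}

setMethod("forcedPairs", "ConstraintSet", function(x) x@pairs)
setMethod("strandLabel", "ConstraintSet", function(x) x@strandLabel)

setMethod("show", "ConstraintSet", function(object) {
    cat("ConstraintSet on ", object@strandLabel, " strand: ",
        nrow(object@pairs), " forced pair(s)\n", sep = "")
})

#' @describeIn constraintSet Number of forced pairs.
#' @export
setMethod("length", "ConstraintSet", function(x) nrow(x@pairs))

#' Map a constraint set to the opposite strand
#'
#' A pair (i, j) on one strand corresponds to (L+1-j, L+1-i) on the
#' complementary strand of a sequence of length L; applying the transform
#' twice returns the original indices.
#'
#' @param x a \linkS4class{ConstraintSet}.
#' @param seqLength integer(1) sequence length.
#' @return A \code{ConstraintSet} on the opposite strand.
#' @examples
#' cs <- constraintSet(cbind(1L, 10L), "bottom")
#' forcedPairs(flipConstraintStrand(cs, 20L))
#' @export
flipConstraintStrand <- function(x, seqLength) {
    p <- x@pairs
    if (nrow(p)) {
        flipped <- cbind(seqLength + 1L - p[, 2L], seqLength + 1L - p[, 1L])
        p <- flipped[order(flipped[, 1L]), , drop = FALSE]
    }
    constraintSet(p, if (x@strandLabel == "bottom") "top" else "bottom")
}

#' Constraints of the recombinogenic attC structure
#'
#' Builds the hard constraint set that defines the recombinogenic fold of an
#' attC strand: every base of L' paired with its counterpart in L''
#' (base-by-base, hairpin geometry), plus the four conserved pairs matching
#' 5'-YAAC-3' in R' against 5'-GTTR-3' in R''.  The constraint set
#' therefore contains \code{|L'| + 4} pairs.
#'
#' @param site an \linkS4class{AttCSite} with boxes present (or locatable
#'   via \code{\link{locateBoxes}}).
#' @param strand \code{"bottom"} (default; the strand the integrase
#'   recombines) or \code{"top"}.
#'
#' @return A \linkS4class{ConstraintSet} with indices on the requested
#'   strand.
#'
#' @details Each forced pair is checked for pairability under the site
#' sequence: Watson-Crick complementary (IUPAC degenerate codes match when
#' some concretization pairs) or a G:T wobble.  A forced pair between
#' non-pairable bases is rejected with an error, since the downstream
#' energy models only score valid pairs.
#'
#' @examples
#' site <- generateAttc(attcParams(vts_len = 8), seed = 1)$site
#' recombinogenicConstraints(site)
#' @export
recombinogenicConstraints <- function(site, strand = c("bottom", "top")) {
    strand <- match.arg(strand)
    b <- boxes(site)
    if (is.null(b))
        b <- tryCatch(locateBoxes(as.character(topStrand(site))),
                      error = function(e) stop(conditionMessage(e),
                                               call. = FALSE))
    L <- length(topStrand(site))
    bb <- .boxesOnBottom(b, L)
    lw <- IRanges::width(bb$lPrime)

    # bottom-strand coordinates: R'' < L'' < L' < R'
    lds <- IRanges::start(bb$lDPrime)
    lpe <- IRanges::end(bb$lPrime)
    pairs <- if (lw > 0L) {
        cbind(lds + seq_len(lw) - 1L, lpe - seq_len(lw) + 1L)
    } else {
        matrix(integer(), ncol = 2L)
    }
    # R-box anchor: GTTR = R'' positions 1..4, YAAC = R' positions 4..7;
    # k-th base of GTTR pairs (5-k)-th base of YAAC counted from R' end
    rds <- IRanges::start(bb$rDPrime)
    rpe <- IRanges::end(bb$rPrime)
    anchor <- cbind(rds + 0:3, rpe - 0:3)
    pairs <- rbind(anchor, pairs)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]

    bs <- strsplit(as.character(bottomStrand(site)), "")[[1L]]
    b1 <- bs[pairs[, 1L]]; b2 <- bs[pairs[, 2L]]
    # pairable = Watson-Crick complementary, or a G:T wobble (scored by the
    # energy models; R:Y anchor positions may realize either)
    ok <- .iupacComplementary(b1, b2) |
        (b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G")
    if (!all(ok)) {
        bad <- which(!ok)[1L]
        stop("forced pair (", pairs[bad, 1L], ", ", pairs[bad, 2L],
             ") on the bottom strand joins non-complementary bases ",
             bs[pairs[bad, 1L]], "/", bs[pairs[bad, 2L]],
             "; recombinogenic constraints require Watson-Crick pairs",
             call. = FALSE)
    }
    cs <- constraintSet(pairs, "bottom")
    if (strand == "top") cs <- flipConstraintStrand(cs, L)
    cs
}
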