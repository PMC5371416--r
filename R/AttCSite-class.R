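#' @include AllGenerics.R
NULL

#' Box architecture of an attC site
#'
#' An attC site carries four integrase-binding boxes.  Along the folded
#' bottom strand (5' to 3') they read R'' (GTTR-anchored, 7 bp), L'', L'
#' and R' (YAAC-anchored, 7 bp), with the variable terminal structure (VTS)
#' between L'' and L'.  \code{BoxAnnotation} stores the four intervals in
#' \emph{top-strand} 1-based coordinates; because the bottom strand is the
#' reverse complement of the top strand, the top-strand order of the
#' intervals is R' < L' < L'' < R''.
#'
#' @param rDPrime,lDPrime,lPrime,rPrime \linkS4class{IRanges} of length 1:
#'   box intervals in top-strand coordinates (1-based, closed).
#'
#' @return \code{boxAnnotation} returns a \code{BoxAnnotation} object.
#'
#' @details Invariants checked by the validity method: both R boxes are
#' exactly 7 bp (the full R box), L' and L'' have equal width, and the four
#' intervals are disjoint and ordered R' < L' < L'' < R'' along the top
#' strand.
#'
#' @examples
#' library(IRanges)
#' boxAnnotation(rDPrime = IRanges(54, 60), lDPrime = IRanges(41, 48),
#'               lPrime = IRanges(13, 20), rPrime = IRanges(1, 7))
#' @name boxAnnotation
#' @aliases BoxAnnotation BoxAnnotation-class
#' @export boxAnnotation
#' @exportClass BoxAnnotation
setClass("BoxAnnotation",
    representation(rDPrime = "IRanges", lDPrime = "IRanges",
                   lPrime = "IRanges", rPrime = "IRanges"))

setValidity("BoxAnnotation", function(object) {
    iv <- list(rPrime = object@rPrime, lPrime = object@lPrime,
               lDPrime = object@lDPrime, rDPrime = object@rDPrime)
    if (any(vapply(iv, length, 1L) != 1L))
        return("each box must be a single interval")
    if (IRanges::width(object@rDPrime) != 7L ||
        IRanges::width(object@rPrime) != 7L)
        return("R'' and R' boxes must be exactly 7 bp (full R box)")
    if (IRanges::width(object@lDPrime) != IRanges::width(object@lPrime))
        return("L'' and L' boxes must have equal width")
    s <- vapply(iv, IRanges::start, 1L)
    e <- vapply(iv, IRanges::end, 1L)
    # top-strand order: R' < L' < L'' < R'' (mirror of the bottom strand)
    if (!(e[["rPrime"]] < s[["lPrime"]] && e[["lPrime"]] < s[["lDPrime"]] &&
          e[["lDPrime"]] < s[["rDPrime"]]))
        return("boxes must be disjoint and ordered R' < L' < L'' < R'' in top-strand coordinates")
    if (any(s < 1L))
        return("box intervals must have start >= 1")
    TRUE
})

boxAnnotation <- function(rDPrime, lDPrime, lPrime, rPrime) {
    new("BoxAnnotation", rDPrime = rDPrime, lDPrime = lDPrime,
        lPrime = lPrime, rPrime = rPrime)
}

setMethod("show", "BoxAnnotation", function(object) {
    fmt <- function(x) sprintf("[%d, %d]", IRanges::start(x), IRanges::end(x))
    cat("BoxAnnotation (top-strand coordinates)\n",
        "  R': ", fmt(object@rPrime), "  L': ", fmt(object@lPrime),
        "  L'': ", fmt(object@lDPrime), "  R'': ", fmt(object@rDPrime), "\n",
        sep = "")
})

.boxWidthL <- function(b) IRanges::width(b@lPrime)

.boxEnd <- function(b) IRanges::end(b@rDPrime)

#' attC recombination site
#'
#' Container for a single attC site: its top-strand sequence (5' to 3'),
#' optional box architecture, origin class and source location.
#'
#' @param id character(1) site identifier.
#' @param topStrand character(1) or \code{DNAString}: top strand, 5' to 3',
#'   IUPAC alphabet.
#' @param boxes optional \linkS4class{BoxAnnotation}.
#' @param originClass one of \code{"MI"}, \code{"SCI"}, \code{"MCI"},
#'   \code{"unknown"}.
#' @param hostTaxon optional character(1).
#' @param source optional \code{GRanges} of length 1 giving the source
#'   replicon location of the site.
#' @param x an \code{AttCSite}.
#' @param value replacement value.
#'
#' @return \code{AttCSite} returns an \code{AttCSite} object;
#'   \code{siteId}, \code{topStrand}, \code{boxes} and \code{originClass}
#'   are accessors.
#'
#' @details Natural attC sites are 57-141 bp long; constructing a site
#' outside this range emits a warning (soft bound), not an error.  If boxes
#' are supplied they must lie within the sequence.
#'
#' @examples
#' s <- AttCSite("toy", "ACGTACGTACGT")
#' siteId(s); as.character(topStrand(s))
#' @name AttCSite
#' @aliases AttCSite-class siteId topStrand boxes boxes<- originClass
#' @export AttCSite
#' @exportClass AttCSite
setClass("AttCSite",
    representation(id = "character", topStrand = "DNAString",
                   boxes = "ANY", originClass = "character",
                   hostTaxon = "character", source = "ANY"))

setValidity("AttCSite", function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
        return("id must be a non-empty character(1)")
    if (length(object@topStrand) == 0L)
        return("top_strand must be non-empty")
    if (!object@originClass %in% c("MI", "SCI", "MCI", "unknown"))
        return("originClass must be one of MI, SCI, MCI, unknown")
    if (!is.null(object@boxes)) {
        if (!is(object@boxes, "BoxAnnotation"))
            return("boxes must be a BoxAnnotation or NULL")
        if (.boxEnd(object@boxes) > length(object@topStrand))
            return("box intervals must lie within the sequence")
    }
    TRUE
})

AttCSite <- function(id, topStrand, boxes = NULL, originClass = "unknown",
                     hostTaxon = NA_character_, source = NULL) {
    if (is.character(topStrand)) {
        .checkAlphabet(topStrand, "top_strand")
        topStrand <- Biostrings::DNAString(toupper(topStrand))
    }
    site <- new("AttCSite", id = id, topStrand = topStrand, boxes = boxes,
                originClass = originClass, hostTaxon = hostTaxon,
                source = source)
    n <- length(topStrand)
    if (n < 57L || n > 141L)
        warning("site '", id, "' is ", n,
                " bp; natural attC sites are 57-141 bp", call. = FALSE)
    site
}

setMethod("siteId", "AttCSite", function(x) x@id)
setMethod("topStrand", "AttCSite", function(x) x@topStrand)
setMethod("boxes", "AttCSite", function(x) x@boxes)
setReplaceMethod("boxes", "AttCSite", function(x, value) {
    x@boxes <- value
    validObject(x)
    x
})
setMethod("originClass", "AttCSite", function(x) x@originClass)

setMethod("show", "AttCSite", function(object) {
    cat("AttCSite '", object@id, "' (", length(object@topStrand), " bp, ",
        object@originClass, ")\n", sep = "")
    cat("  top strand 5'->3': ", as.character(object@topStrand), "\n",
        sep = "")
    if (!is.null(object@boxes)) show(object@boxes)
})

#' Bottom strand of a sequence or attC site
#'
#' The bottom strand is the reverse complement of the top strand, written
#' 5' to 3'.  It is the strand recombined preferentially by the integron
#' integrase and the strand whose folding the pfold statistic describes.
#'
#' @param x an \linkS4class{AttCSite}, \code{DNAString} or character(1).
#'
#' @return Same class as the sequence input (\code{DNAString} for sites).
#'
#' @examples
#' as.character(bottomStrand(AttCSite("toy", "GTTAGTTAGTTAGTTA")))
#' bottomStrand("GTTA")
#' @name bottomStrand
#' @export
setMethod("bottomStrand", "AttCSite", function(x)
    Biostrings::reverseComplement(x@topStrand))

#' @rdname bottomStrand
#' @export
setMethod("bottomStrand", "DNAString", function(x)
    Biostrings::reverseComplement(x))

#' @rdname bottomStrand
#' @export
setMethod("bottomStrand", "character", function(x) {
    stopifnot(length(x) == 1L)
    .checkAlphabet(x, "sequence")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
})

# Map a top-strand index to the bottom strand (both 1-based): i -> L + 1 - i
.topToBottom <- function(i, L) L + 1L - i

# An interval [s, e] on one strand maps to [L+1-e, L+1-s] on the other
.flipRange <- function(r, L)
    IRanges::IRanges(start = L + 1L - IRanges::end(r),
                     end = L + 1L - IRanges::start(r))

# Boxes in bottom-strand coordinates, ordered R'' < L'' < L' < R' with the
# widths preserved.  Returns a list of IRanges.
.boxesOnBottom <- function(b, L) {
    list(rDPrime = .flipRange(b@rDPrime, L),
         lDPrime = .flipRange(b@lDPrime, L),
         lPrime  = .flipRange(b@lPrime, L),
         rPrime  = .flipRange(b@rPrime, L))
}
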