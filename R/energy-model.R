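#' @include constraints.R
NULL

# Unified nearest-neighbor DNA stack free energies at 37 C (kcal/mol),
# indexed by the two 5'->3' bases of the top of the stack; the opposing
# bases are their Watson-Crick complements.  Entry [X, Y] is the increment
# for 5'-XY-3' / 3'-X'Y'-5'.
.DNA_STACKS_37 <- matrix(
    c(-1.00, -1.44, -1.28, -0.88,   # AA AC AG AT
      -1.45, -1.84, -2.17, -1.28,   # CA CC CG CT
      -1.30, -2.24, -1.84, -1.44,   # GA GC GG GT
      -0.58, -1.30, -1.45, -1.00),  # TA TC TG TT
    nrow = 4L, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))

#' Energy model for single-stranded DNA folding
#'
#' The built-in reference model is a stacking-only nearest-neighbor
#' simplification: the free energy of a secondary structure is the sum of
#' stack increments over consecutive base pairs, loop and initiation terms
#' are zero, and the open (fully unpaired) structure has energy 0 exactly,
#' which makes the exhaustive enumeration oracle exact.  Watson-Crick pairs
#' take published DNA stack free energies; G:T wobble pairs are allowed
#' (their complement A:C is not), with a uniform weak stack term for any
#' stack touching a wobble pair.  The wobble asymmetry is what lets the
#' bottom and top strands of a site differ in folding stability, as they do
#' under full DNA parameter tables: with strictly Watson-Crick pairing the
#' two strands of any site would have exactly mirror-image structures and
#' identical energies.  For reproduction of values computed with the full
#' DNA nearest-neighbor tables, see the RNAfold backend
#' (\code{\link{viennaPfold}}).
#'
#' @param temperature folding temperature in kelvin (default 310.15 K,
#'   i.e. 37 C).
#' @param minLoop minimal number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param parameterSetId identifier string for the parameter set.
#' @param stackTable 4 x 4 numeric matrix of Watson-Crick stack free
#'   energies (kcal/mol), rows/columns A, C, G, T.
#' @param wobble allow G:T pairs (default TRUE).
#' @param wobbleStack stack free energy (kcal/mol) for stacks involving at
#'   least one G:T pair (default -0.5, weakly stabilizing).
#'
#' @return \code{referenceEnergyModel} returns an \code{EnergyModel}.
#'
#' @examples
#' m <- referenceEnergyModel()
#' structureEnergy("GGGAAAACCC", "(((....)))", m)
#' @name referenceEnergyModel
#' @aliases EnergyModel-class
#' @export referenceEnergyModel
#' @exportClass EnergyModel
setClass("EnergyModel",
    representation(parameterSetId = "character", temperature = "numeric",
                   stackTable = "matrix", minLoop = "integer",
                   wobble = "logical", wobbleStack = "numeric"))

setValidity("EnergyModel", function(object) {
    if (object@temperature <= 0) return("temperature must be positive (K)")
    if (!identical(dim(object@stackTable), c(4L, 4L)))
        return("stackTable must be 4 x 4")
    if (object@minLoop < 0L) return("minLoop must be >= 0")
    TRUE
})

referenceEnergyModel <- function(temperature = 310.15, minLoop = 3L,
                                 parameterSetId = "dna-stack-37",
                                 stackTable = .DNA_STACKS_37,
                                 wobble = TRUE, wobbleStack = -0.5) {
    new("EnergyModel", parameterSetId = parameterSetId,
        temperature = temperature, stackTable = stackTable,
        minLoop = as.integer(minLoop), wobble = wobble,
        wobbleStack = wobbleStack)
}

setMethod("show", "EnergyModel", function(object) {
    cat("EnergyModel '", object@parameterSetId, "' (T = ",
        object@temperature, " K, min loop ", object@minLoop, ")\n", sep = "")
})

.rt <- function(model) .RGAS * model@temperature

# integer encoding A=0 C=1 G=2 T=3; other codes are rejected by the folding
# routines (the thermodynamic model scores concrete bases only)
.encodeSeq <- function(seq) {
    chars <- .checkAlphabet(seq)
    code <- match(chars, c("A", "C", "G", "T")) - 1L
    if (anyNA(code))
        stop("folding requires a concrete A/C/G/T sequence ",
             "(degenerate IUPAC codes cannot be scored)", call. = FALSE)
    code
}

#' Dot-bracket parsing and structure energy
#'
#' \code{parseDotBracket} converts a dot-bracket string into a base-pair
#' matrix; \code{structureEnergy} scores a structure under an
#' \linkS4class{EnergyModel} (sum of stack increments over consecutive
#' pairs; the open structure scores 0).
#'
#' @param structure dot-bracket character(1).
#' @param seq character(1) sequence (A/C/G/T).
#' @param model an \linkS4class{EnergyModel}.
#' @return \code{parseDotBracket}: integer matrix of pairs (i, j), i < j;
#'   \code{structureEnergy}: numeric(1), kcal/mol.
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(structure) {
    chars <- strsplit(structure, "")[[1L]]
    stack <- integer()
    pairs <- matrix(integer(), ncol = 2L)
    rows <- list()
    for (k in seq_along(chars)) {
        if (chars[k] == "(") {
            stack <- c(stack, k)
        } else if (chars[k] == ")") {
            if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
            rows[[length(rows) + 1L]] <- c(stack[length(stack)], k)
            stack <- stack[-length(stack)]
        } else if (chars[k] != ".") {
            stop("dot-bracket may only contain '.', '(' and ')'",
                 call. = FALSE)
        }
    }
    if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
    if (length(rows)) pairs <- do.call(rbind, rows)
    pairs[order(pairs[, 1L]), , drop = FALSE]
}

# TRUE for a G:T (wobble) pair of concrete bases
.isGT <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

#' @rdname parseDotBracket
#' @export
structureEnergy <- function(seq, structure, model = referenceEnergyModel()) {
    chars <- .checkAlphabet(seq)
    pairs <- if (is.matrix(structure)) structure else parseDotBracket(structure)
    if (is.character(structure) && nchar(structure) != length(chars))
        stop("structure length must match sequence length", call. = FALSE)
    if (!nrow(pairs)) return(0)
    partner <- integer(length(chars))
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
    e <- 0
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        # stack when the inner adjacent pair (i+1, j-1) is also formed
        if (i + 1L < j - 1L && partner[i + 1L] == j - 1L) {
            e <- e + if (.isGT(chars[i], chars[j]) ||
                         .isGT(chars[i + 1L], chars[j - 1L]))
                model@wobbleStack
            else model@stackTable[chars[i], chars[i + 1L]]
        }
    }
    e
}

# pairs -> dot-bracket
.pairsToDotBracket <- function(pairs, n) {
    s <- rep(".", n)
    if (nrow(pairs)) {
        s[pairs[, 1L]] <- "("
        s[pairs[, 2L]] <- ")"
    }
    paste(s, collapse = "")
}
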