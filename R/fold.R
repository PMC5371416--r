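#' @include energy-model.R
NULL

#' Folding outcome of a single strand
#'
#' Result container for \code{\link{foldSequence}}: the minimum free energy
#' (MFE) structure and energy and the ensemble free energy
#' \eqn{-RT \ln Z}, with a flag recording whether hard constraints were
#' applied.  The ensemble free energy never exceeds the MFE energy, since
#' \eqn{Z \ge e^{-E_{mfe}/RT}}.
#'
#' @param x a \code{FoldOutcome}.
#' @name FoldOutcome
#' @aliases FoldOutcome-class mfeStructure mfeEnergy ensembleEnergy
#' @export mfeStructure mfeEnergy ensembleEnergy
#' @exportClass FoldOutcome
setClass("FoldOutcome",
    representation(sequence = "character", mfeStructure = "character",
                   mfeEnergy = "numeric", ensembleEnergy = "numeric",
                   constrained = "logical"))

setValidity("FoldOutcome", function(object) {
    if (object@ensembleEnergy > object@mfeEnergy + 1e-9)
        return("ensemble free energy must not exceed the MFE energy")
    TRUE
})

setMethod("mfeStructure", "FoldOutcome", function(x) x@mfeStructure)
setMethod("mfeEnergy", "FoldOutcome", function(x) x@mfeEnergy)
setMethod("ensembleEnergy", "FoldOutcome", function(x) x@ensembleEnergy)

setMethod("show", "FoldOutcome", function(object) {
    cat("FoldOutcome (", if (object@constrained) "constrained" else
        "unconstrained", ")\n  ", object@sequence, "\n  ",
        object@mfeStructure, sprintf("  (%.3f kcal/mol)", object@mfeEnergy),
        sprintf("\n  ensemble free energy: %.4f kcal/mol\n",
                object@ensembleEnergy), sep = "")
})

.emptyEnsemble <- function(msg = "empty constrained ensemble") {
    stop(structure(class = c("attCfold_empty_ensemble", "error", "condition"),
                   list(message = msg, call = NULL)))
}

.asPlainSeq <- function(seq) toupper(as.character(seq))

.partnerVector <- function(n, constraints) {
    partner <- rep(-1L, n)
    if (!is.null(constraints)) {
        p <- forcedPairs(constraints)
        if (nrow(p)) {
            if (max(p) > n)
                stop("constraint index exceeds sequence length",
                     call. = FALSE)
            partner[p[, 1L]] <- p[, 2L] - 1L
            partner[p[, 2L]] <- p[, 1L] - 1L
        }
    }
    partner
}

#' Fold a single-stranded DNA sequence
#'
#' Computes the MFE structure and the ensemble free energy of a single
#' strand under an \linkS4class{EnergyModel}, optionally restricted to the
#' sub-ensemble of structures containing every forced pair of a
#' \linkS4class{ConstraintSet}.  Structures are non-crossing sets of
#' Watson-Crick pairs with at least \code{minLoop} unpaired hairpin bases;
#' the ensemble free energy is \eqn{-RT \ln \sum_S e^{-E(S)/RT}}.
#'
#' @param seq character(1) or \code{DNAString} (A/C/G/T).
#' @param model an \linkS4class{EnergyModel} (default
#'   \code{referenceEnergyModel()}).
#' @param constraints optional \linkS4class{ConstraintSet}; indices are
#'   interpreted on \code{seq} as given (callers fold the bottom strand
#'   with bottom-strand constraints).
#'
#' @return A \linkS4class{FoldOutcome}.
#'
#' @details Unsatisfiable constraints (a forced pair between
#' non-complementary bases, or one that cannot coexist with the minimum
#' loop) leave no valid structure and raise an error of class
#' \code{attCfold_empty_ensemble}; \code{\link{pfold}} maps this to
#' pfold = 0.
#'
#' @examples
#' foldSequence("GGGGAAAACCCC")
#' @export
foldSequence <- function(seq, model = referenceEnergyModel(),
                         constraints = NULL) {
    seq <- .asPlainSeq(seq)
    code <- .encodeSeq(seq)
    partner <- .partnerVector(length(code), constraints)
    res <- .fold_core(code, partner, model@stackTable, .rt(model),
                      model@minLoop, model@wobble, model@wobbleStack)
    if (res$empty)
        .emptyEnsemble()
    new("FoldOutcome", sequence = seq,
        mfeStructure = .pairsToDotBracket(res$pairs, length(code)),
        mfeEnergy = res$mfe,
        ensembleEnergy = -.rt(model) * res$lnZ,
        constrained = !is.null(constraints) && length(constraints) > 0L)
}

#' Probability of the recombinogenic fold (pfold)
#'
#' pfold is the Boltzmann probability that a strand's thermodynamic
#' ensemble adopts the recombinogenic structure:
#' \deqn{pfold = e^{(E_u - E_c)/RT} = Z_c / Z_u,}
#' where \eqn{E_u} is the Gibbs free energy of the unconstrained (total)
#' ensemble and \eqn{E_c} that of the ensemble constrained to contain every
#' recombinogenic pair (L' paired with L'', YAAC in R' paired with GTTR in
#' R'').  An empty constraint set gives pfold = 1 exactly; an empty
#' constrained ensemble gives pfold = 0.
#'
#' @param seq character(1)/\code{DNAString} sequence, or an
#'   \linkS4class{AttCSite} (whose bottom strand is folded with its
#'   recombinogenic constraints).
#' @param model an \linkS4class{EnergyModel}.
#' @param constraints a \linkS4class{ConstraintSet}; required for plain
#'   sequences, derived via \code{\link{recombinogenicConstraints}} for
#'   sites.
#' @param x a \code{PfoldResult}.
#'
#' @return A \code{PfoldResult} with slots \code{Eu}, \code{Ec} (kcal/mol),
#'   \code{R} (kcal/(mol K)), \code{T} (K) and \code{pfold};
#'   \code{pfoldValue} extracts the probability.
#'
#' @examples
#' site <- generateAttc(attcParams(), seed = 3)$site
#' pfoldValue(pfold(site))
#' @name pfold
#' @aliases PfoldResult-class pfoldValue
#' @export
#' @exportClass PfoldResult
setClass("PfoldResult",
    representation(Eu = "numeric", Ec = "numeric", R = "numeric",
                   temperature = "numeric", pfold = "numeric"))

setValidity("PfoldResult", function(object) {
    if (object@pfold < 0 || object@pfold > 1 + 1e-12)
        return("pfold must lie in [0, 1]")
    if (is.finite(object@Ec) && object@Ec < object@Eu - 1e-9)
        return("constrained ensemble energy must be >= unconstrained")
    TRUE
})

setMethod("pfoldValue", "PfoldResult", function(x) x@pfold)

setMethod("show", "PfoldResult", function(object) {
    cat(sprintf(
        "PfoldResult: pfold = %.4g (Eu = %.4f, Ec = %s kcal/mol, T = %.2f K)\n",
        object@pfold, object@Eu,
        if (is.finite(object@Ec)) sprintf("%.4f", object@Ec) else "Inf",
        object@temperature))
})

#' @rdname pfold
#' @export
pfold <- function(seq, model = referenceEnergyModel(), constraints = NULL) {
    if (is(seq, "AttCSite")) {
        if (is.null(constraints))
            constraints <- recombinogenicConstraints(seq, "bottom")
        seq <- bottomStrand(seq)
    }
    if (is.null(constraints))
        stop("constraints are required (use an empty constraintSet() for ",
             "the unconstrained reference)", call. = FALSE)
    unc <- foldSequence(seq, model)
    Eu <- ensembleEnergy(unc)
    con <- tryCatch(foldSequence(seq, model, constraints),
                    attCfold_empty_ensemble = function(e) NULL)
    if (is.null(con)) {
        return(new("PfoldResult", Eu = Eu, Ec = Inf, R = .RGAS,
                   temperature = model@temperature, pfold = 0))
    }
    Ec <- ensembleEnergy(con)
    p <- exp((Eu - Ec) / (.RGAS * model@temperature))
    new("PfoldResult", Eu = Eu, Ec = Ec, R = .RGAS,
        temperature = model@temperature, pfold = min(p, 1))
}

#' Bottom-minus-top strand stability gap
#'
#' Difference in MFE free energy between the folded bottom and top strands
#' of an attC site, \eqn{\Delta G_{bs} - \Delta G_{ts}}; negative values
#' mean the bottom strand folds more stably.  In \code{"constrained"} mode
#' each strand is folded under its own recombinogenic constraint set.
#'
#' @param site an \linkS4class{AttCSite}.
#' @param model an \linkS4class{EnergyModel}.
#' @param mode \code{"unconstrained"} (default) or \code{"constrained"}.
#'
#' @return numeric(1), kcal/mol.
#' @examples
#' site <- generateAttc(attcParams(), seed = 5)$site
#' strandStabilityGap(site)
#' @export
strandStabilityGap <- function(site, model = referenceEnergyModel(),
                               mode = c("unconstrained", "constrained")) {
    mode <- match.arg(mode)
    bs <- bottomStrand(site)
    ts <- topStrand(site)
    if (mode == "unconstrained") {
        mfeEnergy(foldSequence(bs, model)) - mfeEnergy(foldSequence(ts, model))
    } else {
        cb <- recombinogenicConstraints(site, "bottom")
        ct <- recombinogenicConstraints(site, "top")
        mfeEnergy(foldSequence(bs, model, cb)) -
            mfeEnergy(foldSequence(ts, model, ct))
    }
}

#' Exhaustive enumeration of secondary structures (oracle)
#'
#' Enumerates every valid non-crossing structure of a short sequence
#' (Watson-Crick pairs, minimum hairpin loop from the model), optionally
#' restricted to structures containing all forced pairs, each structure
#' exactly once.  This is the brute-force reference against which the
#' dynamic-programming routines are validated; it refuses sequences longer
#' than 20 nt.
#'
#' @param seq character(1)/\code{DNAString}, at most 20 nt.
#' @param model an \linkS4class{EnergyModel}.
#' @param constraints optional \linkS4class{ConstraintSet}.
#'
#' @return data.frame with columns \code{structure} (dot-bracket) and
#'   \code{energy} (kcal/mol).
#' @examples
#' enumerateStructures("GAAAC")
#' @export
enumerateStructures <- function(seq, model = referenceEnergyModel(),
                                constraints = NULL) {
    seq <- .asPlainSeq(seq)
    code <- .encodeSeq(seq)
    n <- length(code)
    if (n > 20L)
        stop("enumeration oracle refuses sequences > 20 nt", call. = FALSE)
    partner <- .partnerVector(n, constraints)
    wc <- function(a, b) (a == 0L && b == 3L) || (a == 3L && b == 0L) ||
        (a == 1L && b == 2L) || (a == 2L && b == 1L) ||
        (model@wobble && ((a == 2L && b == 3L) || (a == 3L && b == 2L)))
    allowed <- function(i, j) {
        (j - i - 1L) >= model@minLoop && wc(code[i], code[j]) &&
            (partner[i] == -1L || partner[i] == j - 1L) &&
            (partner[j] == -1L || partner[j] == i - 1L)
    }
    # rightmost-base decomposition: each structure generated exactly once
    structs <- function(i, j) {
        if (j < i) return(list(matrix(integer(), ncol = 2L)))
        out <- list()
        if (partner[j] == -1L)
            out <- structs(i, j - 1L)
        if (j > i) for (k in i:(j - 1L)) {
            if (!allowed(k, j)) next
            left <- structs(i, k - 1L)
            inner <- structs(k + 1L, j - 1L)
            for (a in left) for (b in inner)
                out[[length(out) + 1L]] <- rbind(a, c(k, j), b)
        }
        out
    }
    all <- structs(1L, n)
    data.frame(
        structure = vapply(all, .pairsToDotBracket, "", n = n),
        energy = vapply(all, function(p)
            structureEnergy(seq, p[order(p[, 1L]), , drop = FALSE], model),
            0),
        stringsAsFactors = FALSE)
}
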