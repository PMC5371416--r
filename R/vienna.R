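#' @include fold.R
NULL

#' RNAfold (ViennaRNA) DNA-parameter backend
#'
#' Optional backend that delegates folding to the \code{RNAfold} executable
#' with a DNA nearest-neighbor parameter table, the combination used to
#' compute published attC pfold values.  Hard constraints are passed as a
#' dot-bracket constraint string with enforced pairs
#' (\code{-C --enforceConstraint}); ensemble free energies come from the
#' partition function (\code{-p}).
#'
#' \code{viennaAvailable} reports whether both the executable and a DNA
#' parameter file can be found.  \code{viennaFold} returns MFE structure
#' and energies for one strand; \code{viennaPfold} combines an
#' unconstrained and a constrained run into a pfold value, and accepts an
#' \linkS4class{AttCSite} (bottom strand + recombinogenic constraints) or a
#' plain sequence plus \linkS4class{ConstraintSet}.
#'
#' @param seq character(1)/\code{DNAString}, or an \linkS4class{AttCSite}
#'   for \code{viennaPfold}.
#' @param constraints optional \linkS4class{ConstraintSet} (indices on
#'   \code{seq}).
#' @param temperature folding temperature in Celsius (default 37).
#' @param paramFile path to a ViennaRNA parameter file; by default the DNA
#'   table \code{dna_mathews2004.par} shipped next to the executable.
#'
#' @return \code{viennaFold}: list with \code{mfe_structure}, \code{mfe},
#'   \code{ensemble} (kcal/mol).  \code{viennaPfold}: list with \code{Eu},
#'   \code{Ec}, \code{pfold}.
#'
#' @examples
#' if (viennaAvailable()) {
#'   viennaFold("GGGGAAAACCCC")
#' }
#' @name viennaBackend
NULL

#' @rdname viennaBackend
#' @export
viennaParamFile <- function() {
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe)) return(NA_character_)
    cand <- file.path(dirname(dirname(exe)), "share", "ViennaRNA",
                      "dna_mathews2004.par")
    if (file.exists(cand)) cand else NA_character_
}

#' @rdname viennaBackend
#' @export
viennaAvailable <- function() {
    nzchar(Sys.which("RNAfold")) && !is.na(viennaParamFile())
}

.viennaRun <- function(seq, constraintString = NULL, temperature = 37,
                       paramFile = viennaParamFile()) {
    if (!nzchar(Sys.which("RNAfold")))
        stop("RNAfold executable not found on PATH", call. = FALSE)
    if (is.na(paramFile) || !file.exists(paramFile))
        stop("DNA parameter file not found; pass paramFile=", call. = FALSE)
    input <- c(">q", seq)
    args <- c("--noconv", "--noPS", "-p", "-P", paramFile,
              "-T", format(temperature))
    if (!is.null(constraintString)) {
        input <- c(input, constraintString)
        args <- c(args, "-C", "--enforceConstraint")
    }
    # RNAfold -p writes dot-plot PostScript into the working directory;
    # run it in a scratch dir so callers' directories stay clean
    owd <- setwd(tempdir())
    on.exit(setwd(owd), add = TRUE)
    out <- suppressWarnings(system2("RNAfold", args = args,
                                    input = input, stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
        stop("RNAfold failed: ", paste(out, collapse = "\n"), call. = FALSE)
    # MFE line: "STRUCT ( -1.20)"; ensemble line: "STRUCT [ -1.54]"
    mfeLine <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
    ensLine <- grep("\\[\\s*-?[0-9.]+\\]\\s*$", out, value = TRUE)
    if (!length(mfeLine) || !length(ensLine))
        stop("could not parse RNAfold output:\n",
             paste(out, collapse = "\n"), call. = FALSE)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                          mfeLine[1L]))
    ens <- as.numeric(sub(".*\\[\\s*(-?[0-9.]+)\\]\\s*$", "\\1",
                          ensLine[1L]))
    struct <- sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", mfeLine[1L])
    list(mfe_structure = struct, mfe = mfe, ensemble = ens)
}

.constraintString <- function(n, constraints) {
    s <- rep(".", n)
    p <- forcedPairs(constraints)
    if (nrow(p)) {
        s[p[, 1L]] <- "("
        s[p[, 2L]] <- ")"
    }
    paste(s, collapse = "")
}

#' @rdname viennaBackend
#' @export
viennaFold <- function(seq, constraints = NULL, temperature = 37,
                       paramFile = viennaParamFile()) {
    seq <- .asPlainSeq(seq)
    cstr <- if (!is.null(constraints) && length(constraints) > 0L)
        .constraintString(nchar(seq), constraints) else NULL
    .viennaRun(seq, cstr, temperature, paramFile)
}

#' @rdname viennaBackend
#' @export
viennaPfold <- function(seq, constraints = NULL, temperature = 37,
                        paramFile = viennaParamFile()) {
    if (is(seq, "AttCSite")) {
        if (is.null(constraints))
            constraints <- recombinogenicConstraints(seq, "bottom")
        seq <- bottomStrand(seq)
    }
    seq <- .asPlainSeq(seq)
    if (is.null(constraints))
        stop("constraints are required", call. = FALSE)
    unc <- viennaFold(seq, NULL, temperature, paramFile)
    con <- viennaFold(seq, constraints, temperature, paramFile)
    rt <- .RGAS * (temperature + 273.15)
    p <- exp((unc$ensemble - con$ensemble) / rt)
    list(Eu = unc$ensemble, Ec = con$ensemble, pfold = min(p, 1),
         mfe_constrained = con$mfe, mfe_unconstrained = unc$mfe)
}
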