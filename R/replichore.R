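#' @include AttCSite-class.R
NULL

#' GC-disparity profile of a sequence
#'
#' Cumulative excess of G over C along the top strand (the GC-disparity
#' component of the Z-curve): position \code{i} holds the number of G minus
#' the number of C in the prefix of length \code{i}.  The leading strand of
#' a replichore shows an increasing gradient of GC disparity.
#'
#' @param seq character(1) or \code{DNAString}; ambiguity codes contribute 0.
#' @return integer vector of the same length as the sequence.
#' @examples
#' gcDisparityProfile("GGCC")
#' @export
gcDisparityProfile <- function(seq) {
    chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
    cumsum((chars == "G") - (chars == "C"))
}

#' Replication geometry of a circular replicon
#'
#' A \code{ReplichoreMap} holds the oriC/terminus geometry of a circular
#' replicon.  Replication forks proceed from oriC to ter along both arcs;
#' on the arc from oriC rightward to ter the fork moves in the direction of
#' increasing coordinates and the GC disparity of the top strand increases.
#'
#' @param repliconLength integer(1), bp.
#' @param oric integer(1) origin position (1-based).
#' @param ter optional terminus position; defaults to the antipode.
#' @param circular logical(1); only circular replicons are supported.
#' @param repliconId character(1) identifier.
#' @param x,map a \code{ReplichoreMap}.
#' @param pos integer vector of positions (1-based).
#'
#' @return \code{replichoreMap} returns a \code{ReplichoreMap};
#'   \code{forkDirection} a character vector in
#'   \code{c("increasing", "decreasing")}.
#'
#' @examples
#' m <- replichoreMap(1000L, oric = 1L)
#' forkDirection(m, c(10L, 600L))
#' @name replichoreMap
#' @aliases ReplichoreMap-class oriC terminus forkDirection
#' @export replichoreMap
#' @exportClass ReplichoreMap
setClass("ReplichoreMap",
    representation(repliconId = "character", repliconLength = "integer",
                   circular = "logical", oric = "integer", ter = "integer"))

setValidity("ReplichoreMap", function(object) {
    if (!object@circular) return("only circular replicons are supported")
    if (object@oric == object@ter) return("oriC and ter must differ")
    if (object@oric < 1L || object@oric > object@repliconLength ||
        object@ter < 1L || object@ter > object@repliconLength)
        return("oriC/ter must lie within the replicon")
    TRUE
})

replichoreMap <- function(repliconLength, oric, ter = NULL, circular = TRUE,
                          repliconId = "replicon") {
    repliconLength <- as.integer(repliconLength)
    if (is.null(ter))
        ter <- ((as.integer(oric) - 1L + repliconLength %/% 2L) %%
                    repliconLength) + 1L
    new("ReplichoreMap", repliconId = repliconId,
        repliconLength = repliconLength, circular = circular,
        oric = as.integer(oric), ter = as.integer(ter))
}

setMethod("oriC", "ReplichoreMap", function(x) x@oric)
setMethod("terminus", "ReplichoreMap", function(x) x@ter)

setMethod("show", "ReplichoreMap", function(object) {
    cat("ReplichoreMap '", object@repliconId, "': ", object@repliconLength,
        " bp circular, oriC = ", object@oric, ", ter = ", object@ter, "\n",
        sep = "")
})

#' @rdname replichoreMap
#' @export
forkDirection <- function(map, pos) {
    stopifnot(is(map, "ReplichoreMap"))
    if (any(pos < 1L | pos > map@repliconLength))
        stop("position outside replicon", call. = FALSE)
    o <- map@oric; t <- map@ter
    inc <- if (o < t) pos >= o & pos < t else pos >= o | pos < t
    ifelse(inc, "increasing", "decreasing")
}

#' Infer replichores from a GC-disparity profile
#'
#' Locates oriC and ter on a circular replicon.  A user-supplied oriC
#' always passes through unchanged; otherwise oriC is placed at the global
#' minimum and ter at the global maximum of the circularly detrended
#' cumulative GC disparity (the profile minus its linear trend, which
#' removes the replicon-wide G/C imbalance).
#'
#' @param profile integer vector from \code{\link{gcDisparityProfile}}.
#' @param oric optional known origin position.
#' @param ter optional known terminus position.
#' @param circular logical(1); linear replicons are refused.
#' @param repliconId identifier stored in the map.
#' @param flatTol signal-to-noise multiplier: the profile is treated as
#'   flat (no skew signal) when the detrended amplitude does not exceed
#'   \code{flatTol} standard deviations of an unbiased G/C random walk of
#'   the same step count.
#'
#' @return A \linkS4class{ReplichoreMap}.
#'
#' @details A flat profile carries no strand signal; without a supplied
#' oriC the orientation is indeterminate and an error is raised.
#' @examples
#' sr <- generateReplicon(repliconLength = 20000L, seed = 1)
#' inferReplichores(gcDisparityProfile(sr$sequence))
#' @export
inferReplichores <- function(profile, oric = NULL, ter = NULL,
                             circular = TRUE, repliconId = "replicon",
                             flatTol = 5) {
    if (!circular)
        stop("replichore inference requires a circular replicon",
             call. = FALSE)
    L <- length(profile)
    detrended <- profile - seq_len(L) / L * profile[L]
    steps <- sum(abs(diff(profile))) + abs(profile[1L])
    flat <- diff(range(detrended)) <= flatTol * sqrt(steps)
    if (!is.null(oric)) {
        if (is.null(ter))
            ter <- if (flat) NULL else which.max(detrended)
        if (!is.null(ter) && ter == as.integer(oric))
            ter <- NULL
        return(replichoreMap(L, oric, ter, repliconId = repliconId))
    }
    if (flat)
        stop("orientation indeterminate: flat GC-disparity profile and no ",
             "oriC supplied", call. = FALSE)
    replichoreMap(L, which.min(detrended), which.max(detrended),
                  repliconId = repliconId)
}

#' Leading/lagging-strand-template class of a strand at a position
#'
#' During replication each physical strand serves at each locus either as
#' the leading-strand template (copied continuously) or the lagging-strand
#' template (copied discontinuously, transiently single-stranded between
#' Okazaki fragments).  Where the fork moves toward increasing coordinates,
#' the minus strand is the leading-strand template and the plus strand the
#' lagging-strand template; the classes swap on the other replichore, and
#' flipping the strand always flips the class.
#'
#' @param pos integer vector of positions (1-based).
#' @param strand character vector in \code{c("+", "-")} (recycled).
#' @param map a \linkS4class{ReplichoreMap}.
#'
#' @return character vector in
#'   \code{c("leading_template", "lagging_template")}.
#' @examples
#' m <- replichoreMap(1000L, oric = 1L)
#' templateClass(10L, c("+", "-"), m)
#' @export
templateClass <- function(pos, strand, map) {
    stopifnot(all(strand %in% c("+", "-")))
    n <- max(length(pos), length(strand))
    pos <- rep_len(pos, n)
    strand <- rep_len(strand, n)
    inc <- forkDirection(map, pos) == "increasing"
    ifelse(inc == (strand == "-"), "leading_template", "lagging_template")
}

#' Aggregate attC sites into arrays
#'
#' Consecutive attC sites whose gap does not exceed \code{maxDistance} are
#' clustered into one array (default 4 kb, configurable to 15 kb for the
#' handful of sedentary integrons that need looser clustering).
#'
#' @param attc a \code{GRanges} or data.frame with \code{start}/\code{end},
#'   sorted by start.
#' @param maxDistance maximal gap between consecutive sites (bp).
#' @return integer vector assigning each site to an array (1, 2, ...).
#' @examples
#' gr <- GenomicRanges::GRanges("r", IRanges::IRanges(
#'     c(1, 1100, 2200, 23000), width = 60))
#' aggregateArray(gr, 4000)
#' @export
aggregateArray <- function(attc, maxDistance = 4000) {
    if (is(attc, "GRanges")) {
        s <- GenomicRanges::start(attc); e <- GenomicRanges::end(attc)
    } else {
        s <- attc$start; e <- attc$end
    }
    if (is.unsorted(s))
        stop("attC sites must be sorted by start", call. = FALSE)
    if (length(s) == 0L) return(integer())
    gaps <- s[-1L] - e[-length(e)]
    cumsum(c(1L, as.integer(gaps > maxDistance)))
}

#' Integron record: integrase plus ordered attC array
#'
#' @param repliconId character(1).
#' @param attc \code{GRanges} of attC sites (sorted by start, strand
#'   \code{+}/\code{-}).
#' @param integrase optional \code{GRanges} of length 0 or 1 (metadata
#'   column \code{class} for the integrase class).
#' @param elementClass one of \code{"SCI"}, \code{"MI"}, \code{"MCI"},
#'   \code{"unknown"}.
#' @param x an \code{IntegronRecord}.
#' @return \code{IntegronRecord} returns an \code{IntegronRecord}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
#'     c(100, 700), width = 60), strand = "-")
#' IntegronRecord("chr", gr)
#' @name IntegronRecord
#' @aliases IntegronRecord-class attcSites elementClass
#' @export IntegronRecord
#' @exportClass IntegronRecord
setClass("IntegronRecord",
    representation(repliconId = "character", integrase = "ANY",
                   attc = "ANY", elementClass = "character"))

setValidity("IntegronRecord", function(object) {
    if (!is(object@attc, "GRanges")) return("attc must be a GRanges")
    if (length(object@attc) == 0L) return("record must carry >= 1 attC site")
    if (is.unsorted(GenomicRanges::start(object@attc)))
        return("attC sites must be sorted by start")
    if (!all(as.character(GenomicRanges::strand(object@attc)) %in%
             c("+", "-")))
        return("attC strands must be '+' or '-'")
    if (!object@elementClass %in% c("SCI", "MI", "MCI", "unknown"))
        return("elementClass must be SCI, MI, MCI or unknown")
    TRUE
})

IntegronRecord <- function(repliconId, attc,
                           integrase = GenomicRanges::GRanges(),
                           elementClass = "unknown") {
    new("IntegronRecord", repliconId = repliconId, attc = attc,
        integrase = integrase, elementClass = elementClass)
}

setMethod("attcSites", "IntegronRecord", function(x) x@attc)
setMethod("elementClass", "IntegronRecord", function(x) x@elementClass)

setMethod("show", "IntegronRecord", function(object) {
    cat("IntegronRecord on '", object@repliconId, "': ",
        length(object@attc), " attC site(s), class ", object@elementClass,
        if (length(object@integrase)) ", integrase present" else "",
        "\n", sep = "")
})

#' Orientation of an integron array relative to replication
#'
#' Classifies each attC site of a record by the template class of its
#' bottom strand (the strand opposite the annotated top-strand orientation)
#' and combines the per-site classes into an array label: the unanimous
#' class when all sites agree, otherwise the majority class with a
#' \code{mixed} flag; ties are labelled \code{"mixed"}.
#'
#' @param record an \linkS4class{IntegronRecord}.
#' @param map a \linkS4class{ReplichoreMap} for the record's replicon.
#' @return list with \code{orientation} (\code{"leading_template"},
#'   \code{"lagging_template"} or \code{"mixed"}), \code{perSite}
#'   (character vector), and \code{mixed} (logical flag).
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
#'     c(100, 700), width = 60), strand = "-")
#' orientIntegron(IntegronRecord("chr", gr), replichoreMap(10000L, 1L))
#' @export
orientIntegron <- function(record, map) {
    attc <- attcSites(record)
    ts <- as.character(GenomicRanges::strand(attc))
    bs <- ifelse(ts == "+", "-", "+")
    mid <- (GenomicRanges::start(attc) + GenomicRanges::end(attc)) %/% 2L
    perSite <- templateClass(mid, bs, map)
    tab <- table(factor(perSite,
                        levels = c("leading_template", "lagging_template")))
    mixed <- length(unique(perSite)) > 1L
    orientation <- if (tab[1L] == tab[2L] && mixed) "mixed"
        else names(tab)[which.max(tab)]
    list(orientation = orientation, perSite = perSite, mixed = mixed)
}

#' Cassette and CDS length metrics
#'
#' Cassette length is the start-to-start distance between consecutive attC
#' sites of an array (each cassette includes one attC site); CDS lengths
#' are partitioned into those inside the integron span and those outside,
#' optionally excluding antibiotic-resistance genes (ARGs).
#'
#' @param record an \linkS4class{IntegronRecord} (sites sorted,
#'   non-overlapping).
#' @param annotations optional \code{GRanges} of CDS features on the same
#'   replicon; logical metadata column \code{is_ARG} flags resistance
#'   genes (absent = \code{FALSE}).
#' @param excludeARG drop ARG-flagged CDSs from the length summaries.
#' @param repliconLength optional; enables modular arithmetic for arrays
#'   spanning the origin of a circular replicon.
#'
#' @return list with \code{cassettes} (data.frame: upstream_attc,
#'   downstream_attc, length), \code{cds} (data.frame: length, inside,
#'   is_ARG), and \code{summary} (mean CDS length inside/outside and their
#'   difference, replicon minus integron).
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
#'     c(100, 700), width = 60), strand = "-")
#' cassetteMetrics(IntegronRecord("chr", gr))$cassettes
#' @export
cassetteMetrics <- function(record, annotations = NULL, excludeARG = FALSE,
                            repliconLength = NA_integer_) {
    attc <- attcSites(record)
    s <- GenomicRanges::start(attc); e <- GenomicRanges::end(attc)
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
        stop("overlapping attC annotations", call. = FALSE)
    if (length(s) > 1L) {
        len <- diff(s)
        if (!is.na(repliconLength))
            len <- ((len - 1L) %% repliconLength) + 1L
        cassettes <- data.frame(upstream_attc = head(s, -1L),
                                downstream_attc = s[-1L], length = len)
    } else {
        cassettes <- data.frame(upstream_attc = integer(),
                                downstream_attc = integer(),
                                length = integer())
    }
    cds <- data.frame(length = integer(), inside = logical(),
                      is_ARG = logical())
    summary <- list(mean_cds_inside = NA_real_, mean_cds_outside = NA_real_,
                    replicon_minus_integron = NA_real_)
    if (!is.null(annotations) && length(annotations)) {
        span <- IRanges::IRanges(min(s), max(e))
        cs <- GenomicRanges::start(annotations)
        ce <- GenomicRanges::end(annotations)
        inside <- cs <= IRanges::end(span) & ce >= IRanges::start(span)
        isArg <- if ("is_ARG" %in%
                     names(S4Vectors::mcols(annotations)))
            as.logical(S4Vectors::mcols(annotations)$is_ARG)
        else rep(FALSE, length(annotations))
        cds <- data.frame(length = ce - cs + 1L, inside = inside,
                          is_ARG = isArg)
        keep <- if (excludeARG) !cds$is_ARG else rep(TRUE, nrow(cds))
        mi <- mean(cds$length[keep & cds$inside])
        mo <- mean(cds$length[keep & !cds$inside])
        summary <- list(mean_cds_inside = mi, mean_cds_outside = mo,
                        replicon_minus_integron = mo - mi)
    }
    list(cassettes = cassettes, cds = cds, summary = summary)
}

.MOBILE_INTEGRASE_CLASSES <- c("class1", "class2", "class3", "class4",
                               "class5", "1", "2", "3", "4", "5")

#' Classify an integron as sedentary (SCI) or mobile (MI)
#'
#' An integron is sedentary when it is present in all sequenced strains of
#' its species or carries more than 19 attC sites; it is mobile when it is
#' absent from more than 40\% of the sequenced genomes, lies on a plasmid,
#' or carries an integrase from one of the five mobile-integron classes.
#' Sedentary criteria take precedence; when both sets of criteria fire the
#' record is flagged as a conflict and kept sedentary.  A mobile integron
#' located on a chromosome is labelled MCI by
#' \code{\link{runOrientation}}.
#'
#' @param record an \linkS4class{IntegronRecord}.
#' @param fractionOfStrainsPresent fraction of sequenced strains of the
#'   species carrying the integron (NA = unknown).
#' @param onPlasmid logical(1) or NA.
#' @param integraseClass character(1) integrase class or NA.
#'
#' @return character(1) in \code{c("SCI", "MI", "unknown")} with attribute
#'   \code{conflict} (logical).
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
#'     seq(1, by = 700, length.out = 20), width = 60), strand = "-")
#' classifyIntegron(IntegronRecord("chr", gr))
#' @export
classifyIntegron <- function(record, fractionOfStrainsPresent = NA_real_,
                             onPlasmid = NA, integraseClass = NA_character_) {
    nAttc <- length(attcSites(record))
    sci <- isTRUE(fractionOfStrainsPresent == 1) || nAttc > 19L
    mi <- isTRUE(fractionOfStrainsPresent < 0.6) || isTRUE(onPlasmid) ||
        (!is.na(integraseClass) &&
             tolower(integraseClass) %in% .MOBILE_INTEGRASE_CLASSES)
    out <- if (sci) "SCI" else if (mi) "MI" else "unknown"
    attr(out, "conflict") <- sci && mi
    out
}
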