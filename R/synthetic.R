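#' @include boxes.R fold.R replichore.R
NULL

# run expr with a private RNG stream; the caller's RNG state is untouched
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

#' Parameters of the attC site generator
#'
#' Architecture parameters for \code{\link{generateAttc}}.  On the bottom
#' strand the generated site reads, 5' to 3':
#' R'' (GTTR-anchored 7-mer), a spacer of \code{spacer_len + ucs_len}
#' unpaired bases (the extra \code{ucs_len} bases model the unpaired
#' central spacer), the L'' stem arm, \code{ehb_count} unpaired bases at
#' the stem-loop junction (modelling extrahelical bases as a bulge), the
#' variable terminal structure (VTS), the L' stem arm (reverse complement
#' of L''), a spacer of \code{spacer_len} bases, and R' (YAAC-anchored
#' 7-mer).  Total length is
#' \code{2 * (7 + stem_pairs + spacer_len) + ucs_len + vts_len + ehb_count}.
#'
#' @param stem_pairs width of the L''/L' stem (paired boxes).
#' @param ehb_count unpaired extrahelical bases (bulge at the L''/VTS
#'   junction).
#' @param ucs_len extra unpaired bases of the central spacer on the R''
#'   side.
#' @param vts_len VTS length (>= 3, the smallest natural VTS).
#' @param spacer_len unpaired spacer between each R box and its L box.
#' @param purine_bias_bottom fraction of purines drawn for unpaired
#'   bottom-strand bases (split evenly between G and A); ignored when
#'   \code{unpaired_probs} is given.
#' @param unpaired_probs optional named probabilities (A, C, G, T) for
#'   unpaired bottom-strand bases.
#' @param vts_competitor 0 for an unstructured VTS; a positive integer k
#'   embeds in the VTS a decoy arm complementary to L'' plus k adjacent
#'   spacer bases, creating a competing helix k pairs stronger than the
#'   recombinogenic L''/L' stem (emulates structured, low-pfold VTS).
#'
#' @return list of class \code{AttCGeneratorParams}.
#' @examples
#' attcParams(vts_len = 10)
#' @export
attcParams <- function(stem_pairs = 16L, ehb_count = 0L, ucs_len = 3L,
                       vts_len = 5L, spacer_len = 5L,
                       purine_bias_bottom = 0.7, unpaired_probs = NULL,
                       vts_competitor = 0L) {
    p <- list(stem_pairs = as.integer(stem_pairs),
              ehb_count = as.integer(ehb_count),
              ucs_len = as.integer(ucs_len),
              vts_len = as.integer(vts_len),
              spacer_len = as.integer(spacer_len),
              purine_bias_bottom = purine_bias_bottom,
              unpaired_probs = unpaired_probs,
              vts_competitor = as.integer(vts_competitor))
    if (any(vapply(p[c(1:5, 8)], function(x) x < 0L, TRUE)))
        stop("negative length parameter", call. = FALSE)
    if (p$vts_len < 3L)
        stop("vts_len must be >= 3 (minimal natural VTS)", call. = FALSE)
    if (p$stem_pairs < 4L)
        stop("stem_pairs must be >= 4", call. = FALSE)
    if (p$vts_competitor > 0L &&
        p$vts_len < p$stem_pairs + p$vts_competitor + 13L)
        stop("vts_len too short to host the competitor arm", call. = FALSE)
    if (p$vts_competitor > 0L && p$vts_competitor > p$spacer_len + p$ucs_len)
        stop("vts_competitor exceeds the available spacer", call. = FALSE)
    class(p) <- "AttCGeneratorParams"
    p
}

.drawBases <- function(n, probs = NULL) {
    if (n == 0L) return(character())
    if (is.null(probs)) probs <- c(A = .25, C = .25, G = .25, T = .25)
    sample(names(probs), n, replace = TRUE, prob = probs)
}

.unpairedProbs <- function(params) {
    if (!is.null(params$unpaired_probs)) return(params$unpaired_probs)
    b <- params$purine_bias_bottom
    c(A = b / 2, C = (1 - b) / 2, G = b / 2, T = (1 - b) / 2)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a synthetic attC site with planted ground truth
#'
#' Builds the bottom strand according to \code{\link{attcParams}} (see its
#' layout description), reverse-complements it into the stored top strand,
#' and returns the site together with the planted truth: box annotation,
#' bottom-strand box intervals, the intended recombinogenic structure
#' (forced-pair set) and the generation parameters.  Sequence boundaries
#' adjacent to the stem are drawn so that the stem cannot be extended by a
#' chance complementary base, which makes heuristic box recovery exact for
#' mismatch-free sites.
#'
#' @param params an \code{AttCGeneratorParams} list.
#' @param seed integer(1); the same (params, seed) always yields the same
#'   site.
#' @param id site identifier.
#' @param originClass stored origin class.
#' @param hostTaxon stored host taxon.
#' @return list with elements \code{site} (\linkS4class{AttCSite} with
#'   boxes set) and \code{truth}.
#' @examples
#' generateAttc(attcParams(), seed = 1)$site
#' @export
generateAttc <- function(params, seed, id = sprintf("synthetic_attc_%d", seed),
                         originClass = "unknown", hostTaxon = NA_character_) {
    stopifnot(inherits(params, "AttCGeneratorParams"))
    .withSeed(seed, {
        probs <- .unpairedProbs(params)
        stem <- params$stem_pairs
        r4 <- sample(c("A", "G"), 1L)
        rdp <- c("G", "T", "T", r4, .drawBases(3L, probs))
        # the R' pyrimidine of YAAC complements the R'' purine of GTTR so
        # that all four anchor pairs are Watson-Crick
        rp <- c(.drawBases(3L, probs), unname(.COMP[r4]), "A", "A", "C")
        sp1 <- .drawBases(params$spacer_len + params$ucs_len, probs)
        sp2 <- .drawBases(params$spacer_len, probs)
        # boundary guard: the L''/L' stem must not extend outward by chance
        # (a base never pairs itself)
        if (length(sp1) && length(sp2))
            sp1[length(sp1)] <- sp2[1L]
        if (length(sp1) >= 2L && length(sp2) >= 2L)
            sp1[length(sp1) - 1L] <- sp2[2L]
        ldp <- .drawBases(stem)                 # uniform stem arm
        lp <- rev(unname(.COMP[ldp]))           # perfect complement
        ehb <- .drawBases(params$ehb_count, probs)

        if (params$vts_competitor > 0L) {
            k <- params$vts_competitor
            # decoy 3' arm pairing (tail of spacer1) + L'': k pairs stronger
            # than the genuine L''/L' helix
            tail1 <- sp1[seq(length(sp1) - k + 1L, length(sp1))]
            decoy <- rev(unname(.COMP[c(tail1, ldp)]))
            pad <- params$vts_len - length(decoy) - 3L
            vts <- c(.drawBases(3L, probs), decoy, .drawBases(pad, probs))
        } else {
            vts <- .drawBases(params$vts_len, probs)
        }

        # inward boundary guards: the stem must not extend into the loop;
        # the two positions flanking each arm are made equal to their
        # would-be partners (a base never pairs itself)
        inner <- c(ehb, vts)
        vts[length(vts)] <- inner[1L]
        vts[length(vts) - 1L] <- inner[2L]

        bsChars <- c(rdp, sp1, ldp, ehb, vts, lp, sp2, rp)
        L <- length(bsChars)
        # bottom-strand box intervals
        rdpB <- IRanges::IRanges(1L, 7L)
        ldpB <- IRanges::IRanges(8L + length(sp1),
                                 7L + length(sp1) + stem)
        lpB <- IRanges::IRanges(L - 7L - length(sp2) - stem + 1L,
                                L - 7L - length(sp2))
        rpB <- IRanges::IRanges(L - 6L, L)
        boxesTop <- boxAnnotation(rDPrime = .flipRange(rdpB, L),
                                  lDPrime = .flipRange(ldpB, L),
                                  lPrime = .flipRange(lpB, L),
                                  rPrime = .flipRange(rpB, L))
        bs <- paste(bsChars, collapse = "")
        top <- bottomStrand(bs)   # revcomp: top strand 5'->3'
        site <- suppressWarnings(
            AttCSite(id, top, boxes = boxesTop, originClass = originClass,
                     hostTaxon = hostTaxon))
        cs <- recombinogenicConstraints(site, "bottom")
        truth <- list(params = params, seed = seed,
                      bottom_strand = bs,
                      boxes_top = boxesTop,
                      boxes_bottom = list(rDPrime = rdpB, lDPrime = ldpB,
                                          lPrime = lpB, rPrime = rpB),
                      intended_structure = .pairsToDotBracket(
                          forcedPairs(cs), L),
                      forced_pairs = forcedPairs(cs),
                      length = L)
        list(site = site, truth = truth)
    })
}

#' Cohort presets for the synthetic generator
#'
#' Documented parameter distributions emulating the contrasts between
#' mobile-integron sites, non-Vibrio sedentary sites and Vibrio sedentary
#' sites: \code{MI_like} draws short, weakly structured VTS and
#' purine-biased bottom strands; \code{SCI_vibrio_like} draws 120-129 bp
#' sites whose long VTS hosts a competing decoy helix (low pfold) and a
#' reversed skew bias; \code{SCI_other_like} is intermediate, without the
#' decoy.
#'
#' @param name one of \code{"MI_like"}, \code{"SCI_other_like"},
#'   \code{"SCI_vibrio_like"}.
#' @return list of class \code{CohortPreset} with a parameter-drawing
#'   function and cohort metadata.
#' @examples
#' cohortPreset("MI_like")$origin_class
#' @export
cohortPreset <- function(name = c("MI_like", "SCI_other_like",
                                  "SCI_vibrio_like")) {
    name <- match.arg(name)
    draw <- switch(name,
        MI_like = function() {
            # bottom strands purine-rich, with G > A excess and enough T to
            # form extra wobble structure: negative top-strand GC/AT skews
            # and a more stable bottom strand
            attcParams(stem_pairs = sample(15:18, 1L),
                       spacer_len = sample(4:6, 1L),
                       ucs_len = sample(2:5, 1L),
                       ehb_count = sample(0:1, 1L),
                       vts_len = sample(3:15, 1L),
                       unpaired_probs = c(A = .25, C = .15, G = .40,
                                          T = .20))
        },
        SCI_other_like = function() {
            attcParams(stem_pairs = sample(15:18, 1L),
                       spacer_len = sample(4:6, 1L),
                       ucs_len = sample(2:5, 1L),
                       ehb_count = sample(0:1, 1L),
                       vts_len = sample(5:25, 1L),
                       unpaired_probs = c(A = .26, C = .18, G = .33,
                                          T = .23))
        },
        SCI_vibrio_like = function() {
            stem <- sample(15:18, 1L)
            spacer <- sample(4:6, 1L)
            ucs <- sample(2:5, 1L)
            total <- sample(120:129, 1L)
            vts <- total - 2L * (7L + stem + spacer) - ucs
            attcParams(stem_pairs = stem, spacer_len = spacer,
                       ucs_len = ucs, ehb_count = 0L, vts_len = vts,
                       unpaired_probs = c(A = .25, C = .40, G = .15,
                                          T = .20),
                       vts_competitor = sample(2:4, 1L))
        })
    structure(list(name = name, draw = draw,
                   origin_class = if (name == "MI_like") "MI" else "SCI",
                   host_taxon = if (name == "SCI_vibrio_like") "Vibrio"
                       else "other"),
              class = "CohortPreset")
}

#' Generate a cohort of synthetic attC sites
#'
#' Draws \code{n} sites from a \code{\link{cohortPreset}}, deterministically
#' under \code{seed}.
#'
#' @param preset a \code{CohortPreset} or preset name.
#' @param n number of sites (>= 1).
#' @param seed integer(1).
#' @return list with \code{sites} (list of \linkS4class{AttCSite}) and
#'   \code{truths} (list of per-site truth records).
#' @examples
#' cohort <- generateCohort("MI_like", n = 3, seed = 42)
#' vapply(cohort$sites, function(s) length(topStrand(s)), 1L)
#' @export
generateCohort <- function(preset, n, seed) {
    if (is.character(preset)) preset <- cohortPreset(preset)
    stopifnot(inherits(preset, "CohortPreset"))
    if (n < 1L) stop("n must be >= 1", call. = FALSE)
    .withSeed(seed, {
        paramsList <- replicate(n, preset$draw(), simplify = FALSE)
        seeds <- sample.int(.Machine$integer.max - 1L, n)
        out <- lapply(seq_len(n), function(i)
            generateAttc(paramsList[[i]], seeds[i],
                         id = sprintf("%s_%03d", preset$name, i),
                         originClass = preset$origin_class,
                         hostTaxon = preset$host_taxon))
        list(sites = lapply(out, `[[`, "site"),
             truths = lapply(out, `[[`, "truth"))
    })
}

#' Generate a synthetic replicon with planted integron arrays
#'
#' Builds a circular replicon whose background composition is G-enriched on
#' each leading strand (strength \code{skewStrength}), plants integron
#' arrays oriented so that each attC bottom strand lies on the requested
#' template, and records complete ground truth.
#'
#' @param repliconLength total length, bp.
#' @param oric planted origin position (1-based); ter is the antipode.
#' @param arrays list of array requests, each a list with
#'   \code{orientation} (\code{"lagging_template"} or
#'   \code{"leading_template"}), \code{n_sites}, and optionally
#'   \code{cassette_lengths} (numeric vector of length n_sites - 1) or
#'   \code{cassette_meanlog}/\code{cassette_sdlog} for lognormal draws.
#' @param skewStrength relative G enrichment of the leading strand
#'   (0 = no signal).
#' @param seed integer(1).
#' @param repliconId identifier.
#' @return list of class \code{SyntheticReplicon}: \code{sequence}
#'   (\code{DNAString}), \code{oric}, \code{map}
#'   (\linkS4class{ReplichoreMap}), \code{integrons} (list of
#'   \linkS4class{IntegronRecord}), \code{cds} (\code{GRanges}) and
#'   \code{truth}.
#' @examples
#' sr <- generateReplicon(repliconLength = 20000L, seed = 1)
#' sr$truth$arrays
#' @export
generateReplicon <- function(repliconLength = 50000L, oric = 1L,
                             arrays = list(
                                 list(orientation = "leading_template",
                                      n_sites = 4L),
                                 list(orientation = "lagging_template",
                                      n_sites = 4L)),
                             skewStrength = 0.3, seed = 1L,
                             repliconId = "synthetic_replicon") {
    repliconLength <- as.integer(repliconLength)
    .withSeed(seed, {
        map <- replichoreMap(repliconLength, oric,
                             repliconId = repliconId)
        inc <- forkDirection(map, seq_len(repliconLength)) == "increasing"
        pg <- ifelse(inc, 0.25 * (1 + skewStrength),
                     0.25 * (1 - skewStrength))
        pc <- 0.5 - pg
        u <- stats::runif(repliconLength)
        chars <- ifelse(u < pg, "G",
                 ifelse(u < 0.5, "C",
                 ifelse(u < 0.75, "A", "T")))

        # plant arrays alternately on the two replichores, 10% of the
        # replicon clear of oriC and ter, so that distinct arrays never
        # fall within one aggregation window
        m <- as.integer(0.10 * repliconLength)
        ter <- terminus(map)
        if (oriC(map) >= ter)
            stop("planting requires oriC left of ter (use the default ",
                 "antipodal geometry)", call. = FALSE)
        windows <- list(inc = c(oriC(map) + m, ter - m),
                        dec = c(ter + m, oriC(map) + repliconLength - m))
        if (any(vapply(windows, function(w) w[2] <= w[1], TRUE)))
            stop("replicon too short for planted arrays", call. = FALSE)
        nArr <- length(arrays)
        winOf <- ((seq_len(nArr) - 1L) %% 2L) + 1L
        anchors <- integer(nArr)
        for (w in 1:2) {
            ids <- which(winOf == w)
            if (!length(ids)) next
            anchors[ids] <- as.integer(seq(windows[[w]][1], windows[[w]][2],
                length.out = length(ids) + 1L))[seq_along(ids)]
        }
        integrons <- list()
        cdsStart <- integer(); cdsEnd <- integer(); cdsStrand <- character()
        cdsArg <- logical(); cdsInside <- logical()
        siteRows <- list()
        arrayRows <- list()
        occupied <- IRanges::IRanges()
        for (ai in seq_along(arrays)) {
            a <- arrays[[ai]]
            nS <- as.integer(a$n_sites)
            # on the increasing arc '+' is the lagging-strand template; the
            # assignment swaps on the other replichore
            lag <- a$orientation == "lagging_template"
            strand <- if (winOf[ai] == 1L) {
                if (lag) "-" else "+"
            } else {
                if (lag) "+" else "-"
            }
            gen <- lapply(seq_len(nS), function(i)
                generateAttc(attcParams(stem_pairs = sample(15:18, 1L),
                                        vts_len = sample(3:12, 1L)),
                             seed = sample.int(.Machine$integer.max - 1L, 1L),
                             id = sprintf("%s_arr%d_site%d", repliconId,
                                          ai, i)))
            widths <- vapply(gen, function(g) g$truth$length, 1L)
            clen <- if (!is.null(a$cassette_lengths)) {
                as.integer(a$cassette_lengths)
            } else if (nS > 1L) {
                ml <- if (is.null(a$cassette_meanlog)) log(600)
                    else a$cassette_meanlog
                sl <- if (is.null(a$cassette_sdlog)) 0.25 else a$cassette_sdlog
                pmax(as.integer(stats::rlnorm(nS - 1L, ml, sl)),
                     widths[-nS] + 60L)
            } else integer()
            if (nS > 1L && any(clen <= widths[-nS]))
                stop("cassette length shorter than its attC site",
                     call. = FALSE)
            starts <- anchors[ai] + c(0L, cumsum(clen))
            ends <- starts + widths - 1L
            span <- IRanges::IRanges(min(starts), max(ends))
            if (max(ends) > windows[[winOf[ai]]][2])
                stop("array does not fit within its replichore arc",
                     call. = FALSE)
            if (length(occupied) &&
                any(IRanges::overlapsAny(span, occupied)))
                stop("planted arrays overlap", call. = FALSE)
            occupied <- c(occupied, span)

            for (i in seq_len(nS)) {
                seg <- if (strand == "+")
                    as.character(topStrand(gen[[i]]$site))
                else gen[[i]]$truth$bottom_strand
                chars[starts[i]:ends[i]] <- strsplit(seg, "")[[1L]]
            }
            attcGr <- GenomicRanges::GRanges(
                repliconId, IRanges::IRanges(starts, ends),
                strand = strand)
            S4Vectors::mcols(attcGr)$site_id <-
                vapply(gen, function(g) siteId(g$site), "")
            integrons[[ai]] <- IntegronRecord(repliconId, attcGr)
            # one CDS per cassette
            if (nS > 1L) {
                for (i in seq_len(nS - 1L)) {
                    cs <- ends[i] + 15L
                    ce <- starts[i + 1L] - 15L
                    if (ce > cs + 90L) {
                        cdsStart <- c(cdsStart, cs)
                        cdsEnd <- c(cdsEnd, ce)
                        cdsStrand <- c(cdsStrand, strand)
                        cdsArg <- c(cdsArg, FALSE)
                    }
                }
            }
            siteRows[[ai]] <- data.frame(
                site_id = vapply(gen, function(g) siteId(g$site), ""),
                array = ai, start = starts, end = ends, strand = strand,
                orientation = a$orientation)
            arrayRows[[ai]] <- data.frame(
                array = ai, orientation = a$orientation, n_sites = nS,
                cassette_lengths = I(list(clen)))
        }
        # background CDSs outside planted arrays (longer, replicon-typical)
        pos <- as.integer(0.05 * repliconLength)
        while (pos < repliconLength - 2000L) {
            len <- as.integer(stats::rnorm(1L, 850, 150))
            len <- max(len, 200L)
            cand <- IRanges::IRanges(pos, pos + len - 1L)
            if (!any(IRanges::overlapsAny(
                    cand, IRanges::IRanges(IRanges::start(occupied) - 200L,
                                           IRanges::end(occupied) + 200L)))) {
                cdsStart <- c(cdsStart, pos)
                cdsEnd <- c(cdsEnd, pos + len - 1L)
                cdsStrand <- c(cdsStrand, sample(c("+", "-"), 1L))
                cdsArg <- c(cdsArg, FALSE)
            }
            pos <- pos + len + sample(80:200, 1L)
        }
        o <- order(cdsStart)
        cds <- GenomicRanges::GRanges(
            repliconId, IRanges::IRanges(cdsStart[o], cdsEnd[o]),
            strand = cdsStrand[o])
        S4Vectors::mcols(cds)$is_ARG <- cdsArg[o]
        truth <- list(oric = as.integer(oric), skew_strength = skewStrength,
                      sites = do.call(rbind, siteRows),
                      arrays = do.call(rbind, arrayRows), seed = seed)
        structure(list(sequence = Biostrings::DNAString(
                           paste(chars, collapse = "")),
                       repliconId = repliconId, oric = as.integer(oric),
                       map = map, integrons = integrons, cds = cds,
                       truth = truth),
                  class = "SyntheticReplicon")
    })
}
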