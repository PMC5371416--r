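#' @include io.R vienna.R stats.R
NULL

#' Run configuration for the analysis pipelines
#'
#' Collects the tunable parameters shared by the pipeline entry points.
#' All defaults are documented here: folding at 37 C under the built-in
#' stacking model, pfold threshold 0.1 (strict), array aggregation at
#' 4 kb, identity scoring match +1 / mismatch -1 / gap open -2 /
#' gap extend -1.
#'
#' @param temperature kelvin (default 310.15).
#' @param backend \code{"reference"} (built-in model) or \code{"vienna"}
#'   (RNAfold with DNA parameters).
#' @param pfoldThreshold threshold for the high-pfold proportion.
#' @param aggregationDistance array aggregation distance, bp.
#' @param identityScoring named numeric: match, mismatch, gapOpening,
#'   gapExtension.
#' @param seed integer seed recorded and used by every random operation.
#' @param excludeTaxon optional taxon name excluded from comparisons.
#' @param excludeARG drop ARG-flagged CDSs in length metrics.
#' @return list of class \code{RunConfig}.
#' @examples
#' runConfig(seed = 7)$pfold_threshold
#' @export
runConfig <- function(temperature = 310.15, backend = "reference",
                      pfoldThreshold = 0.1, aggregationDistance = 4000,
                      identityScoring = c(match = 1, mismatch = -1,
                                          gapOpening = 2, gapExtension = 1),
                      seed = 1L, excludeTaxon = NA_character_,
                      excludeARG = FALSE) {
    structure(list(temperature = temperature, backend = backend,
                   pfold_threshold = pfoldThreshold,
                   aggregation_distance = aggregationDistance,
                   identity_scoring = identityScoring,
                   seed = as.integer(seed), exclude_taxon = excludeTaxon,
                   exclude_arg = excludeARG),
              class = "RunConfig")
}

.configModel <- function(config) {
    referenceEnergyModel(temperature = config$temperature)
}

.flattenConfig <- function(config) {
    flat <- list()
    for (nm in names(config)) {
        v <- config[[nm]]
        if (length(v) > 1L)
            v <- paste(sprintf("%s=%s", names(v), v), collapse = ",")
        flat[[nm]] <- as.character(v)
    }
    flat
}

#' Per-site folding and skew metrics
#'
#' Computes, for each attC site, its length, the bottom-strand pfold, the
#' MFE free energies of both strands with and without recombinogenic
#' constraints, the bottom-minus-top stability gaps and the top-strand
#' skews.  Sites whose boxes cannot be annotated are reported with status
#' \code{"unannotatable"} and NA metrics rather than aborting the run.
#'
#' @param sites named list of \linkS4class{AttCSite} (e.g. from
#'   \code{\link{readAttCSites}} or \code{\link{generateCohort}}), or a
#'   FASTA path.
#' @param boxAnnotations optional named list of
#'   \linkS4class{BoxAnnotation} overriding stored/heuristic boxes.
#' @param config a \code{\link{runConfig}}.
#' @return data.frame, one row per site: \code{site_id}, \code{length},
#'   \code{pfold}, \code{mfe_bs}, \code{mfe_ts}, \code{mfe_bs_con},
#'   \code{mfe_ts_con}, \code{gap}, \code{gap_con}, \code{gc_skew},
#'   \code{at_skew}, \code{origin_class}, \code{host_taxon},
#'   \code{status}.
#' @examples
#' cohort <- generateCohort("MI_like", n = 2, seed = 1)
#' runSiteMetrics(cohort$sites)
#' @export
runSiteMetrics <- function(sites, boxAnnotations = NULL,
                           config = runConfig()) {
    if (is.character(sites) && length(sites) == 1L)
        sites <- readAttCSites(sites, boxAnnotations)
    if (!length(sites)) stop("no sites to analyse", call. = FALSE)
    model <- .configModel(config)
    rows <- lapply(sites, function(site) {
        id <- siteId(site)
        if (!is.null(boxAnnotations) && !is.null(boxAnnotations[[id]]))
            boxes(site) <- boxAnnotations[[id]]
        na <- data.frame(site_id = id,
                         length = length(topStrand(site)),
                         pfold = NA_real_, mfe_bs = NA_real_,
                         mfe_ts = NA_real_, mfe_bs_con = NA_real_,
                         mfe_ts_con = NA_real_, gap = NA_real_,
                         gap_con = NA_real_, gc_skew = NA_real_,
                         at_skew = NA_real_,
                         origin_class = originClass(site),
                         host_taxon = site@hostTaxon,
                         status = "unannotatable")
        cs <- tryCatch(recombinogenicConstraints(site, "bottom"),
                       error = function(e) NULL)
        sk <- skews(topStrand(site), "top")
        na$gc_skew <- sk$gc_skew
        na$at_skew <- sk$at_skew
        if (is.null(cs)) return(na)
        bs <- bottomStrand(site); ts <- topStrand(site)
        fb <- foldSequence(bs, model)
        ft <- foldSequence(ts, model)
        pf <- pfold(bs, model, cs)
        cst <- flipConstraintStrand(cs, length(ts))
        fbc <- tryCatch(foldSequence(bs, model, cs),
                        attCfold_empty_ensemble = function(e) NULL)
        ftc <- tryCatch(foldSequence(ts, model, cst),
                        attCfold_empty_ensemble = function(e) NULL)
        na$pfold <- pfoldValue(pf)
        na$mfe_bs <- mfeEnergy(fb)
        na$mfe_ts <- mfeEnergy(ft)
        na$mfe_bs_con <- if (is.null(fbc)) NA_real_ else mfeEnergy(fbc)
        na$mfe_ts_con <- if (is.null(ftc)) NA_real_ else mfeEnergy(ftc)
        na$gap <- na$mfe_bs - na$mfe_ts
        na$gap_con <- na$mfe_bs_con - na$mfe_ts_con
        na$status <- "ok"
        na
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    nbad <- sum(out$status != "ok")
    if (nbad) message(nbad, " site(s) could not be annotated")
    out
}

#' Orientation of integron arrays relative to replication
#'
#' For every aggregated array: the template class of its attC bottom
#' strands (unanimous/majority with a mixed flag), the number of sites and
#' the array span.  Replicons without a usable oriC (no supplied position
#' and a flat GC-disparity profile) are reported as
#' \code{"indeterminate"}.
#'
#' @param genome \code{DNAStringSet} or FASTA path of replicon sequences.
#' @param integronTable data.frame (see \code{\link{readIntegronTable}})
#'   or TSV path.
#' @param oricTable named integer vector of oriC positions, TSV path, or
#'   NULL to infer from the skew profile.
#' @param config a \code{\link{runConfig}}.
#' @return data.frame, one row per array: \code{replicon_id},
#'   \code{array}, \code{n_attC}, \code{span_start}, \code{span_end},
#'   \code{orientation}, \code{mixed}, \code{element_class}.
#' @export
runOrientation <- function(genome, integronTable, oricTable = NULL,
                           config = runConfig()) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
    if (is.character(integronTable) && length(integronTable) == 1L)
        integronTable <- readIntegronTable(integronTable)
    if (is.character(oricTable) && length(oricTable) == 1L)
        oricTable <- readOriCTable(oricTable)
    records <- integronRecordsFromTable(integronTable,
                                        config$aggregation_distance)
    missing <- setdiff(unique(vapply(records, function(r) r@repliconId, "")),
                       names(genome))
    if (length(missing))
        stop("no replicon sequence for annotated integron(s) on: ",
             paste(missing, collapse = ", "), call. = FALSE)
    maps <- new.env(parent = emptyenv())
    arrayCount <- new.env(parent = emptyenv())
    rows <- lapply(records, function(rec) {
        rid <- rec@repliconId
        if (is.null(maps[[rid]])) {
            oric <- if (!is.null(oricTable) && rid %in% names(oricTable))
                oricTable[[rid]] else NULL
            maps[[rid]] <- tryCatch(
                inferReplichores(gcDisparityProfile(genome[[rid]]),
                                 oric = oric, repliconId = rid),
                error = function(e) NA)
        }
        map <- maps[[rid]]
        gr <- attcSites(rec)
        ai <- if (is.null(arrayCount[[rid]])) 1L else arrayCount[[rid]] + 1L
        arrayCount[[rid]] <- ai
        base <- data.frame(replicon_id = rid, array = ai,
                           n_attC = length(gr),
                           span_start = min(GenomicRanges::start(gr)),
                           span_end = max(GenomicRanges::end(gr)),
                           orientation = "indeterminate", mixed = NA,
                           element_class = elementClass(rec))
        if (is(map, "ReplichoreMap")) {
            ori <- orientIntegron(rec, map)
            base$orientation <- ori$orientation
            base$mixed <- ori$mixed
        }
        base
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    tab <- table(out$element_class, out$orientation)
    message("orientation by class:\n",
            paste(utils::capture.output(print(tab)), collapse = "\n"))
    out
}

#' Group comparisons of site metrics
#'
#' All pairwise rank-sum tests between groups for pfold, length and
#' stability gap, per-group cohort summaries, and per-group regressions of
#' pfold and stability gap against site length.
#'
#' @param siteTable data.frame from \code{\link{runSiteMetrics}} (or with
#'   compatible columns).
#' @param grouping column name in \code{siteTable} or a vector of group
#'   labels (>= 2 non-empty groups required).
#' @param config a \code{\link{runConfig}}; \code{exclude_taxon} rows are
#'   dropped before testing.
#' @return list with \code{summary} (from \code{\link{cohortSummary}}),
#'   \code{tests} (data.frame: metric, group1, group2, p) and
#'   \code{regressions} (data.frame: group, response, slope, r_squared,
#'   p_slope).
#' @export
runCompare <- function(siteTable, grouping = "origin_class",
                       config = runConfig()) {
    if (length(grouping) == 1L && grouping %in% names(siteTable))
        grouping <- siteTable[[grouping]]
    grouping <- as.character(grouping)
    stopifnot(length(grouping) == nrow(siteTable))
    if (!is.na(config$exclude_taxon) &&
        "host_taxon" %in% names(siteTable)) {
        keep <- is.na(siteTable$host_taxon) |
            siteTable$host_taxon != config$exclude_taxon
        siteTable <- siteTable[keep, , drop = FALSE]
        grouping <- grouping[keep]
    }
    groups <- unique(grouping)
    if (length(groups) < 2L)
        stop("need >= 2 non-empty groups", call. = FALSE)
    summary <- cohortSummary(siteTable, grouping,
                             pfoldThreshold = config$pfold_threshold)
    metrics <- intersect(c("pfold", "length", "gap"), names(siteTable))
    tests <- list()
    for (m in metrics) {
        for (a in seq_len(length(groups) - 1L)) {
            for (b in seq((a + 1L), length(groups))) {
                x <- siteTable[[m]][grouping == groups[a]]
                y <- siteTable[[m]][grouping == groups[b]]
                x <- x[!is.na(x)]; y <- y[!is.na(y)]
                if (!length(x) || !length(y)) next
                rs <- rankSumTest(x, y)
                tests[[length(tests) + 1L]] <- data.frame(
                    metric = m, group1 = groups[a], group2 = groups[b],
                    statistic = rs$statistic, p = rs$p_two_sided,
                    method = rs$method)
            }
        }
    }
    regs <- list()
    for (g in groups) {
        d <- siteTable[grouping == g, , drop = FALSE]
        for (resp in intersect(c("pfold", "gap"), names(d))) {
            ok <- !is.na(d[[resp]]) & !is.na(d$length)
            if (sum(ok) < 3L || stats::var(d$length[ok]) == 0) next
            fit <- linearFit(d$length[ok], d[[resp]][ok])
            regs[[length(regs) + 1L]] <- data.frame(
                group = g, response = resp, slope = fit$slope,
                r_squared = fit$r_squared, p_slope = fit$p_slope)
        }
    }
    list(summary = summary,
         tests = do.call(rbind, tests),
         regressions = if (length(regs)) do.call(rbind, regs) else NULL)
}

#' Write pipeline reports to disk
#'
#' Writes every table as TSV (always) and optionally JSON, plus a run
#' manifest echoing the full configuration, package and R versions and the
#' seed.  Two runs with identical configuration and seeds produce
#' byte-identical TSVs.
#'
#' @param tables named list of data.frames.
#' @param outdir output directory (created if needed).
#' @param formats subset of \code{c("tsv", "json")}.
#' @param config a \code{\link{runConfig}}, echoed into the manifest.
#' @return invisible named vector of written file paths.
#' @export
writeReport <- function(tables, outdir, formats = "tsv",
                        config = runConfig()) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (nm in names(tables)) {
        if ("tsv" %in% formats) {
            p <- file.path(outdir, paste0(nm, ".tsv"))
            write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            paths[paste0(nm, ".tsv")] <- p
        }
        if ("json" %in% formats) {
            p <- file.path(outdir, paste0(nm, ".json"))
            jsonlite::write_json(tables[[nm]], p, digits = NA,
                                 na = "null")
            paths[paste0(nm, ".json")] <- p
        }
    }
    manifest <- file.path(outdir, "manifest.txt")
    flat <- .flattenConfig(config)
    lines <- c(sprintf("attCfold_version: %s",
                       as.character(packageVersion("attCfold"))),
               sprintf("r_version: %s", R.version.string),
               sprintf("%s: %s", names(flat), unlist(flat)),
               sprintf("tables: %s", paste(names(tables), collapse = ", ")))
    writeLines(lines, manifest)
    paths["manifest.txt"] <- manifest
    invisible(paths)
}
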