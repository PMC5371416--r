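#' @include synthetic.R
NULL

#' Read attC sites from a FASTA file
#'
#' Reads top-strand site sequences (one record per site; the record id up
#' to the first whitespace becomes the site id) and attaches explicit box
#' annotations when provided.
#'
#' @param path FASTA file.
#' @param boxAnnotations optional named list of
#'   \linkS4class{BoxAnnotation} (see \code{\link{readBoxAnnotations}}).
#' @param originClass origin class recorded for every site.
#' @return named list of \linkS4class{AttCSite}.
#' @export
readAttCSites <- function(path, boxAnnotations = NULL,
                          originClass = "unknown") {
    ss <- Biostrings::readDNAStringSet(path)
    if (!length(ss)) stop("empty FASTA: ", path, call. = FALSE)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
    out <- lapply(seq_along(ss), function(i) {
        bx <- if (!is.null(boxAnnotations)) boxAnnotations[[ids[i]]]
        suppressWarnings(AttCSite(ids[i], ss[[i]], boxes = bx,
                                  originClass = originClass))
    })
    names(out) <- ids
    out
}

#' Read an integron annotation table
#'
#' Tab-separated table in an IntegronFinder-like layout with columns
#' \code{replicon_id}, \code{element} (\code{attC} or \code{integrase}),
#' \code{start}, \code{end}, \code{strand} and optional \code{annotation}
#' (integrase class for integrase rows), \code{host_taxon},
#' \code{element_class}, \code{on_plasmid}.
#'
#' @param path file path; \code{#} lines are comments.
#' @return data.frame.
#' @export
readIntegronTable <- function(path) {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("replicon_id", "element", "start", "end", "strand")
    if (!all(need %in% names(tab)))
        stop("integron table must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    tab
}

#' Build integron records from an annotation table
#'
#' Groups attC rows by replicon, aggregates consecutive sites into arrays
#' (gap threshold \code{maxDistance}) and attaches each integrase row to
#' the nearest array on its replicon.
#'
#' @param tab data.frame from \code{\link{readIntegronTable}}.
#' @param maxDistance aggregation distance, bp (default 4000).
#' @return list of \linkS4class{IntegronRecord}.
#' @export
integronRecordsFromTable <- function(tab, maxDistance = 4000) {
    out <- list()
    for (rid in unique(tab$replicon_id)) {
        d <- tab[tab$replicon_id == rid, , drop = FALSE]
        attc <- d[d$element == "attC", , drop = FALSE]
        intg <- d[d$element == "integrase", , drop = FALSE]
        if (!nrow(attc)) next
        attc <- attc[order(attc$start), , drop = FALSE]
        grp <- aggregateArray(attc, maxDistance)
        for (g in unique(grp)) {
            a <- attc[grp == g, , drop = FALSE]
            gr <- GenomicRanges::GRanges(rid,
                IRanges::IRanges(a$start, a$end), strand = a$strand)
            if ("site_id" %in% names(a))
                S4Vectors::mcols(gr)$site_id <- a$site_id
            igr <- GenomicRanges::GRanges()
            if (nrow(intg)) {
                mid <- (min(a$start) + max(a$end)) / 2
                k <- which.min(abs((intg$start + intg$end) / 2 - mid))
                igr <- GenomicRanges::GRanges(rid,
                    IRanges::IRanges(intg$start[k], intg$end[k]),
                    strand = intg$strand[k])
                if ("annotation" %in% names(intg))
                    S4Vectors::mcols(igr)$class <- intg$annotation[k]
            }
            ec <- if ("element_class" %in% names(a) &&
                      a$element_class[1L] %in% c("SCI", "MI", "MCI"))
                a$element_class[1L] else "unknown"
            out[[length(out) + 1L]] <- IntegronRecord(rid, gr, igr, ec)
        }
    }
    out
}

#' Read an oriC position table
#'
#' Tab-separated columns \code{replicon_id}, \code{position}.
#'
#' @param path file path.
#' @return named integer vector of origin positions.
#' @export
readOriCTable <- function(path) {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("replicon_id", "position") %in% names(tab)))
        stop("oriC table must have columns replicon_id, position",
             call. = FALSE)
    setNames(as.integer(tab$position), tab$replicon_id)
}

#' Read CDS features from GFF3
#'
#' Imports CDS (and gene) features; the logical attribute \code{is_ARG},
#' or membership of the feature \code{ID} in \code{argIds}, flags
#' antibiotic-resistance genes.
#'
#' @param path GFF3 file.
#' @param argIds optional character vector of ARG feature ids.
#' @return \code{GRanges} with metadata column \code{is_ARG}.
#' @export
readCDSTable <- function(path, argIds = character()) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
        gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
    m <- S4Vectors::mcols(gr)
    arg <- rep(FALSE, length(gr))
    if ("is_ARG" %in% names(m))
        arg <- tolower(as.character(m$is_ARG)) %in% c("true", "1", "yes")
    if (length(argIds) && "ID" %in% names(m))
        arg <- arg | as.character(m$ID) %in% argIds
    S4Vectors::mcols(gr)$is_ARG <- arg
    gr
}

#' Write a synthetic replicon and its annotations to disk
#'
#' Serializes a \code{\link{generateReplicon}} result as plain-text files
#' that round-trip through the package readers: replicon FASTA, CDS GFF3,
#' an IntegronFinder-like integron TSV, an oriC TSV and the ground-truth
#' site table.
#'
#' @param sr a \code{SyntheticReplicon}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeSyntheticReplicon <- function(sr, dir) {
    stopifnot(inherits(sr, "SyntheticReplicon"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "replicon.fasta"),
               gff = file.path(dir, "cds.gff3"),
               integrons = file.path(dir, "integrons.tsv"),
               oric = file.path(dir, "oric.tsv"),
               truth = file.path(dir, "truth_sites.tsv"))
    ss <- Biostrings::DNAStringSet(setNames(list(sr$sequence),
                                            sr$repliconId))
    Biostrings::writeXStringSet(ss, paths["fasta"])
    cds <- sr$cds
    S4Vectors::mcols(cds)$type <- "CDS"
    S4Vectors::mcols(cds)$phase <- 0L
    rtracklayer::export(cds, paths["gff"], format = "gff3")
    rows <- do.call(rbind, lapply(sr$integrons, function(rec) {
        gr <- attcSites(rec)
        data.frame(replicon_id = sr$repliconId, element = "attC",
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   site_id = S4Vectors::mcols(gr)$site_id)
    }))
    write.table(rows, paths["integrons"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(replicon_id = sr$repliconId,
                           position = sr$oric),
                paths["oric"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sr$truth$sites, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths
}
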