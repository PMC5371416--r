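test_that("generateAttc is deterministic and obeys the construction arithmetic", {
    p <- attcParams(stem_pairs = 15, ehb_count = 1, ucs_len = 4,
                    vts_len = 9, spacer_len = 5)
    g1 <- generateAttc(p, seed = 77)
    g2 <- generateAttc(p, seed = 77)
    expect_identical(as.character(topStrand(g1$site)),
                     as.character(topStrand(g2$site)))
    expect_equal(g1$truth$length,
                 2 * (7 + p$stem_pairs + p$spacer_len) + p$ucs_len +
                     p$vts_len + p$ehb_count)
    g3 <- generateAttc(p, seed = 78)
    expect_false(identical(as.character(topStrand(g1$site)),
                           as.character(topStrand(g3$site))))
    expect_error(attcParams(vts_len = 2), "vts_len")
    expect_error(attcParams(stem_pairs = -1), "negative|stem")
})

test_that("default presets emit natural site lengths and recoverable boxes", {
    for (preset in c("MI_like", "SCI_other_like", "SCI_vibrio_like")) {
        cohort <- generateCohort(preset, n = 15, seed = 3)
        lens <- vapply(cohort$sites,
                       function(s) length(topStrand(s)), 1L)
        expect_true(all(lens >= 57 & lens <= 141), info = preset)
    }
    # vibrio-like sites target the 120-129 bp mode
    vb <- generateCohort("SCI_vibrio_like", n = 15, seed = 3)
    lens <- vapply(vb$sites, function(s) length(topStrand(s)), 1L)
    expect_true(all(lens >= 120 & lens <= 129))

    # mismatch-free sites: exact heuristic box recovery
    cohort <- generateCohort("MI_like", n = 10, seed = 12)
    for (i in seq_along(cohort$sites)) {
        g <- cohort$truths[[i]]
        if (g$params$ehb_count > 0) next
        found <- locateBoxes(topStrand(cohort$sites[[i]]))
        planted <- g$boxes_top
        for (slotn in c("rDPrime", "lDPrime", "lPrime", "rPrime"))
            expect_equal(c(IRanges::start(slot(found, slotn)),
                           IRanges::end(slot(found, slotn))),
                         c(IRanges::start(slot(planted, slotn)),
                           IRanges::end(slot(planted, slotn))),
                         info = paste(i, slotn))
    }
})

test_that("generated recombinogenic constraints are pairable under the planted sequence", {
    for (seed in 1:8) {
        preset <- cohortPreset(c("MI_like", "SCI_vibrio_like")[seed %% 2 + 1])
        g <- generateCohort(preset, 1, seed)$truths[[1]]
        bs <- strsplit(g$bottom_strand, "")[[1]]
        p <- g$forced_pairs
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ok <- unname(comp[bs[p[, 1]]]) == bs[p[, 2]] |
            (bs[p[, 1]] == "G" & bs[p[, 2]] == "T") |
            (bs[p[, 1]] == "T" & bs[p[, 2]] == "G")
        expect_true(all(ok))
    }
})

test_that("cohort boundaries and determinism hold", {
    expect_error(generateCohort("MI_like", 0, seed = 1), "n must be")
    one <- generateCohort("MI_like", 1, seed = 5)
    expect_length(one$sites, 1L)
    a <- generateCohort("SCI_vibrio_like", 4, seed = 9)
    b <- generateCohort("SCI_vibrio_like", 4, seed = 9)
    expect_identical(lapply(a$sites, function(s) as.character(topStrand(s))),
                     lapply(b$sites, function(s) as.character(topStrand(s))))
})

test_that("cohort contrasts have the directions built into the presets", {
    mi <- generateCohort("MI_like", 40, seed = 101)
    vb <- generateCohort("SCI_vibrio_like", 40, seed = 102)
    pf <- function(cc) vapply(cc$sites, function(s) pfoldValue(pfold(s)), 1)
    lens <- function(cc) vapply(cc$sites,
                                function(s) length(topStrand(s)), 1L)
    gsk <- function(cc) vapply(cc$sites,
                               function(s) skews(topStrand(s))$gc_skew, 1)
    expect_gt(median(pf(mi)), median(pf(vb)))
    expect_lt(median(lens(mi)), median(lens(vb)))
    expect_lt(median(gsk(mi)), 0)
    expect_gt(median(gsk(vb)), 0)
    # stability gaps: bottom more stable for MI-like, top for Vibrio-like
    gmi <- vapply(mi$sites, strandStabilityGap, 1)
    gvb <- vapply(vb$sites, strandStabilityGap, 1)
    expect_lt(median(gmi), 0)
    expect_gt(median(gvb), 0)
})

test_that("synthetic replicons plant arrays with the requested orientation and cassette lengths", {
    sr <- generateReplicon(
        repliconLength = 30000L, oric = 1L,
        arrays = list(list(orientation = "leading_template", n_sites = 3L,
                           cassette_lengths = c(600L, 600L)),
                      list(orientation = "lagging_template", n_sites = 3L)),
        seed = 21)
    expect_length(sr$integrons, 2L)
    o1 <- orientIntegron(sr$integrons[[1]], sr$map)
    o2 <- orientIntegron(sr$integrons[[2]], sr$map)
    expect_equal(o1$orientation, "leading_template")
    expect_equal(o2$orientation, "lagging_template")
    expect_false(o1$mixed || o2$mixed)
    cm <- cassetteMetrics(sr$integrons[[1]])
    expect_equal(cm$cassettes$length, c(600, 600))
    # planted sequence really carries the attC site at the annotated spot
    gr <- attcSites(sr$integrons[[1]])
    seg <- as.character(Biostrings::subseq(
        sr$sequence, GenomicRanges::start(gr)[1],
        GenomicRanges::end(gr)[1]))
    expect_equal(nchar(seg), GenomicRanges::width(gr)[1])
})

test_that("planted orientation is recovered across many seeded replicons", {
    hits <- 0L; total <- 0L
    for (seed in 1:12) {
        sr <- generateReplicon(repliconLength = 24000L, seed = seed,
                               arrays = list(
                                   list(orientation = "leading_template",
                                        n_sites = 3L),
                                   list(orientation = "lagging_template",
                                        n_sites = 3L)))
        map <- inferReplichores(gcDisparityProfile(sr$sequence))
        planted <- sr$truth$arrays$orientation
        got <- vapply(sr$integrons,
                      function(r) orientIntegron(r, map)$orientation, "")
        hits <- hits + sum(got == planted)
        total <- total + length(got)
    }
    expect_equal(hits, total)   # 100% recovery of unambiguous arrays
})

test_that("synthetic replicons round-trip through the package readers", {
    sr <- generateReplicon(repliconLength = 24000L, seed = 31)
    dir <- withr::local_tempdir()
    paths <- writeSyntheticReplicon(sr, dir)
    expect_true(all(file.exists(paths)))
    tab <- readIntegronTable(paths["integrons"])
    recs <- integronRecordsFromTable(tab)
    expect_length(recs, length(sr$integrons))
    expect_equal(GenomicRanges::start(attcSites(recs[[1]])),
                 GenomicRanges::start(attcSites(sr$integrons[[1]])))
    oric <- readOriCTable(paths["oric"])
    expect_equal(unname(oric[sr$repliconId]), sr$oric)
    cds <- readCDSTable(paths["gff"])
    expect_equal(length(cds), length(sr$cds))
})
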