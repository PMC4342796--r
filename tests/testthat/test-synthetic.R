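test_that("the noiseless limit marks every enhancer and nothing else", {
    cfg <- simulationConfig(n_chroms = 2L, chrom_length = 2e6,
                            n_target_enhancers = 60L,
                            n_other_enhancers = 60L,
                            p_max = 1, lam = 0, p_bg = 0, shared_frac = 0,
                            seed = 61L)
    st <- simulateStudy(cfg)
    man <- as.data.frame(studyManifest(st))
    heart_ids <- man$dataset_id[man$tissue == "heart"]
    enh_all <- c(granges(targetEnhancers(st)), granges(otherEnhancers(st)))
    for (id in heart_ids) {
        pk <- peakSets(st)[[id]]
        # every target enhancer marked, every peak covers an enhancer
        expect_true(all(hasOverlap(targetEnhancers(st), pk)), label = id)
        expect_true(all(hasOverlap(pk, enh_all)), label = id)
    }
    # with shared_frac = 0, tissue contexts mark exactly their own tissue
    other <- otherEnhancers(st)
    for (tis in cfg$tissue_names) {
        pk <- peakSets(st)[[paste0(tis, "_H3K27ac")]]
        own <- other[mcols(other)$tissue == tis]
        expect_true(all(hasOverlap(own, pk)))
        expect_false(any(hasOverlap(targetEnhancers(st), pk)))
    }
})

test_that("with no decay all lineage contexts mark at a common rate", {
    cfg <- simulationConfig(n_target_enhancers = 500L,
                            n_other_enhancers = 60L, lam = 0, p_bg = 0,
                            shared_frac = 0, seed = 62L)
    st <- simulateStudy(cfg)
    man <- as.data.frame(studyManifest(st))
    heart_ids <- man$dataset_id[man$tissue == "heart"]
    marked <- vapply(heart_ids, function(id)
        sum(hasOverlap(targetEnhancers(st), peakSets(st)[[id]])),
        numeric(1))
    # equality of the marking rates across contexts (all should be p_max)
    chisq <- suppressWarnings(chisq.test(rbind(marked, 500 - marked)))
    expect_gt(chisq$p.value, 0.01)
    expect_true(all(abs(marked / 500 - cfg$p_max) <
                        3 * sqrt(cfg$p_max * (1 - cfg$p_max) / 500)))
})

test_that("marking frequency tracks the exponential-decay closed form", {
    cfg <- simulationConfig(n_target_enhancers = 2000L,
                            n_other_enhancers = 60L, p_bg = 0,
                            shared_frac = 0, seed = 63L)
    st <- simulateStudy(cfg)
    man <- as.data.frame(studyManifest(st))
    heart <- man[man$tissue == "heart", ]
    freq <- vapply(seq_len(nrow(heart)), function(i)
        mean(hasOverlap(targetEnhancers(st),
                        peakSets(st)[[heart$dataset_id[i]]])), numeric(1))
    d <- abs(heart$stage_coord - cfg$target_stage)
    p_expect <- cfg$p_max * exp(-cfg$lam * d)
    se <- sqrt(p_expect * (1 - p_expect) / 2000)
    expect_true(all(abs(freq - p_expect) <= 3 * se))
    # monotone non-increasing in developmental distance (averaged per stage)
    stage_freq <- tapply(freq, d, mean)
    expect_true(all(diff(stage_freq[order(as.numeric(names(stage_freq)))])
                    <= 0))
})

test_that("enhancer placement is non-overlapping and within bounds", {
    st <- simulateStudy(smallStudyConfig())
    tgt <- targetEnhancers(st); oth <- otherEnhancers(st)
    all_enh <- c(granges(tgt), granges(oth))
    hits <- findOverlaps(all_enh, all_enh)
    expect_true(all(queryHits(hits) == subjectHits(hits)))
    lens <- seqlengths(studyGenome(st))
    for (gr in c(list(tgt, oth), as.list(peakSets(st)))) {
        expect_true(all(start(gr) >= 1))
        expect_true(all(end(gr) <= lens[as.character(seqnames(gr))]))
    }
    w <- width(tgt)
    expect_true(all(w >= 500 & w <= 3500))
})

test_that("infeasible enhancer demands raise a configuration error", {
    cfg <- simulationConfig(n_chroms = 1L, chrom_length = 1e5,
                            n_target_enhancers = 100L,
                            n_other_enhancers = 100L)
    expect_error(simulateStudy(cfg), "configuration error")
})

test_that("cross-species degradation drops, jitters and preserves identity limits", {
    genome <- Seqinfo("chr1", 1e7)
    set.seed(64)
    regions <- GRanges("chr1",
                       IRanges(sample.int(9e6, 500), width = 1000),
                       seqinfo = genome)
    names(regions) <- paste0("r", 1:500)
    # identity limit
    same <- degradeCrossSpecies(regions, unmappable_frac = 0,
                                map_jitter_sd = 0, seed = 1)
    expect_identical(granges(same), granges(regions))
    # total loss
    none <- degradeCrossSpecies(regions, unmappable_frac = 1, seed = 1)
    expect_length(none, 0L)
    # jitter moves coordinates but keeps widths and stays in bounds
    jit <- degradeCrossSpecies(regions, unmappable_frac = 0,
                               map_jitter_sd = 300, seed = 2)
    expect_length(jit, 500L)
    expect_equal(width(jit), width(regions))
    expect_true(any(start(jit) != start(regions)))
    expect_true(all(start(jit) >= 1 & end(jit) <= 1e7))
})

test_that("the retained fraction under degradation is binomial around 77%", {
    genome <- Seqinfo("chr1", 5e8)
    set.seed(65)
    regions <- GRanges("chr1", IRanges(sample.int(4.9e8, 10000),
                                       width = 500), seqinfo = genome)
    kept <- degradeCrossSpecies(regions, unmappable_frac = 0.23,
                                map_jitter_sd = 0, seed = 3)
    se <- sqrt(0.23 * 0.77 * 10000)
    expect_lt(abs(length(kept) - 7700), 3 * se)
})

test_that("export/import round-trips a study exactly and deterministically", {
    cfg <- smallStudyConfig(seed = 66L)
    st <- simulateStudy(cfg)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    man_path <- exportStudy(st, d1)
    expect_true(file.exists(man_path))
    man <- read.delim(man_path)
    expect_equal(nrow(man), length(peakSets(st)))
    expect_equal(colnames(man), c("dataset_id", "tissue", "stage_coord",
                                  "species", "mark", "path"))
    back <- importStudy(d1)
    expect_equal(granges(targetEnhancers(back)),
                 granges(targetEnhancers(st)))
    expect_equal(names(targetEnhancers(back)), names(targetEnhancers(st)))
    expect_equal(mcols(otherEnhancers(back))$tissue,
                 mcols(otherEnhancers(st))$tissue)
    expect_equal(mcols(otherEnhancers(back))$ubiquitous,
                 mcols(otherEnhancers(st))$ubiquitous)
    for (id in names(peakSets(st)))
        expect_equal(granges(peakSets(back)[[id]]),
                     granges(peakSets(st)[[id]]), label = id)
    expect_equal(as.data.frame(studyManifest(back)),
                 as.data.frame(studyManifest(st)))
    # identical config + seed => byte-identical export
    exportStudy(simulateStudy(cfg), d2)
    for (f in list.files(d1, recursive = TRUE))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
})

test_that("an empty peak set still exports as a listed zero-length BED", {
    cfg <- simulationConfig(n_chroms = 1L, chrom_length = 2e6,
                            n_target_enhancers = 20L,
                            n_other_enhancers = 20L, p_bg = 0,
                            shared_frac = 0, p_max = 0.9, lam = 10,
                            seed = 67L)
    st <- simulateStudy(cfg)
    # with this decay the most distal context has marking probability
    # ~1e-22 and p_bg = 0, so its peak set is empty
    n_peaks <- vapply(as.list(peakSets(st)), length, integer(1))
    expect_equal(min(n_peaks), 0L)
    d <- withr::local_tempdir()
    man <- read.delim(exportStudy(st, d))
    empty_id <- names(n_peaks)[which.min(n_peaks)][1]
    expect_true(empty_id %in% man$dataset_id)
    f <- file.path(d, man$path[man$dataset_id == empty_id])
    expect_true(file.exists(f))
    expect_length(readLines(f), 0L)
})
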