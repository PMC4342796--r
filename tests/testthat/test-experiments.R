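# Orchestration tests run on a reduced study (2 chromosomes x 4 Mb,
# 120 + 120 enhancers) so the whole file stays fast; the full-size
# structure-recovery checks live in the acceptance suite.

smallStudy <- simulateStudy(smallStudyConfig(seed = 71L))

test_that("scenario negatives follow the requested negative mode", {
    neg_bg <- crossmark:::scenarioNegatives(smallStudy,
                                            targetEnhancers(smallStudy),
                                            "genomic_background", 10L, 5L)
    expect_length(neg_bg, 10L * length(targetEnhancers(smallStudy)))
    expect_false(any(hasOverlap(neg_bg, targetEnhancers(smallStudy))))
    expect_false(any(hasOverlap(neg_bg, otherEnhancers(smallStudy))))
    neg_oe <- crossmark:::scenarioNegatives(smallStudy,
                                            targetEnhancers(smallStudy),
                                            "other_enhancers", 10L, 5L)
    expect_equal(granges(neg_oe),
                 granges(otherEnhancers(smallStudy), use.names = TRUE))
})

test_that("a lineage-features scenario recovers the target enhancers", {
    rep <- runScenario(smallStudy, featuresTissue("heart"),
                       "genomic_background", masterSeed = 3L,
                       name = "unit_stage_bg")
    expect_s4_class(rep, "CVReport")
    expect_gt(meanAUC(rep), 0.9)
    imp <- importanceTable(rep)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_setequal(names(imp),
                    studyManifest(smallStudy)$dataset_id[
                        studyManifest(smallStudy)$tissue == "heart"])
})

test_that("scenario results are deterministic in the master seed and named", {
    a <- runScenario(smallStudy, featuresTissue("heart"),
                     "genomic_background", masterSeed = 4L, name = "s")
    b <- runScenario(smallStudy, featuresTissue("heart"),
                     "genomic_background", masterSeed = 4L, name = "s")
    expect_identical(foldAUC(a), foldAUC(b))
    expect_identical(importanceTable(a), importanceTable(b))
    other_name <- runScenario(smallStudy, featuresTissue("heart"),
                              "genomic_background", masterSeed = 4L,
                              name = "different")
    expect_false(identical(foldAUC(a), foldAUC(other_name)))
})

test_that("the classifier sweep runs all six algorithms on shared folds", {
    sweep <- runClassifierSweep(smallStudy, featuresTissue("heart"),
                                "genomic_background", masterSeed = 5L)
    expect_equal(sort(sweep$algorithm), sort(ALGORITHMS))
    expect_true(all(sweep$mean_auc > 0.5))
    sweep2 <- runClassifierSweep(smallStudy, featuresTissue("heart"),
                                 "genomic_background", masterSeed = 5L)
    expect_identical(sweep, sweep2)
})

test_that("a duplicated context is predicted perfectly in mark leave-out", {
    # duplicate one lineage dataset under a new id: features then contain
    # an exact copy of the held-out positives
    st <- smallStudy
    man <- as.data.frame(studyManifest(st))
    dup <- man[man$dataset_id == "heart_s4_H3K27ac", ]
    dup$dataset_id <- "heart_s4_H3K27ac_copy"
    man2 <- rbind(man, dup)
    pk2 <- as.list(peakSets(st))
    pk2[["heart_s4_H3K27ac_copy"]] <- pk2[["heart_s4_H3K27ac"]]
    st2 <- new("SyntheticStudy", genome = studyGenome(st),
               targetEnhancers = targetEnhancers(st),
               otherEnhancers = otherEnhancers(st),
               peakSets = S4Vectors::SimpleList(pk2),
               manifest = S4Vectors::DataFrame(man2), config = st@config)
    res <- runMarkLeaveout(st2, masterSeed = 6L)
    auc_dup <- res$mean_auc[res$dataset_id == "heart_s4_H3K27ac"]
    expect_gt(auc_dup, 0.99)
})

test_that("a pure-noise context is at chance in mark leave-out", {
    st <- smallStudy
    man <- as.data.frame(studyManifest(st))
    noise <- man[1, ]
    noise$dataset_id <- "heart_s99_H3K27ac"
    noise$stage_coord <- 99
    man2 <- rbind(man, noise)
    pk2 <- as.list(peakSets(st))
    pk2[["heart_s99_H3K27ac"]] <- crossmark:::withSeed(99L,
        crossmark:::spuriousPeaks(10, c(500L, 2000L), studyGenome(st)))
    st2 <- new("SyntheticStudy", genome = studyGenome(st),
               targetEnhancers = targetEnhancers(st),
               otherEnhancers = otherEnhancers(st),
               peakSets = S4Vectors::SimpleList(pk2),
               manifest = S4Vectors::DataFrame(man2), config = st@config)
    res <- runMarkLeaveout(st2, masterSeed = 7L)
    auc_noise <- res$mean_auc[res$dataset_id == "heart_s99_H3K27ac"]
    expect_gt(auc_noise, 0.4)
    expect_lt(auc_noise, 0.6)
})
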