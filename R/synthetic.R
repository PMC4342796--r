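#' Configuration for the synthetic cross-context study generator
#'
#' Returns the generator configuration as a validated named list.  The
#' defaults define the reference study used throughout the package's tests
#' and examples: a 4 x 10 Mb genome; 300 target-context ("heart", stage 5)
#' true enhancers and 300 other-tissue enhancers (3 tissues x 100); a
#' developmental lineage assayed at stages 0, 2, 4, 6, 8, 10 for both
#' H3K4me1 and H3K27ac; marking probability decaying exponentially with
#' developmental distance d from the target as `p(d) = pMax * exp(-lam*d)`;
#' a background rate of spurious peaks per Mb; a fraction of other-tissue
#' enhancers that are ubiquitously marked in every context (the
#' tissue-specificity confound); and a cross-species degradation model in
#' which 23% of regions fail to map and mapped coordinates are jittered.
#'
#' @param n_chroms,chrom_length genome shape (chromosome count, bp each).
#' @param n_target_enhancers,n_other_enhancers enhancer counts; other
#'   enhancers are split evenly across `tissue_names`.
#' @param enhancer_length_range uniform range of enhancer lengths (bp).
#' @param target_stage developmental coordinate of the target context.
#' @param stage_coords coordinates of the assayed lineage contexts.
#' @param tissue_names non-target tissues.
#' @param p_max marking probability at zero developmental distance.
#' @param lam exponential decay rate per unit developmental distance.
#' @param p_bg expected spurious peaks per Mb per context.
#' @param shared_frac fraction of other-tissue enhancers ubiquitously
#'   marked in every context; also the relative rate at which non-target
#'   contexts mark target enhancers.
#' @param unmappable_frac fraction of regions dropped as unmappable in the
#'   cross-species scenario.
#' @param map_jitter_sd bp standard deviation of the coordinate
#'   perturbation applied to mapped regions.
#' @param peak_width_range uniform range of peak widths (bp).
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return named list of class-checked generator parameters.
#' @seealso [simulateStudy()]
#' @export
simulationConfig <- function(n_chroms = 4L, chrom_length = 1e7,
                             n_target_enhancers = 300L,
                             n_other_enhancers = 300L,
                             enhancer_length_range = c(500L, 3500L),
                             target_stage = 5,
                             stage_coords = c(0, 2, 4, 6, 8, 10),
                             tissue_names = c("limb", "brain", "liver"),
                             p_max = 0.9, lam = 0.35, p_bg = 5,
                             shared_frac = 0.2, unmappable_frac = 0.23,
                             map_jitter_sd = 300,
                             peak_width_range = c(500L, 2000L),
                             seed = 1L) {
    cfg <- list(n_chroms = as.integer(n_chroms),
                chrom_length = chrom_length,
                n_target_enhancers = as.integer(n_target_enhancers),
                n_other_enhancers = as.integer(n_other_enhancers),
                enhancer_length_range = enhancer_length_range,
                target_stage = target_stage,
                stage_coords = stage_coords,
                tissue_names = tissue_names,
                p_max = p_max, lam = lam, p_bg = p_bg,
                shared_frac = shared_frac,
                unmappable_frac = unmappable_frac,
                map_jitter_sd = map_jitter_sd,
                peak_width_range = peak_width_range,
                seed = as.integer(seed))
    stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0,
              cfg$n_target_enhancers >= 0L, cfg$n_other_enhancers >= 0L,
              length(cfg$enhancer_length_range) == 2L,
              cfg$enhancer_length_range[1L] > 0,
              diff(cfg$enhancer_length_range) >= 0,
              length(cfg$peak_width_range) == 2L,
              cfg$peak_width_range[1L] > 0,
              diff(cfg$peak_width_range) >= 0,
              cfg$p_max > 0, cfg$p_max <= 1, cfg$lam >= 0, cfg$p_bg >= 0,
              cfg$shared_frac >= 0, cfg$shared_frac <= 1,
              cfg$unmappable_frac >= 0, cfg$unmappable_frac <= 1,
              cfg$map_jitter_sd >= 0)
    cfg
}

#' Simulate a complete cross-context study
#'
#' Generates a genome, non-overlapping true enhancers, and one peak set per
#' (context, mark) pair:
#'
#' * Enhancers are placed uniformly without overlap, lengths uniform in
#'   `enhancer_length_range`; the first `n_target_enhancers` are the target
#'   context's true enhancers, the rest are split across `tissue_names`,
#'   with a fraction `shared_frac` flagged as ubiquitously active.
#' * Each lineage ("heart") context at stage s covers each target enhancer
#'   with a peak with probability `p(d) = p_max * exp(-lam * d)`,
#'   `d = |s - target_stage|`; peak widths are uniform in
#'   `peak_width_range` and placed with uniform jitter keeping >= 1 bp
#'   overlap.  Draws are independent per (context, mark, enhancer).
#' * Each non-target tissue context marks its own tissue's enhancers with
#'   probability `p_max` and target enhancers with probability
#'   `p_max * shared_frac`; ubiquitous enhancers are marked with
#'   probability `p_max` in every context, lineage contexts included.
#' * Every context additionally receives `Poisson(p_bg x genome Mb)`
#'   spurious peaks placed uniformly; these may overlap enhancers by chance
#'   and are deliberately not rejected.
#'
#' Generation is fully deterministic given the configuration (including its
#' seed).
#'
#' @param config a [simulationConfig()].
#' @return a [SyntheticStudy-class].
#' @export
simulateStudy <- function(config = simulationConfig()) {
    genome <- Seqinfo(paste0("chr", seq_len(config$n_chroms)),
                      rep(config$chrom_length, config$n_chroms))
    n_total <- config$n_target_enhancers + config$n_other_enhancers
    total_bp <- sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
    if (n_total * config$enhancer_length_range[2L] > total_bp)
        stop("configuration error: requested enhancer bp exceeds genome capacity")
    marks <- c("H3K4me1", "H3K27ac")
    withSeed(config$seed, {
        enh <- placeNonOverlapping(n_total, config$enhancer_length_range,
                                   genome)
        # placement order is random, so the first n_target form an unbiased
        # target set; each set is then stored in canonical sorted order
        n_t <- config$n_target_enhancers
        target <- sortRegions(enh[seq_len(n_t)])
        names(target) <- sprintf("target_%d", seq_len(n_t))
        other <- sortRegions(enh[seq_len(length(enh) - n_t) + n_t])
        tissues <- rep(config$tissue_names,
                       length.out = config$n_other_enhancers)
        S4Vectors::mcols(other)$tissue <- tissues
        n_ub <- round(config$shared_frac * config$n_other_enhancers)
        ub <- logical(config$n_other_enhancers)
        ub[order(stats::runif(config$n_other_enhancers))[seq_len(n_ub)]] <-
            TRUE
        S4Vectors::mcols(other)$ubiquitous <- ub
        names(other) <- sprintf("%s_other_%d", tissues,
                                seq_len(config$n_other_enhancers))

        manifest <- rbind(
            expand.grid(tissue = "heart", stage_coord = config$stage_coords,
                        mark = marks, stringsAsFactors = FALSE),
            expand.grid(tissue = config$tissue_names,
                        stage_coord = config$target_stage, mark = marks,
                        stringsAsFactors = FALSE))
        manifest$species <- "mouse"
        manifest$dataset_id <- ifelse(
            manifest$tissue == "heart",
            sprintf("heart_s%s_%s",
                    gsub("[.]", "p", as.character(manifest$stage_coord)),
                    manifest$mark),
            sprintf("%s_%s", manifest$tissue, manifest$mark))
        manifest <- manifest[, c("dataset_id", "tissue", "stage_coord",
                                 "species", "mark")]

        peak_sets <- lapply(seq_len(nrow(manifest)), function(i) {
            ctx <- manifest[i, ]
            if (ctx$tissue == "heart") {
                d <- abs(ctx$stage_coord - config$target_stage)
                p_t <- config$p_max * exp(-config$lam * d)
                marked <- c(
                    target[stats::runif(length(target)) < p_t],
                    other[ub & stats::runif(length(other)) < config$p_max])
            } else {
                own <- S4Vectors::mcols(other)$tissue == ctx$tissue
                hit <- stats::runif(length(other)) <
                    config$p_max
                keep_other <- (own | ub) & hit
                marked <- c(
                    target[stats::runif(length(target)) <
                               config$p_max * config$shared_frac],
                    other[keep_other])
            }
            peaks <- c(coverPeaks(marked, config$peak_width_range, genome),
                       spuriousPeaks(config$p_bg, config$peak_width_range,
                                     genome))
            peaks <- sortRegions(peaks)
            names(peaks) <- sprintf("%s_peak%d", manifest$dataset_id[i],
                                    seq_along(peaks))
            peaks
        })
        names(peak_sets) <- manifest$dataset_id
        new("SyntheticStudy", genome = genome,
            targetEnhancers = GenomicRanges::granges(target,
                                                     use.names = TRUE),
            otherEnhancers = other,
            peakSets = S4Vectors::SimpleList(peak_sets),
            manifest = DataFrame(manifest), config = config)
    })
}

# Uniform non-overlapping placement by rejection against accepted regions.
placeNonOverlapping <- function(n, length_range, genome, max_rounds = 200L) {
    lens <- GenomeInfoDb::seqlengths(genome)
    accepted <- GRanges(seqinfo = genome)
    for (round in seq_len(max_rounds)) {
        need <- n - length(accepted)
        if (need == 0L) break
        w <- runifInt(need, length_range[1L], length_range[2L])
        chrom <- names(lens)[
            findInterval(stats::runif(need) * sum(as.numeric(lens)),
                         cumsum(as.numeric(lens))) + 1L]
        s <- runifInt(need, 1L, lens[chrom] - w + 1L)
        cand <- GRanges(chrom, IRanges::IRanges(s, width = w),
                        seqinfo = genome)
        # reject candidates clashing with accepted or earlier candidates
        ok <- !hasOverlap(cand, accepted)
        self <- GenomicRanges::findOverlaps(cand, cand,
                                            ignore.strand = TRUE)
        clash <- S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)
        ok[unique(S4Vectors::queryHits(self)[clash])] <- FALSE
        accepted <- c(accepted, cand[ok])
    }
    if (length(accepted) < n)
        stop("configuration error: could not place enhancers without overlap")
    accepted
}

# A covering peak for each marked region: width uniform in width_range,
# start uniform over placements sharing >= 1 bp with the region, clipped to
# chromosome bounds (clipping moves the peak toward the region, so the
# overlap guarantee is preserved).
coverPeaks <- function(marked, width_range, genome) {
    n <- length(marked)
    if (n == 0L) return(GRanges(seqinfo = genome))
    lens <- GenomeInfoDb::seqlengths(genome)
    w <- runifInt(n, width_range[1L], width_range[2L])
    lo <- GenomicRanges::start(marked) - w + 1L
    hi <- GenomicRanges::end(marked)
    s <- runifInt(n, pmax(lo, 1L), hi)
    chrom <- as.character(GenomeInfoDb::seqnames(marked))
    s <- pmin(s, lens[chrom] - w + 1L)
    GRanges(chrom, IRanges::IRanges(s, width = w), seqinfo = genome)
}

# Uniformly placed spurious peaks at an expected density per Mb.
spuriousPeaks <- function(p_bg, width_range, genome) {
    lens <- GenomeInfoDb::seqlengths(genome)
    total_mb <- sum(as.numeric(lens)) / 1e6
    n <- stats::rpois(1L, p_bg * total_mb)
    if (n == 0L) return(GRanges(seqinfo = genome))
    w <- runifInt(n, width_range[1L], width_range[2L])
    chrom <- names(lens)[
        findInterval(stats::runif(n) * sum(as.numeric(lens)),
                     cumsum(as.numeric(lens))) + 1L]
    s <- runifInt(n, 1L, lens[chrom] - w + 1L)
    GRanges(chrom, IRanges::IRanges(s, width = w), seqinfo = genome)
}

#' Emulate cross-species coordinate mapping degradation
#'
#' Models what mapping regions to another species' genome through
#' whole-genome alignment does to a region set: each region is
#' independently dropped as unmappable with probability `unmappable_frac`
#' (default 0.23, the fraction of validated human heart enhancers that do
#' not reliably map to mouse), and surviving regions are shifted by a
#' Normal(0, `map_jitter_sd`) offset rounded to whole bp and clipped to
#' chromosome bounds.
#'
#' @param regions GRanges to degrade.
#' @param unmappable_frac drop probability per region.
#' @param map_jitter_sd bp standard deviation of the coordinate shift.
#' @param genome optional Seqinfo for bounds clipping (defaults to the
#'   regions' own seqinfo when it has lengths).
#' @param seed integer seed.
#' @return GRanges of surviving, jittered regions (names preserved).
#' @export
degradeCrossSpecies <- function(regions, unmappable_frac = 0.23,
                                map_jitter_sd = 300, genome = NULL,
                                seed = 1L) {
    if (is.null(genome)) genome <- GenomeInfoDb::seqinfo(regions)
    withSeed(seed, {
        keep <- stats::runif(length(regions)) >= unmappable_frac
        out <- regions[keep]
        if (length(out) && map_jitter_sd > 0) {
            delta <- round(stats::rnorm(length(out), 0, map_jitter_sd))
            lens <- GenomeInfoDb::seqlengths(genome)[
                as.character(GenomeInfoDb::seqnames(out))]
            w <- GenomicRanges::width(out)
            s <- GenomicRanges::start(out) + delta
            if (!any(is.na(lens))) s <- pmin(pmax(s, 1), lens - w + 1)
            nm <- names(out)
            GenomicRanges::ranges(out) <- IRanges::IRanges(s, width = w)
            names(out) <- nm
        }
        out
    })
}

#' Export a synthetic study to a directory of plain-text files
#'
#' Writes one BED file per peak set (under `peaks/`), the target enhancer
#' BED, one BED per other-enhancer tissue, a `chrom.sizes` table, the
#' dataset manifest as TSV (columns `dataset_id`, `tissue`, `stage_coord`,
#' `species`, `mark`, `path`), and `study.json` holding the generator
#' configuration and the ubiquitous-enhancer flags.  [importStudy()] on the
#' directory reproduces the study exactly.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return path to the manifest TSV, invisibly.
#' @export
exportStudy <- function(study, dir) {
    dir.create(file.path(dir, "peaks"), recursive = TRUE,
               showWarnings = FALSE)
    writeChromSizes(study@genome, file.path(dir, "chrom.sizes"))
    writeBed(study@targetEnhancers, file.path(dir, "target_enhancers.bed"))
    other <- study@otherEnhancers
    for (tis in unique(S4Vectors::mcols(other)$tissue))
        writeBed(other[S4Vectors::mcols(other)$tissue == tis],
                 file.path(dir, sprintf("other_%s.bed", tis)))
    man <- as.data.frame(study@manifest)
    man$path <- file.path("peaks", paste0(man$dataset_id, ".bed"))
    for (i in seq_len(nrow(man)))
        writeBed(study@peakSets[[man$dataset_id[i]]],
                 file.path(dir, man$path[i]))
    man_path <- file.path(dir, "manifest.tsv")
    utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(config = study@config,
             ubiquitous = names(other)[S4Vectors::mcols(other)$ubiquitous]),
        file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(man_path)
}

#' Import a synthetic study exported with [exportStudy()]
#'
#' @param dir directory written by [exportStudy()].
#' @return a [SyntheticStudy-class] equal to the exported one.
#' @export
importStudy <- function(dir) {
    genome <- readChromSizes(file.path(dir, "chrom.sizes"))
    meta <- jsonlite::read_json(file.path(dir, "study.json"),
                                simplifyVector = TRUE)
    config <- meta$config
    config$seed <- as.integer(config$seed)
    target <- readBed(file.path(dir, "target_enhancers.bed"), genome)
    tissues <- config$tissue_names
    other <- GRanges(seqinfo = genome)
    for (tis in tissues) {
        gr <- readBed(file.path(dir, sprintf("other_%s.bed", tis)), genome)
        S4Vectors::mcols(gr)$tissue <- rep(tis, length(gr))
        other <- c(other, gr)
    }
    # restore original (generation) order encoded in the region names
    ord <- order(as.integer(sub(".*_other_", "", names(other))))
    other <- other[ord]
    S4Vectors::mcols(other)$ubiquitous <-
        names(other) %in% meta$ubiquitous
    man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    peak_sets <- lapply(seq_len(nrow(man)), function(i)
        readBed(file.path(dir, man$path[i]), genome))
    names(peak_sets) <- man$dataset_id
    new("SyntheticStudy", genome = genome, targetEnhancers = target,
        otherEnhancers = other,
        peakSets = S4Vectors::SimpleList(peak_sets),
        manifest = DataFrame(man[, c("dataset_id", "tissue", "stage_coord",
                                     "species", "mark")]),
        config = config)
}

#' @rdname crossmark-accessors
#' @export
setMethod("peakSets", "SyntheticStudy", function(x) x@peakSets)

#' @rdname crossmark-accessors
#' @export
setMethod("targetEnhancers", "SyntheticStudy", function(x)
    x@targetEnhancers)

#' @rdname crossmark-accessors
#' @export
setMethod("otherEnhancers", "SyntheticStudy", function(x) x@otherEnhancers)

#' @rdname crossmark-accessors
#' @export
setMethod("studyGenome", "SyntheticStudy", function(x) x@genome)

#' @rdname crossmark-accessors
#' @export
setMethod("studyManifest", "SyntheticStudy", function(x) x@manifest)

setMethod("show", "SyntheticStudy", function(object) {
    cat(sprintf(
        "SyntheticStudy: %d chromosomes, %d target + %d other enhancers, %d peak sets\n",
        length(GenomeInfoDb::seqnames(object@genome)),
        length(object@targetEnhancers), length(object@otherEnhancers),
        length(object@peakSets)))
    cat(sprintf("lineage stages: %s (target %s); tissues: %s\n",
                paste(object@config$stage_coords, collapse = ", "),
                object@config$target_stage,
                paste(object@config$tissue_names, collapse = ", ")))
})
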