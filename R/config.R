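#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline in one place,
#' seeded and serialisable. Defaults follow the deep-sea sponge ground
#' study design: samples with fewer than 5000 reads are discarded,
#' rarefaction depth is 5000, "core" membership requires occurrence in more
#' than 70% of sponge samples, "exclusive" ASVs require within-group
#' prevalence above 90%, sea paths are constrained below 200 m water depth,
#' taxa entering driver models must occur in more than 10 samples of a
#' sponge type, and module membership (kME) is called at 0.8.
#'
#' @param core_fraction core occupancy fraction, strict ("more than").
#' @param exclusive_prevalence within-group prevalence bound, strict.
#' @param rarefaction_depth reads per sample after rarefying.
#' @param min_reads minimum library size; samples with fewer reads dropped.
#' @param depth_threshold_m minimum water depth (m) for navigable sea cells.
#' @param clustering_thresholds sequence identity thresholds, descending.
#' @param min_occurrence_per_type occurrence floor for driver analyses.
#' @param kme_threshold module-membership correlation threshold.
#' @param vif_threshold variance inflation factor cutoff for predictor pruning.
#' @param n_permutations permutations for all permutation tests.
#' @param seed integer seed consumed by every randomised stage.
#' @param alpha significance level.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(core_fraction = 0.7,
                            exclusive_prevalence = 0.9,
                            rarefaction_depth = 5000,
                            min_reads = 5000,
                            depth_threshold_m = 200,
                            clustering_thresholds = c(1.00, 0.99, 0.97, 0.95, 0.90),
                            min_occurrence_per_type = 10,
                            kme_threshold = 0.8,
                            vif_threshold = 10,
                            n_permutations = 999,
                            seed = 1L,
                            alpha = 0.05) {
  stopifnot(core_fraction > 0, core_fraction <= 1,
            exclusive_prevalence > 0, exclusive_prevalence <= 1,
            rarefaction_depth >= 1, min_reads >= 0,
            n_permutations >= 99, alpha > 0, alpha < 1)
  if (is.unsorted(rev(clustering_thresholds), strictly = FALSE))
    stop("clustering_thresholds must be sorted in descending order")
  structure(list(core_fraction = core_fraction,
                 exclusive_prevalence = exclusive_prevalence,
                 rarefaction_depth = rarefaction_depth,
                 min_reads = min_reads,
                 depth_threshold_m = depth_threshold_m,
                 clustering_thresholds = clustering_thresholds,
                 min_occurrence_per_type = min_occurrence_per_type,
                 kme_threshold = kme_threshold,
                 vif_threshold = vif_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 alpha = alpha),
            class = "analysis_config")
}

#' Core/variable/individual occurrence boundaries
#'
#' Occurrence-count boundaries that partition features into the individual
#' (exactly one sample), variable, and core (strictly more than
#' `core_fraction` of samples) categories. With 931 sponge samples and the
#' 70% rule the core boundary is 652 occurrences and the variable range is
#' 2-651.
#'
#' @param n_samples number of (sponge) samples the occupancy refers to.
#' @param core_fraction strict core fraction, default 0.7.
#' @return list with `individual`, `variable_min`, `variable_max`,
#'   `core_min` occurrence counts.
#' @export
membership_boundaries <- function(n_samples, core_fraction = 0.7) {
  stopifnot(n_samples >= 1, core_fraction > 0, core_fraction <= 1)
  core_min <- floor(core_fraction * n_samples) + 1
  list(individual = 1L,
       variable_min = 2L,
       variable_max = as.integer(core_min - 1L),
       core_min = as.integer(core_min))
}
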