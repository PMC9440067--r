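host_rank_column <- function(rank) {
  ranks <- c(species = "host_species", genus = "host_genus",
             family = "host_family", order = "host_order",
             class = "host_class")
  if (!rank %in% names(ranks)) stop("rank must be one of ",
                                    paste(names(ranks), collapse = ", "))
  ranks[[rank]]
}

#' Host-specific ASVs at a host taxonomic rank
#'
#' An ASV is specific to a group (e.g. one host species at the species
#' rank) when it is present in at least one sponge sample of that group,
#' absent from every other group at the rank, and absent from all seawater
#' and sediment reference samples. ASVs occurring in exactly one sample
#' overall (the "individual" fraction) are removed first unless
#' `exclude_individual = FALSE`.
#'
#' @param table count matrix (sponge + reference samples).
#' @param metadata matching metadata with `sample_type` and host rank
#'   columns (`host_species` ... `host_class`).
#' @param rank one of species/genus/family/order/class.
#' @param exclude_individual drop single-occurrence ASVs first? Default TRUE.
#' @return list(rank, specific: group -> character vector of ASVs,
#'   group_sample_count, single_sample_groups, n_candidate_asvs).
#' @export
host_specific_asvs <- function(table, metadata, rank,
                               exclude_individual = TRUE) {
  col <- host_rank_column(rank)
  if (!col %in% names(metadata)) stop("metadata lacks column '", col, "'")
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  if (!any(sponge)) stop("no sponge samples")
  pres <- table > 0
  keep <- rep(TRUE, nrow(pres))
  if (exclude_individual)
    keep <- rowSums(pres[, sponge, drop = FALSE]) != 1
  in_ref <- rowSums(pres[, !sponge, drop = FALSE]) > 0
  groups <- md[[col]][sponge]
  glev <- sort(unique(groups))
  occ <- sapply(glev, function(g)
    rowSums(pres[, sponge, drop = FALSE][, groups == g, drop = FALSE]) > 0)
  n_groups_present <- rowSums(occ)
  specific <- lapply(glev, function(g)
    rownames(table)[keep & !in_ref & n_groups_present == 1 & occ[, g]])
  names(specific) <- glev
  counts <- table(groups)[glev]
  list(rank = rank,
       specific = specific,
       group_sample_count = setNames(as.integer(counts), glev),
       single_sample_groups = glev[counts == 1],
       n_candidate_asvs = sum(keep))
}

#' Exclusive ASVs: specific ASVs with high within-group prevalence
#'
#' Exclusive ASVs are the subset of a rank's specific ASVs whose prevalence
#' within their group is strictly greater than `prevalence_threshold`
#' (">90% of all samples per group").
#'
#' @param specificity result of [host_specific_asvs()].
#' @param table,metadata as for [host_specific_asvs()].
#' @param prevalence_threshold default 0.9, strict.
#' @return the specificity list extended with `exclusive` (group -> ASVs)
#'   and `prevalence` (group -> named prevalence vector of its specific ASVs).
#' @export
exclusive_asvs <- function(specificity, table, metadata,
                           prevalence_threshold = 0.9) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold <= 1)
  col <- host_rank_column(specificity$rank)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  groups <- md[[col]][sponge]
  pres <- table[, sponge, drop = FALSE] > 0
  exclusive <- list(); prevalence <- list()
  for (g in names(specificity$specific)) {
    gs <- which(groups == g)
    if (length(gs) == 0) { warning("group '", g, "' has no samples; skipped"); next }
    asvs <- specificity$specific[[g]]
    prev <- if (length(asvs))
      rowSums(pres[asvs, gs, drop = FALSE]) / length(gs) else numeric(0)
    names(prev) <- asvs
    prevalence[[g]] <- prev
    exclusive[[g]] <- asvs[prev > prevalence_threshold]
  }
  specificity$exclusive <- exclusive
  specificity$prevalence <- prevalence
  specificity
}

#' Per-rank specificity summary
#'
#' Groups owning specific ASVs and the median fraction of each group's ASV
#' pool that is specific (the per-rank percentage shown alongside
#' host-richness alluvials).
#'
#' @param specificity result of [host_specific_asvs()] (optionally after
#'   [exclusive_asvs()]).
#' @param table,metadata as above.
#' @return list(groups_with_specific, n_groups, median_specific_fraction
#'   (percent), per_group: data.frame).
#' @export
specificity_summary <- function(specificity, table, metadata) {
  col <- host_rank_column(specificity$rank)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  groups <- md[[col]][sponge]
  pres <- table[, sponge, drop = FALSE] > 0
  per <- do.call(rbind, lapply(names(specificity$specific), function(g) {
    pool <- sum(rowSums(pres[, groups == g, drop = FALSE]) > 0)
    nsp <- length(specificity$specific[[g]])
    data.frame(group = g, pool_size = pool, n_specific = nsp,
               specific_fraction_pct = if (pool > 0) 100 * nsp / pool else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(groups_with_specific = sum(per$n_specific > 0),
       n_groups = nrow(per),
       median_specific_fraction = stats::median(per$specific_fraction_pct,
                                                na.rm = TRUE),
       per_group = per)
}

#' Fraction of each sponge type's ASV pool that is host species-specific
#'
#' For each sponge type: the number of species-specific ASVs across the
#' type's species divided by the number of ASVs occurring in that type, as
#' a percentage.
#'
#' @param specificity species-rank result of [host_specific_asvs()].
#' @param table,metadata as above (metadata needs `sponge_type`).
#' @return named numeric vector, percent per sponge type.
#' @export
specific_fraction_by_type <- function(specificity, table, metadata) {
  if (specificity$rank != "species")
    stop("requires the species-rank specificity result")
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  pres <- table[, sponge, drop = FALSE] > 0
  stype <- md$sponge_type[sponge]
  spp <- md$host_species[sponge]
  types <- sort(unique(stype))
  out <- sapply(types, function(t) {
    pool <- sum(rowSums(pres[, stype == t, drop = FALSE]) > 0)
    if (pool == 0) return(NA_real_)
    type_species <- unique(spp[stype == t])
    nspec <- length(unique(unlist(specificity$specific[type_species])))
    100 * nspec / pool
  })
  setNames(out, types)
}
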