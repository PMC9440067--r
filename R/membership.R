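#' Greedy seed-first sequence clustering at an identity threshold
#'
#' CD-HIT-like greedy clustering: sequences are sorted by decreasing length
#' then lexicographically; each query joins the first existing seed whose
#' global-alignment identity (matches / alignment columns, unit match
#' score, linear gap penalty 1) reaches the threshold, otherwise it founds
#' a new cluster. Threshold 1.0 is identity clustering of distinct
#' sequences.
#'
#' @param sequences named character vector of A/C/G/T/N sequences, or a
#'   path to a FASTA file.
#' @param threshold identity fraction in (0, 1].
#' @return named character vector: feature id -> cluster id (the seed's id).
#' @export
cluster_features <- function(sequences, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sequences) == 1 && is.null(names(sequences)) &&
      file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- setNames(as.character(ss), names(ss))
  }
  if (length(sequences) == 0) stop("no sequences to cluster")
  if (is.null(names(sequences))) stop("sequences must be named")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("non-ACGTN characters in: ",
                     paste(names(sequences)[bad], collapse = ", "))
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  seeds <- integer(0)                  # indices into seqs
  assign <- character(length(seqs))
  for (q in seq_along(seqs)) {
    placed <- FALSE
    for (s in seeds) {
      if (seqs[s] == seqs[q]) { assign[q] <- ids[s]; placed <- TRUE; break }
      # identity <= min(len)/max(len): cheap upper bound before aligning
      if (nchar(seqs[q]) / nchar(seqs[s]) < threshold) next
      aln <- Biostrings::pairwiseAlignment(seqs[q], seqs[s], type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 1)
      identity <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      if (identity >= threshold) { assign[q] <- ids[s]; placed <- TRUE; break }
    }
    if (!placed) { seeds <- c(seeds, q); assign[q] <- ids[q] }
  }
  setNames(assign, ids)[names(sequences)]
}

#' Collapse a feature table by a cluster map
#' @param table count matrix. @param cluster_map feature id -> cluster id.
#' @return count matrix over clusters (column sums preserved).
#' @export
collapse_clusters <- function(table, cluster_map) {
  grp <- unname(cluster_map[rownames(table)])
  if (any(is.na(grp))) stop("cluster map does not cover all table features")
  feature_table(rowsum(table, grp))
}

#' Core/variable/individual membership classification
#'
#' On sponge samples only: a unit is "individual" when it occurs in exactly
#' one sample, "core" when it occurs in strictly more than
#' `core_fraction` of the N samples (occurrence >= floor(core_fraction*N)+1),
#' and "variable" otherwise. No relative-abundance threshold is applied.
#'
#' @param table count matrix restricted to sponge samples.
#' @param core_fraction default 0.7.
#' @return data.frame(unit, occurrence, category) plus attributes
#'   `n_samples` and `boundaries`.
#' @export
classify_membership <- function(table, core_fraction = 0.7) {
  if (ncol(table) < 1 || nrow(table) < 1) stop("empty table")
  n <- ncol(table)
  b <- membership_boundaries(n, core_fraction)
  occ <- rowSums(table > 0)
  category <- ifelse(occ >= b$core_min, "core",
                     ifelse(occ == 1, "individual",
                            ifelse(occ == 0, "absent", "variable")))
  out <- data.frame(unit = rownames(table), occurrence = as.integer(occ),
                    category = category, stringsAsFactors = FALSE)
  out <- out[out$category != "absent", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n
  attr(out, "boundaries") <- b
  out
}

#' Membership across sequence clustering thresholds
#'
#' Runs [classify_membership()] on the ASV table and on the table collapsed
#' at each OTU clustering threshold.
#'
#' @param table sponge-sample count matrix.
#' @param sequences named sequences for the table's features.
#' @param thresholds identity thresholds, descending (1.0 = ASV level).
#' @param core_fraction default 0.7.
#' @return named list threshold -> membership data.frame.
#' @export
membership_across_thresholds <- function(table, sequences,
                                         thresholds = c(1.00, 0.99, 0.97, 0.95, 0.90),
                                         core_fraction = 0.7) {
  out <- lapply(thresholds, function(th) {
    cm <- cluster_features(sequences[rownames(table)], th)
    classify_membership(collapse_clusters(table, cm), core_fraction)
  })
  names(out) <- format(thresholds)
  out
}

#' ASV sharing between sample/sponge types
#'
#' Labels every ASV by the set of groups (e.g. HMA, LMA_demo, LMA_glass,
#' seawater, sediment) it occurs in, and summarises the percentage of ASVs
#' found in exactly one group, shared by each pair, and shared by all.
#'
#' @param table count matrix.
#' @param groups named character: sample id -> group (every table sample
#'   must be mapped).
#' @return list(asv_groups: ASV -> "+"-joined group set,
#'   pct_single, pct_all, pairwise: data.frame(group1, group2, pct_shared),
#'   n_asvs).
#' @export
sample_type_sharing <- function(table, groups) {
  unmapped <- setdiff(colnames(table), names(groups))
  if (length(unmapped)) stop("samples without a group: ",
                             paste(utils::head(unmapped), collapse = ", "))
  g <- groups[colnames(table)]
  pres <- table > 0
  zero <- rowSums(pres) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero feature(s) excluded")
    pres <- pres[!zero, , drop = FALSE]
  }
  glev <- sort(unique(g))
  occ <- sapply(glev, function(lv) rowSums(pres[, g == lv, drop = FALSE]) > 0)
  nsets <- rowSums(occ)
  asv_groups <- apply(occ, 1, function(r) paste(glev[r], collapse = "+"))
  pairs <- utils::combn(glev, 2)
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         pct_shared = apply(pairs, 2, function(p)
                           100 * mean(occ[, p[1]] & occ[, p[2]])),
                         stringsAsFactors = FALSE)
  list(asv_groups = asv_groups,
       pct_single = 100 * mean(nsets == 1),
       pct_all = 100 * mean(nsets == length(glev)),
       pairwise = pairwise,
       n_asvs = nrow(occ))
}

#' Abundance-occupancy relationship within a sample group
#'
#' Mean relative abundance (zeros included) against occupancy, with a
#' Spearman rank correlation and permutation p-value.
#'
#' @param table count matrix.
#' @param group_samples sample ids forming the group.
#' @param n_permutations default 999. @param seed RNG seed.
#' @return list(per_feature: data.frame(feature, mean_rel_abundance,
#'   occupancy), rho, p_value).
#' @export
abundance_occupancy <- function(table, group_samples, n_permutations = 999,
                                seed = 1L) {
  if (length(group_samples) == 0) stop("empty group")
  sub <- table[, group_samples, drop = FALSE]
  rel <- sweep(sub, 2, pmax(1, colSums(sub)), "/")
  pf <- data.frame(feature = rownames(sub),
                   mean_rel_abundance = rowMeans(rel),
                   occupancy = as.integer(rowSums(sub > 0)),
                   stringsAsFactors = FALSE)
  pf <- pf[pf$occupancy > 0, , drop = FALSE]
  if (length(group_samples) < 2 || nrow(pf) < 3)
    return(list(per_feature = pf, rho = NA_real_, p_value = NA_real_))
  rho <- stats::cor(rank(pf$mean_rel_abundance), rank(pf$occupancy))
  with_seed(seed, {
    perm <- replicate(n_permutations,
      stats::cor(rank(sample(pf$mean_rel_abundance)), rank(pf$occupancy)))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_permutations)
  })
  list(per_feature = pf, rho = rho, p_value = p)
}
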