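#' Location similarity network (Jaccard) with betweenness centrality
#'
#' Sponge samples are pooled per location into presence vectors; the
#' network is the complete weighted graph over locations with edge length
#' equal to Jaccard distance. Heatmap row order comes from
#' complete-linkage clustering of the Jaccard distances.
#'
#' @param table count matrix. @param metadata matching metadata with
#'   `sample_type` and `location_id`.
#' @return list(similarity, distance (matrices), heatmap_order,
#'   betweenness (named), n_samples_per_location).
#' @export
location_similarity_network <- function(table, metadata) {
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  locs <- sort(unique(md$location_id[sponge]))
  empty <- setdiff(unique(md$location_id), locs)
  if (length(empty))
    warning("location(s) without sponge samples excluded: ",
            paste(empty, collapse = ", "))
  if (length(locs) < 2) stop("need at least 2 locations with sponge samples")
  pres <- sapply(locs, function(l)
    rowSums(table[, sponge & md$location_id == l, drop = FALSE] > 0) > 0)
  n <- length(locs)
  sim <- matrix(1, n, n, dimnames = list(locs, locs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    un <- sum(pres[, i] | pres[, j])
    sim[i, j] <- sim[j, i] <- if (un == 0) 0 else sum(pres[, i] & pres[, j]) / un
  }
  dst <- distance_matrix(1 - sim, locs)
  ord <- cluster_dendrogram(dst, "complete")$leaf_order
  g <- igraph::graph_from_adjacency_matrix(
    pmax(dst, 1e-6), mode = "undirected", weighted = TRUE, diag = FALSE)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$weight)
  list(similarity = sim, distance = dst, heatmap_order = ord,
       betweenness = setNames(btw, locs),
       n_samples_per_location = table(md$location_id[sponge])[locs])
}

#' Within-module degree (Zi) and participation (Pi) of locations
#'
#' Builds the bipartite presence graph between locations and ASVs, takes
#' the weighted location projection (edge weight = number of shared ASVs),
#' finds modules by greedy modularity maximisation, and reports each
#' location's within-module degree z-score and participation coefficient
#' P_i = 1 - sum_s (k_is / k_i)^2.
#'
#' @param table count matrix. @param metadata metadata with
#'   `sample_type`, `location_id`.
#' @return list(modules (named membership), z, participation,
#'   projection (matrix)).
#' @export
bipartite_module_degrees <- function(table, metadata) {
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sponge <- md$sample_type == "sponge"
  locs <- sort(unique(md$location_id[sponge]))
  if (length(locs) < 2) stop("need at least 2 locations")
  pres <- sapply(locs, function(l)
    rowSums(table[, sponge & md$location_id == l, drop = FALSE] > 0) > 0)
  w <- crossprod(pres)                     # shared-ASV counts, locations x locations
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mods <- if (igraph::ecount(g) > 0)
    igraph::membership(igraph::cluster_fast_greedy(g)) else
    setNames(seq_along(locs), locs)
  mods <- setNames(as.integer(mods), locs)
  k_is <- sapply(sort(unique(mods)), function(s)
    rowSums(w[, mods == s, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, ncol = 1, dimnames = list(locs, 1))
  k_i <- rowSums(k_is)
  z <- numeric(length(locs)); names(z) <- locs
  for (s in sort(unique(mods))) {
    idx <- which(mods == s)
    kin <- k_is[idx, s]
    sdv <- stats::sd(kin)
    z[idx] <- if (is.na(sdv) || sdv == 0) 0 else (kin - mean(kin)) / sdv
  }
  p <- 1 - rowSums((k_is / pmax(k_i, 1e-300))^2)
  p[k_i == 0] <- 0
  list(modules = mods, z = z, participation = setNames(p, locs),
       projection = w)
}

pick_soft_power <- function(cors, candidates = c(2, 4, 6, 8, 10, 12),
                            target_r2 = 0.8) {
  for (beta in candidates) {
    k <- rowSums(abs(cors)^beta) - 1
    if (stats::var(k) == 0) next
    # scale-free fit: R^2 of log10 p(k) on log10 k over degree bins
    br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11)))
    if (length(br) < 4) next
    bins <- cut(k, breaks = br, include.lowest = TRUE)
    dk <- tapply(k, bins, mean)
    pk <- as.numeric(table(bins)) / length(k)
    ok <- pk > 0 & dk > 0
    if (sum(ok) < 3) next
    r2 <- summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
    if (r2 >= target_r2) return(beta)
  }
  6
}

#' Weighted correlation network modules with trait associations
#'
#' WGCNA-style unsigned network: adjacency = |Pearson r|^beta (beta the
#' smallest of 2,4,...,12 achieving a scale-free fit R^2 >= 0.8, else 6),
#' topological overlap matrix, average-linkage clustering of 1 - TOM,
#' static tree cut (height 0.75, minimum module size `min_module_size`),
#' module eigenprofiles (first principal component), per-taxon module
#' membership kME, and module-trait Pearson correlations.
#'
#' @param table relative-abundance or count matrix (features x samples),
#'   already filtered to taxa occurring in more than the configured number
#'   of samples.
#' @param traits data.frame/matrix of sample-level traits (e.g. nitrate,
#'   phosphate, silicate, oxygen), rows in table column order.
#' @param beta soft power; "auto" (default) selects by scale-free fit.
#' @param cut_height static tree-cut height on 1 - TOM (default 0.75).
#' @param min_module_size default 10.
#' @param kme_threshold taxa reported per trait-associated module, default 0.8.
#' @return list(modules (taxon -> module id or "unassigned"), kME,
#'   eigenprofiles (samples x modules), module_trait_cor, beta,
#'   hub_taxa (kME > threshold per module)).
#' @export
weighted_correlation_modules <- function(table, traits = NULL, beta = "auto",
                                         cut_height = 0.75,
                                         min_module_size = 10,
                                         kme_threshold = 0.8) {
  x <- t(as.matrix(table))                  # samples x taxa
  keep <- apply(x, 2, stats::sd) > 0
  if (any(!keep)) {
    warning("dropping constant taxon profile(s): ",
            paste(utils::head(colnames(x)[!keep]), collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 20 || nrow(x) < 10)
    stop("need at least 20 taxa and 10 samples")
  cors <- stats::cor(x)
  if (identical(beta, "auto")) beta <- pick_soft_power(cors)
  a <- abs(cors)^beta
  diag(a) <- 0
  k <- colSums(a)
  # topological overlap: (L_ij + a_ij) / (min(k_i,k_j) + 1 - a_ij)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_mod <- names(sizes)[sizes >= min_module_size]
  modules <- ifelse(cl %in% as.integer(keep_mod),
                    paste0("M", match(cl, sort(as.integer(keep_mod)))),
                    "unassigned")
  names(modules) <- colnames(x)
  mod_ids <- sort(setdiff(unique(modules), "unassigned"))
  eig <- sapply(mod_ids, function(m) {
    xm <- scale(x[, modules == m, drop = FALSE])
    e <- stats::prcomp(xm, center = FALSE, scale. = FALSE)$x[, 1]
    if (stats::cor(e, rowMeans(xm)) < 0) e <- -e   # orient along the mean profile
    e
  })
  if (length(mod_ids) == 0) eig <- matrix(numeric(0), nrow = nrow(x), ncol = 0)
  kme <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  for (m in mod_ids)
    kme[modules == m] <- stats::cor(x[, modules == m, drop = FALSE], eig[, m])
  mt <- NULL
  if (!is.null(traits) && length(mod_ids) > 0) {
    tr <- as.matrix(traits)
    mt <- stats::cor(eig, tr)
    dimnames(mt) <- list(mod_ids, colnames(tr))
  }
  hubs <- lapply(mod_ids, function(m)
    names(kme)[!is.na(kme) & modules == m & kme > kme_threshold])
  names(hubs) <- mod_ids
  list(modules = modules, kME = kme, eigenprofiles = eig,
       module_trait_cor = mt, beta = beta, hub_taxa = hubs)
}

#' Indicator taxa by Kruskal-Wallis screen + bootstrap LDA-style effect size
#'
#' Simplified LEfSe-like procedure on a taxon-aggregated relative-abundance
#' table: taxa passing a Kruskal-Wallis screen at `alpha` get a one-vs-rest
#' effect size per group — the bootstrap mean of the absolute difference of
#' class means on the log10 scale — and are assigned to the group where
#' their mean abundance is highest.
#'
#' @param table aggregated count/abundance matrix (taxa x samples).
#' @param groups named or ordered group label per sample.
#' @param alpha screen level, default 0.05.
#' @param n_bootstrap default 30. @param seed RNG seed.
#' @return data.frame(taxon, group, effect_size, kw_p), ranked by effect
#'   size within group.
#' @export
indicator_taxa <- function(table, groups, alpha = 0.05, n_bootstrap = 30,
                           seed = 1L) {
  groups <- as.character(groups)
  stopifnot(ncol(table) == length(groups))
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 3]
  if (length(usable) < length(sizes))
    warning("group(s) with n < 3 excluded: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  sel <- groups %in% usable
  if (length(unique(groups[sel])) < 2) stop("need at least 2 usable groups")
  rel <- sweep(table[, sel, drop = FALSE], 2,
               pmax(colSums(table[, sel, drop = FALSE]), 1), "/")
  g <- groups[sel]
  eps <- 1e-6
  with_seed(seed, {
    rows <- lapply(rownames(rel), function(tx) {
      v <- rel[tx, ]
      if (stats::var(v) == 0) return(NULL)
      kw <- stats::kruskal.test(v, factor(g))$p.value
      if (is.na(kw) || kw > alpha) return(NULL)
      means <- tapply(v, g, mean)
      top <- names(which.max(means))
      es <- mean(replicate(n_bootstrap, {
        idx <- unlist(lapply(unique(g), function(gl)
          sample(which(g == gl), sum(g == gl), replace = TRUE)))
        m1 <- mean(v[idx][g[idx] == top])
        m0 <- mean(v[idx][g[idx] != top])
        abs(log10(m1 + eps) - log10(m0 + eps))
      }))
      data.frame(taxon = tx, group = top, effect_size = es, kw_p = kw,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(taxon = character(0), group = character(0),
                      effect_size = numeric(0), kw_p = numeric(0)))
  out[order(out$group, -out$effect_size), , drop = FALSE]
}
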