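#' Dunn's test of multiple comparisons using rank sums
#'
#' Post-hoc pairwise z tests on the pooled ranks after a Kruskal-Wallis
#' screen, with the tie correction term T = sum(t^3 - t):
#' z_ij = (Rbar_i - Rbar_j) / sqrt[(N(N+1)/12 - T/(12(N-1)))(1/n_i + 1/n_j)].
#' Two-sided p from the standard normal; Benjamini-Hochberg adjustment by
#' default.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length (>= 2 groups).
#' @param p_adjust method for [stats::p.adjust()], default "BH".
#' @return list(kruskal_p, pairwise: data.frame(group1, group2, z,
#'   p_value, adjusted_p)).
#' @export
dunn_test <- function(values, groups, p_adjust = "BH") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least 2 groups")
  N <- length(values)
  if (stats::var(values) == 0)
    stop("all pooled values identical; rank test degenerate")
  r <- rank(values)
  rbar <- tapply(r, groups, mean)[glev]
  n <- tapply(r, groups, length)[glev]
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  kw <- stats::kruskal.test(values, factor(groups))$p.value
  pairs <- utils::combn(glev, 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    z <- (rbar[[i]] - rbar[[j]]) / sqrt(v0 * (1 / n[[i]] + 1 / n[[j]]))
    c(z = z, p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  list(kruskal_p = kw, pairwise = out)
}

permanova_ss <- function(d2, groups) {
  # sums of squares from squared distances (Gower identity):
  # SS_total = sum_{i<j} d2_ij / N ; SS_within = sum over groups of the same
  # quantity restricted to within-group pairs.
  N <- length(groups)
  sst <- sum(d2[lower.tri(d2)]) / N
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  c(sst = sst, ssw = ssw)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance:
#' pseudo-F = (SS_between/(k-1)) / (SS_within/(N-k)) computed from the
#' Gower decomposition of squared distances; p-value by label permutation
#' with the add-one rule. Pairwise mode runs all group pairs and adjusts p
#' by Benjamini-Hochberg.
#'
#' @param dist distance matrix.
#' @param groups group label per sample (matrix order).
#' @param n_permutations default 999. @param seed RNG seed.
#' @param pairwise run all pairwise tests instead of the global one?
#' @return list(statistic, p_value, n_permutations, ...) or, when
#'   `pairwise`, a data.frame of pairwise results with `adjusted_p`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = 1L,
                      pairwise = FALSE) {
  groups <- as.character(groups)
  stopifnot(nrow(dist) == length(groups))
  if (pairwise) {
    glev <- sort(unique(groups))
    sizes <- table(groups)
    usable <- glev[sizes[glev] >= 2]
    if (length(usable) < length(glev))
      warning("group(s) of size 1 skipped in pairwise mode: ",
              paste(setdiff(glev, usable), collapse = ", "))
    pairs <- utils::combn(usable, 2)
    res <- apply(pairs, 2, function(p) {
      idx <- groups %in% p
      r <- permanova(dist[idx, idx, drop = FALSE], groups[idx],
                     n_permutations, seed)
      c(r$statistic, r$p_value)
    })
    out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      pseudo_f = res[1, ], p_value = res[2, ],
                      stringsAsFactors = FALSE)
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
    return(out)
  }
  glev <- unique(groups)
  k <- length(glev)
  if (k < 2) stop("need at least 2 groups")
  N <- length(groups)
  d2 <- dist^2
  fstat <- function(g) {
    ss <- permanova_ss(d2, g)
    ((ss[["sst"]] - ss[["ssw"]]) / (k - 1)) / (ss[["ssw"]] / (N - k))
  }
  f0 <- fstat(groups)
  with_seed(seed, {
    ge <- replicate(n_permutations, fstat(sample(groups)) >= f0 - 1e-12)
  })
  list(statistic = unname(f0),
       p_value = (1 + sum(ge)) / (1 + n_permutations),
       n_permutations = n_permutations,
       groups = sort(glev))
}

#' Mantel permutation test between two distance matrices
#'
#' Correlation (Pearson default, Spearman optional) between the
#' off-diagonal vectors, with a two-sided permutation p-value obtained by
#' simultaneously permuting rows and columns of the second matrix
#' (add-one rule).
#'
#' @param d1,d2 distance matrices with matching ids.
#' @param n_permutations default 999. @param seed RNG seed.
#' @param method "pearson" or "spearman".
#' @return list(statistic, p_value, n_permutations).
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1L,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(d1) == nrow(d2))
  v1 <- dist_vector(d1)
  r0 <- stats::cor(v1, dist_vector(d2), method = method)
  n <- nrow(d2)
  with_seed(seed, {
    ge <- replicate(n_permutations, {
      p <- sample.int(n)
      abs(stats::cor(v1, dist_vector(d2[p, p]), method = method)) >=
        abs(r0) - 1e-12
    })
  })
  list(statistic = r0,
       p_value = (1 + sum(ge)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' PCA of an environmental parameter matrix
#'
#' Columns are z-standardised (zero-variance columns dropped with a
#' warning) and decomposed by SVD. The contribution of a variable to a
#' component is its squared loading as a percentage of that component's
#' squared loadings.
#'
#' @param env samples x parameters numeric matrix or data.frame.
#' @return list(scores, loadings, eigenvalues, explained_pct,
#'   contributions_pct (variables x components)).
#' @export
env_pca <- function(env) {
  env <- as.matrix(env)
  stopifnot(nrow(env) >= 2, ncol(env) >= 2)
  v <- apply(env, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(env)[v == 0], collapse = ", "))
    env <- env[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  contrib <- sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/") * 100
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = eig,
       explained_pct = 100 * eig / sum(eig),
       contributions_pct = contrib)
}

#' Sequential variance-inflation-factor pruning
#'
#' Iteratively computes VIF_j = 1/(1 - R^2_j) from regressing each
#' predictor column on the others and removes the largest until all fall
#' below `vif_threshold`. Exact collinearity gives infinite VIF and is
#' removed first; ties break by column order.
#'
#' @param predictors numeric matrix or data.frame (factors must already be
#'   dummy-coded).
#' @param vif_threshold default 10.
#' @return list(retained: column names, removed: data.frame(column, vif)
#'   in removal order, vif: final VIFs).
#' @export
vif_prune <- function(predictors, vif_threshold = 10) {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  removed <- data.frame(column = character(0), vif = numeric(0))
  vifs_of <- function(x) {
    sapply(seq_len(ncol(x)), function(j) {
      fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    })
  }
  while (ncol(x) > 1) {
    v <- vifs_of(x)
    if (all(v < vif_threshold)) break
    drop <- which.max(v)                       # first max = column-order tie-break
    removed <- rbind(removed,
                     data.frame(column = colnames(x)[drop], vif = v[drop]))
    x <- x[, -drop, drop = FALSE]
  }
  final <- if (ncol(x) > 1) vifs_of(x) else 1
  list(retained = colnames(x), removed = removed,
       vif = setNames(final, colnames(x)))
}

#' Hellinger transformation of a count/abundance table (samples x features)
#' @param y samples x features matrix.
#' @return sqrt of row-normalised relative abundances.
#' @export
hellinger <- function(y) {
  y <- as.matrix(y)
  sqrt(sweep(y, 1, pmax(rowSums(y), .Machine$double.eps), "/"))
}

#' Redundancy analysis R-squared and adjusted R-squared
#'
#' Multivariate least squares of a (typically Hellinger-transformed)
#' community matrix on a predictor matrix: R^2 = SS(fitted)/SS(total) on
#' the column-centred response; adjusted = 1 - (1 - R^2)(n-1)/(n-m-1) with
#' m the rank of the predictor matrix (equal to the column count for
#' full-rank predictors; rank makes redundant columns inert, so duplicated
#' predictor sets share rather than fabricate explained variance).
#'
#' @param response samples x features numeric matrix.
#' @param predictors samples x m numeric matrix (dummy-coded factors).
#' @return list(r_squared, adj_r_squared, n, m).
#' @export
rda_adjusted_r2 <- function(response, predictors) {
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  x <- as.matrix(predictors)
  n <- nrow(y)
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- fit$rank - 1L
  if (n <= m + 1) stop("adjusted R^2 undefined: n <= m + 1")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum(y^2)
  r2 <- 1 - ss_res / ss_tot
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - m - 1),
       n = n, m = m)
}

#' Variation partitioning over 2-4 named predictor sets
#'
#' Computes the RDA adjusted R^2 of every non-empty union of the predictor
#' sets and decomposes the full-model adjusted R^2 into unique and shared
#' fractions (exact inclusion-exclusion via the linear system
#' A(U) = sum of fractions of subsets intersecting U). Each set's marginal
#' model is tested by permuting response rows. Sets are ranked by their
#' unique fraction — the pipeline's driver ranking.
#'
#' @param response samples x features matrix (Hellinger-transform upstream).
#' @param predictor_sets named list (2-4) of samples x m_k matrices.
#' @param n_permutations default 999. @param seed RNG seed.
#' @return list(adj_r2_unions, fractions (one per non-empty set
#'   combination, names like "A", "A&B"), unique_fractions, residual,
#'   full_model_adj_r2, set_p_values, ranking).
#' @export
variation_partitioning <- function(response, predictor_sets,
                                   n_permutations = 999, seed = 1L) {
  k <- length(predictor_sets)
  if (k < 2 || k > 4) stop("between 2 and 4 predictor sets required")
  if (is.null(names(predictor_sets)) || any(names(predictor_sets) == ""))
    stop("predictor sets must be named")
  sets <- lapply(predictor_sets, as.matrix)
  nm <- names(sets)
  y <- as.matrix(response)
  subsets <- lapply(seq_len(2^k - 1), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1)) > 0))
  subset_name <- vapply(subsets, function(s) paste(nm[s], collapse = "&"), "")
  adj <- vapply(subsets, function(s)
    rda_adjusted_r2(y, do.call(cbind, sets[s]))$adj_r_squared, 0)
  names(adj) <- subset_name
  # solve A(U) = sum_{T : T n U != 0} x_T for the exact fractions x_T
  M <- outer(seq_along(subsets), seq_along(subsets), Vectorize(function(u, t)
    as.numeric(length(intersect(subsets[[u]], subsets[[t]])) > 0)))
  fractions <- setNames(solve(M, adj), subset_name)
  full <- adj[[length(adj)]]
  uniq <- fractions[vapply(subsets, length, 0L) == 1]
  names(uniq) <- nm
  with_seed(seed, {
    pvals <- vapply(seq_len(k), function(i) {
      r0 <- rda_adjusted_r2(y, sets[[i]])$r_squared
      ge <- replicate(n_permutations, {
        rp <- rda_adjusted_r2(y[sample.int(nrow(y)), , drop = FALSE],
                              sets[[i]])$r_squared
        rp >= r0 - 1e-12
      })
      (1 + sum(ge)) / (1 + n_permutations)
    }, 0)
  })
  list(adj_r2_unions = adj,
       fractions = fractions,
       unique_fractions = uniq,
       residual = 1 - full,
       full_model_adj_r2 = full,
       set_p_values = setNames(pvals, nm),
       ranking = names(sort(uniq, decreasing = TRUE)))
}

#' Dummy-code a categorical vector into a model matrix (no intercept column)
#' @param x character/factor vector. @param prefix column-name prefix.
#' @return n x (levels - 1) indicator matrix (treatment coding).
#' @export
dummy_code <- function(x, prefix = "g") {
  f <- factor(x)
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0(prefix, "_", levels(f)[-1])
  m
}
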