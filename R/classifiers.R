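# --- minimal CART + random forest (no tree package in the tool stack) ----

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best Gini split of one numeric feature; returns c(gain, threshold) or NULL
best_split_feature <- function(x, y, K) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  tot <- tabulate(ys, K)
  parent <- gini_impurity(tot)
  left <- integer(K)
  best_gain <- 0; best_thr <- NA_real_
  for (i in seq_len(n - 1)) {
    left[ys[i]] <- left[ys[i]] + 1
    if (xs[i] == xs[i + 1]) next
    gl <- gini_impurity(left)
    gr <- gini_impurity(tot - left)
    gain <- parent - (i * gl + (n - i) * gr) / n
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best_thr <- (xs[i] + xs[i + 1]) / 2
    }
  }
  if (is.na(best_thr)) NULL else c(best_gain, best_thr)
}

grow_tree <- function(X, y, mtry, K, min_node = 1) {
  nodes <- list()
  importance <- numeric(ncol(X))
  build <- function(idx) {
    node <- list(pred = which.max(tabulate(y[idx], K)), var = NA_integer_,
                 thr = NA_real_, left = NA_integer_, right = NA_integer_)
    counts <- tabulate(y[idx], K)
    if (length(idx) <= min_node || sum(counts > 0) == 1) {
      nodes[[length(nodes) + 1]] <<- node
      return(length(nodes))
    }
    vars <- sample.int(ncol(X), mtry)
    best <- NULL; best_var <- NA_integer_
    for (v in vars) {
      sp <- best_split_feature(X[idx, v], y[idx], K)
      if (!is.null(sp) && (is.null(best) || sp[1] > best[1])) {
        best <- sp; best_var <- v
      }
    }
    if (is.null(best)) {
      nodes[[length(nodes) + 1]] <<- node
      return(length(nodes))
    }
    importance[best_var] <<- importance[best_var] + best[1] * length(idx)
    go_left <- X[idx, best_var] <= best[2]
    node$var <- best_var; node$thr <- best[2]
    node$left <- build(idx[go_left])
    node$right <- build(idx[!go_left])
    nodes[[length(nodes) + 1]] <<- node
    length(nodes)
  }
  root <- build(seq_len(nrow(X)))
  list(nodes = nodes, root = root, importance = importance)
}

predict_tree <- function(tree, X) {
  apply(X, 1, function(row) {
    i <- tree$root
    repeat {
      nd <- tree$nodes[[i]]
      if (is.na(nd$var)) return(nd$pred)
      i <- if (row[nd$var] <= nd$thr) nd$left else nd$right
    }
  })
}

#' Train a random-forest HMA/LMA status classifier
#'
#' Bagged CART trees (Gini splits, sqrt(p) candidate features per split)
#' over phylum- and class-level relative-abundance profiles. Reports
#' out-of-bag accuracy and Gini importances.
#'
#' @param profiles samples x taxa relative-abundance matrix (rows sum to 1;
#'   renormalised if not).
#' @param labels "HMA"/"LMA" per sample.
#' @param n_trees default 500. @param seed RNG seed.
#' @return object of class `status_model`: list(trees, classes, features,
#'   oob_accuracy, oob_votes, importance).
#' @export
hma_lma_train <- function(profiles, labels, n_trees = 500, seed = 1L) {
  X <- as.matrix(profiles)
  X <- sweep(X, 1, pmax(rowSums(X), .Machine$double.eps), "/")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training set contains a single class")
  y <- match(labels, classes)
  n <- nrow(X); K <- length(classes)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  with_seed(seed, {
    votes <- matrix(0, n, K)
    trees <- vector("list", n_trees)
    imp <- numeric(ncol(X))
    for (b in seq_len(n_trees)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), bag)
      tr <- grow_tree(X[bag, , drop = FALSE], y[bag], mtry, K)
      trees[[b]] <- tr
      imp <- imp + tr$importance
      if (length(oob))
        for (i in seq_along(oob)) {
          p <- predict_tree(tr, X[oob[i], , drop = FALSE])
          votes[oob[i], p] <- votes[oob[i], p] + 1
        }
    }
  })
  voted <- rowSums(votes) > 0
  oob_pred <- max.col(votes, ties.method = "first")
  structure(list(trees = trees, classes = classes, features = colnames(X),
                 oob_accuracy = mean(oob_pred[voted] == y[voted]),
                 oob_votes = votes,
                 importance = setNames(imp / n_trees, colnames(X))),
            class = "status_model")
}

#' Predict HMA/LMA status per sample and per species
#'
#' Missing taxa are zero-filled and extra taxa dropped to match the
#' training feature space. Species labels are the majority over the
#' species' samples; exact ties (and all-zero profiles) are "ambiguous".
#'
#' @param model a `status_model` from [hma_lma_train()].
#' @param profiles samples x taxa relative abundances.
#' @param species optional species per sample for aggregation.
#' @return list(sample_labels, vote_fractions (samples x classes),
#'   species_labels, species_vote_fraction).
#' @export
hma_lma_predict <- function(model, profiles, species = NULL) {
  X0 <- as.matrix(profiles)
  X <- matrix(0, nrow(X0), length(model$features),
              dimnames = list(rownames(X0), model$features))
  shared <- intersect(colnames(X0), model$features)
  X[, shared] <- X0[, shared]
  X <- sweep(X, 1, pmax(rowSums(X), .Machine$double.eps), "/")
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(rownames(X), model$classes))
  for (tr in model$trees) {
    p <- predict_tree(tr, X)
    for (k in seq_len(K)) votes[p == k, k] <- votes[p == k, k] + 1
  }
  frac <- votes / length(model$trees)
  empty <- rowSums(X0) == 0
  if (any(empty)) warning(sum(empty), " all-zero profile(s) set to ambiguous")
  lab <- model$classes[max.col(frac, ties.method = "first")]
  tie <- apply(frac, 1, function(v) sum(v == max(v)) > 1)
  lab[tie | empty] <- "ambiguous"
  out <- list(sample_labels = setNames(lab, rownames(X)),
              vote_fractions = frac)
  if (!is.null(species)) {
    sp <- split(lab, species)
    sp_lab <- vapply(sp, function(v) {
      tb <- table(v[v != "ambiguous"])
      if (length(tb) == 0) return("ambiguous")
      top <- tb[tb == max(tb)]
      if (length(top) > 1) "ambiguous" else names(top)
    }, "")
    sp_frac <- vapply(names(sp), function(s)
      if (sp_lab[[s]] == "ambiguous") NA_real_
      else mean(sp[[s]] == sp_lab[[s]]), 0)
    out$species_labels <- sp_lab
    out$species_vote_fraction <- sp_frac
  }
  out
}

#' Classify samples into water masses by temperature-salinity boxes
#'
#' A sample is labelled with the box containing its (T, S) point; when
#' several overlapping boxes match, the box whose centre is nearest in
#' z-scored T-S units wins; no match (or missing T/S) gives
#' "unclassified".
#'
#' @param samples data.frame with `temperature` and `salinity`.
#' @param boxes data.frame(name, T_min, T_max, S_min, S_max).
#' @return character label per sample.
#' @export
watermass_classify <- function(samples, boxes) {
  stopifnot(nrow(boxes) >= 1,
            all(c("name", "T_min", "T_max", "S_min", "S_max") %in% names(boxes)))
  if (anyDuplicated(boxes$name)) stop("duplicate water-mass names")
  if (any(boxes$T_min >= boxes$T_max) || any(boxes$S_min >= boxes$S_max))
    stop("each box needs min < max on both axes")
  ct <- (boxes$T_min + boxes$T_max) / 2
  cs <- (boxes$S_min + boxes$S_max) / 2
  sdt <- max(stats::sd(ct), 1e-9)
  sds <- max(stats::sd(cs), 1e-9)
  vapply(seq_len(nrow(samples)), function(i) {
    t <- samples$temperature[i]; s <- samples$salinity[i]
    if (is.na(t) || is.na(s)) {
      warning("missing T or S for sample ", i, "; unclassified")
      return("unclassified")
    }
    inbox <- which(t >= boxes$T_min & t <= boxes$T_max &
                     s >= boxes$S_min & s <= boxes$S_max)
    if (length(inbox) == 0) return("unclassified")
    if (length(inbox) == 1) return(boxes$name[inbox])
    d <- ((t - ct[inbox]) / sdt)^2 + ((s - cs[inbox]) / sds)^2
    boxes$name[inbox[which.min(d)]]
  }, "")
}
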