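#' Rarefy a feature table to even depth
#'
#' Samples with fewer than `depth` reads are dropped; the rest are
#' subsampled without replacement to exactly `depth` reads. Deterministic
#' for a seed.
#'
#' @param table count matrix. @param depth target reads per sample.
#' @param seed RNG seed.
#' @return rarefied count matrix (possibly fewer columns).
#' @export
rarefy <- function(table, depth = 5000, seed = 1L) {
  if (depth <= 0) stop("depth must be >= 1")
  keep <- colSums(table) >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  table <- table[, keep, drop = FALSE]
  with_seed(seed, {
    out <- apply(table, 2, function(col) {
      tot <- sum(col)
      if (tot == depth) return(col)
      reads <- rep.int(seq_along(col), col)
      picked <- sample(reads, depth)
      tabulate(picked, nbins = length(col))
    })
    dimnames(out) <- dimnames(table)
    out
  })
}

#' Alpha diversity metrics
#'
#' Shannon index in bits (log base 2, amplicon-pipeline convention),
#' Pielou's evenness (Shannon / log2 richness; NA when <= 1 feature),
#' observed features, and (when a tree is given) Faith's phylogenetic
#' diversity: the total branch length of the root-inclusive subtree
#' spanning the sample's present features.
#'
#' @param table count matrix.
#' @param tree optional rooted `phylo` covering all table features.
#' @return data.frame(sample_id, observed, shannon, pielou, faith_pd).
#' @export
alpha_diversity <- function(table, tree = NULL) {
  res <- data.frame(sample_id = colnames(table),
                    observed = NA_integer_, shannon = NA_real_,
                    pielou = NA_real_, faith_pd = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    missing <- setdiff(rownames(table), tree$tip.label)
    if (length(missing)) stop("tree is missing features: ",
                              paste(utils::head(missing), collapse = ", "))
  }
  for (j in seq_len(ncol(table))) {
    x <- table[, j]
    tot <- sum(x)
    if (tot == 0) {
      warning("sample '", colnames(table)[j], "' has zero total count")
      next
    }
    p <- x[x > 0] / tot
    obs <- length(p)
    sh <- -sum(p * log2(p))
    res$observed[j] <- obs
    res$shannon[j] <- sh
    res$pielou[j] <- if (obs > 1) sh / log2(obs) else NA_real_
    if (!is.null(tree))
      res$faith_pd[j] <- faith_pd(names(x)[x > 0], tree)
  }
  res
}

#' Faith's phylogenetic diversity for one set of present features
#' @param present tip labels with non-zero counts.
#' @param tree rooted `phylo`.
#' @return total branch length on the union of root-to-tip paths.
#' @export
faith_pd <- function(present, tree) {
  bp <- branch_proportions(matrix(1, nrow = length(present), ncol = 1,
                                  dimnames = list(present, "s")), tree)
  sum(bp$lengths[bp$prop[, 1] > 0])
}

# Per-branch descendant read proportions by a single postorder accumulation.
# Returns list(prop: edges x samples, lengths: edge lengths).
branch_proportions <- function(table, tree) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stop("tree is missing features: ", paste(utils::head(missing), collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tot <- colSums(table)
  if (any(tot == 0)) stop("zero-total sample in branch accumulation")
  # per-node accumulated proportions
  acc <- matrix(0, nrow = nnode, ncol = ncol(table))
  hit <- match(tree$tip.label, rownames(table))
  has <- !is.na(hit)
  acc[which(has), ] <- sweep(table[hit[has], , drop = FALSE], 2, tot, "/")
  # postorder: children before parents
  ord <- order(node_depths(tree), decreasing = TRUE)
  child_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (node in ord) {
    kids <- child_of[[as.character(node)]]
    if (is.null(kids)) next
    for (e in kids) acc[node, ] <- acc[node, ] + acc[tree$edge[e, 2], ]
  }
  list(prop = acc[tree$edge[, 2], , drop = FALSE],
       lengths = tree$edge.length)
}

# depth (edges from root) of every node; root = ntip + 1
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- rep(NA_integer_, nnode)
  root <- ntip + 1L
  depth[root] <- 0L
  # edges in tree$edge are parent->child; iterate until all assigned
  repeat {
    known <- !is.na(depth[tree$edge[, 1]]) & is.na(depth[tree$edge[, 2]])
    if (!any(known)) break
    depth[tree$edge[known, 2]] <- depth[tree$edge[known, 1]] + 1L
  }
  depth
}

#' Beta diversity distance matrix
#'
#' Weighted UniFrac (raw form: sum over branches of branch length times the
#' absolute difference of descendant read proportions; the normalised
#' variant divides by sum of length times the proportion sum), Jaccard
#' distance on presence/absence, or Bray-Curtis on relative abundances.
#'
#' @param table count matrix.
#' @param metric one of "weighted_unifrac", "jaccard", "bray_curtis".
#' @param tree rooted `phylo`, required for weighted UniFrac.
#' @param normalized normalise weighted UniFrac into [0, 1]? Default FALSE
#'   (raw form).
#' @return distance matrix over samples.
#' @export
beta_diversity <- function(table, metric = c("weighted_unifrac", "jaccard",
                                             "bray_curtis"),
                           tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  n <- ncol(table)
  d <- matrix(0, n, n)
  if (metric == "weighted_unifrac") {
    if (is.null(tree)) stop("weighted UniFrac requires a tree")
    bp <- branch_proportions(table, tree)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(bp$lengths * abs(bp$prop[, i] - bp$prop[, j]))
      d[i, j] <- d[j, i] <- if (normalized)
        num / sum(bp$lengths * (bp$prop[, i] + bp$prop[, j])) else num
    }
  } else if (metric == "jaccard") {
    pres <- table > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      un <- sum(pres[, i] | pres[, j])
      d[i, j] <- d[j, i] <- if (un == 0) 0 else 1 - sum(pres[, i] & pres[, j]) / un
    }
  } else {
    rel <- sweep(table, 2, colSums(table), "/")
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(abs(rel[, i] - rel[, j])) /
        sum(rel[, i] + rel[, j])
  }
  distance_matrix(d, colnames(table))
}

#' Agglomerative sample dendrogram from a distance matrix
#'
#' UPGMA (average linkage, the default for community dendrograms) or
#' complete linkage (used for ordering location similarity heatmaps).
#'
#' @param dist distance matrix.
#' @param linkage "upgma" or "complete".
#' @return list(hclust, tree: `phylo`, newick, leaf_order).
#' @export
cluster_dendrogram <- function(dist, linkage = c("upgma", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(dist) < 2) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::as.dist(dist),
                      method = if (linkage == "upgma") "average" else "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, tree = phy, newick = ape::write.tree(phy),
       leaf_order = hc$labels[hc$order])
}
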