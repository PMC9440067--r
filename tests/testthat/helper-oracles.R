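# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (recursive newick parsing,
# exhaustive enumeration, direct set algebra) so that agreement is evidence,
# not tautology.

# --- weighted UniFrac / Faith PD from the newick string -------------------

# parse a newick string into a nested list: list(children=..., length=)
parse_newick <- function(text) {
  text <- sub(";\\s*$", "", text)
  pos <- 1
  parse_node <- function() {
    node <- list(children = list(), label = NULL, length = 0)
    if (substr(text, pos, pos) == "(") {
      pos <<- pos + 1
      repeat {
        node$children[[length(node$children) + 1]] <- parse_node()
        ch <- substr(text, pos, pos)
        pos <<- pos + 1
        if (ch == ")") break
        if (ch != ",") stop("parse error at ", pos)
      }
    }
    lab <- ""
    while (pos <= nchar(text) &&
           !substr(text, pos, pos) %in% c(",", ")", "(", ":")) {
      lab <- paste0(lab, substr(text, pos, pos)); pos <<- pos + 1
    }
    node$label <- lab
    if (pos <= nchar(text) && substr(text, pos, pos) == ":") {
      pos <<- pos + 1
      num <- ""
      while (pos <= nchar(text) &&
             grepl("[0-9eE.+-]", substr(text, pos, pos))) {
        num <- paste0(num, substr(text, pos, pos)); pos <<- pos + 1
      }
      node$length <- as.numeric(num)
    }
    node
  }
  parse_node()
}

# every branch of the parsed tree with its descendant leaf set
newick_branches <- function(node) {
  branches <- list()
  walk <- function(nd) {
    if (length(nd$children) == 0) {
      leaves <- nd$label
    } else {
      leaves <- character(0)
      for (ch in nd$children) leaves <- c(leaves, walk(ch))
    }
    branches[[length(branches) + 1]] <<- list(length = nd$length,
                                              leaves = leaves)
    leaves
  }
  walk(node)
  branches
}

# brute-force raw weighted UniFrac between two count vectors (named by leaf)
wunifrac_bruteforce <- function(newick, x, y) {
  br <- newick_branches(parse_newick(newick))
  px <- x / sum(x); py <- y / sum(y)
  s <- 0
  for (b in br) {
    pa <- sum(px[b$leaves]); pb <- sum(py[b$leaves])
    s <- s + b$length * abs(pa - pb)
  }
  s
}

faith_bruteforce <- function(newick, present) {
  br <- newick_branches(parse_newick(newick))
  sum(vapply(br, function(b)
    if (any(b$leaves %in% present)) b$length else 0, 0))
}

# --- exhaustive shortest path on a small weighted graph -------------------

# edges: data.frame(from, to, weight), undirected; DFS over simple paths
shortest_path_bruteforce <- function(edges, from, to) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    adj[[a]] <- rbind(adj[[a]], data.frame(n = b, w = edges$weight[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(n = a, w = edges$weight[i]))
  }
  best <- Inf
  dfs <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb)))
      if (!nb$n[i] %in% visited)
        dfs(nb$n[i], c(visited, nb$n[i]), cost + nb$w[i])
  }
  dfs(as.character(from), as.character(from), 0)
  best
}

# flood fill: connected components of a logical mask (4/8-neighbour)
flood_components <- function(mask, diagonal = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (diagonal) offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    comp <- comp + 1L
    stack <- list(c(i, j)); lab[i, j] <- comp
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- cur[1] + offs[k, 1]; c <- cur[2] + offs[k, 2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- comp
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  comp
}

# --- PERMANOVA pseudo-F (independent formulation) + full enumeration ------

pseudo_f_oracle <- function(d, groups) {
  # direct from the definition: SS via centroid-free within-group pair sums
  n <- length(groups); k <- length(unique(groups))
  d2 <- d^2
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

permanova_enumerate <- function(d, groups) {
  f0 <- pseudo_f_oracle(d, groups)
  perms <- all_permutations(length(groups))
  fs <- apply(perms, 1, function(p) pseudo_f_oracle(d, groups[p]))
  mean(fs >= f0 - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# --- small fixtures -------------------------------------------------------

# memoised small zero-noise synthetic dataset shared across test files
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, dispersion = Inf,
                        n_species_per_type = c(HMA = 3L, LMA_demo = 3L, LMA_glass = 2L),
                        samples_per_species = 5L,
                        n_reference_samples = c(seawater = 8L, sediment = 5L),
                        n_background_asvs = 150L, n_locations = 5L)
      ds <- generate_dataset(cfg)
      fl <- filter_samples(ds$table, ds$metadata, 5000)
      cache <<- list(config = cfg, ds = ds, table = fl$table,
                     metadata = fl$metadata)
    }
    cache
  }
})

random_counts <- function(n, nonzero = n) {
  x <- numeric(n)
  x[sample.int(n, nonzero)] <- rpois(nonzero, 20) + 1
  x
}
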