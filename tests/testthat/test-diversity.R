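test_that("rarefaction keeps full-depth columns, drops shallow ones, and is seeded", {
  tab <- feature_table(matrix(c(3, 2, 0, 10, 0, 0, 2, 1, 1), nrow = 3,
                              dimnames = list(paste0("f", 1:3), paste0("s", 1:3))))
  r <- rarefy(tab, 5, seed = 1)
  expect_identical(colnames(r), c("s1", "s2"))           # sums 5, 10, 4
  expect_equal(unname(r[, "s1"]), c(3, 2, 0))            # sum == depth: unchanged
  expect_error(rarefy(tab, 0), "depth")
  single <- feature_table(matrix(c(10, 0, 0), 3, 1,
                                 dimnames = list(paste0("f", 1:3), "s")))
  expect_equal(unname(rarefy(single, 5, seed = 2)[, 1]), c(5, 0, 0))
  expect_identical(rarefy(tab, 4, seed = 9), rarefy(tab, 4, seed = 9))
})

test_that("rarefied column means match the hypergeometric expectation", {
  col <- feature_table(matrix(c(50, 30, 20), 3, 1,
                              dimnames = list(c("a", "b", "c"), "s")))
  depth <- 10
  draws <- sapply(1:1000, function(i) rarefy(col, depth, seed = i)[, 1])
  expected <- depth * c(50, 30, 20) / 100
  # multivariate hypergeometric variance for each taxon count
  v <- depth * (c(50, 30, 20) / 100) * (1 - c(50, 30, 20) / 100) * (100 - depth) / 99
  se <- sqrt(v / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("alpha metrics match closed forms and the Faith brute-force oracle", {
  tab <- feature_table(matrix(c(1, 1, 1, 1, 0, 0, 7, 0), nrow = 4,
                              dimnames = list(paste0("t", 1:4), c("u", "v"))))
  tree <- generate_tree(paste0("t", 1:4), seed = 3)
  a <- alpha_diversity(tab, tree)
  expect_equal(a$shannon[1], 2)                          # uniform, bits
  expect_equal(a$pielou[1], 1)
  expect_equal(a$shannon[2], 0)                          # single feature
  expect_true(is.na(a$pielou[2]))
  nwk <- ape::write.tree(tree)
  expect_equal(a$faith_pd[2], faith_bruteforce(nwk, "t3"))
  # 5-leaf random tree, 3 present leaves, explicit edge-union enumeration
  tr5 <- generate_tree(paste0("x", 1:5), seed = 8)
  expect_equal(faith_pd(c("x1", "x3", "x4"), tr5),
               faith_bruteforce(ape::write.tree(tr5), c("x1", "x3", "x4")))
  expect_warning(alpha_diversity(feature_table(
    matrix(0, 1, 1, dimnames = list("f", "s")))), "zero total")
})

test_that("alpha invariants hold on random tables", {
  set.seed(21)
  tab <- feature_table(matrix(rpois(60, 30), nrow = 10,
                              dimnames = list(paste0("f", 1:10), paste0("s", 1:6))))
  a <- alpha_diversity(tab)
  expect_true(all(a$shannon <= log2(a$observed) + 1e-12))
  expect_true(all(a$pielou >= 0 & a$pielou <= 1, na.rm = TRUE))
  ar <- alpha_diversity(rarefy(tab, min(colSums(tab)), seed = 1))
  expect_true(all(ar$observed <= a$observed))
})

test_that("weighted UniFrac matches hand evaluation and basic limits", {
  tree <- ape::read.tree(text = "(A:0.3,B:0.7);")
  tab <- feature_table(matrix(c(10, 0, 0, 4), 2, 2,
                              dimnames = list(c("A", "B"), c("s1", "s2"))))
  d <- beta_diversity(tab, "weighted_unifrac", tree = tree)
  expect_equal(d["s1", "s2"], 0.3 + 0.7)                 # pure samples: a + b
  dn <- beta_diversity(tab, "weighted_unifrac", tree = tree, normalized = TRUE)
  expect_equal(dn["s1", "s2"], 1)
  same <- feature_table(matrix(c(3, 5, 3, 5), 2, 2,
                               dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(max(beta_diversity(same, "weighted_unifrac", tree = tree)), 0)
  expect_error(beta_diversity(tab, "weighted_unifrac"), "tree")
})

test_that("weighted UniFrac equals the independent newick-string oracle", {
  set.seed(99)
  for (case in 1:60) {
    n <- sample(3:8, 1)
    ids <- paste0("L", seq_len(n))
    nwk <- ape::write.tree(generate_tree(ids, seed = case))
    tr <- ape::read.tree(text = nwk)       # same serialised lengths both routes
    x <- random_counts(n, sample(2:n, 1))
    y <- random_counts(n, sample(2:n, 1))
    tab <- feature_table(matrix(c(x, y), ncol = 2,
                                dimnames = list(ids, c("a", "b"))))
    mine <- beta_diversity(tab, "weighted_unifrac", tree = tr)["a", "b"]
    oracle <- wunifrac_bruteforce(nwk, setNames(x, ids), setNames(y, ids))
    expect_lt(abs(mine - oracle), 1e-10)
  }
})

test_that("jaccard and bray-curtis behave at the extremes and stay metric-shaped", {
  tab <- feature_table(matrix(c(3, 2, 0, 0, 0, 0, 1, 9), nrow = 4,
                              dimnames = list(paste0("f", 1:4), c("p", "q"))))
  expect_equal(beta_diversity(tab, "jaccard")["p", "q"], 1)   # disjoint
  expect_equal(beta_diversity(tab, "bray_curtis")["p", "q"], 1)
  set.seed(5)
  big <- feature_table(matrix(rpois(50, 10), nrow = 5,
                              dimnames = list(paste0("f", 1:5), paste0("s", 1:10))))
  for (m in c("jaccard", "bray_curtis")) {
    d <- beta_diversity(big, m)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  bw <- beta_diversity(big, "weighted_unifrac",
                       tree = generate_tree(paste0("f", 1:5), seed = 1),
                       normalized = TRUE)
  expect_true(all(bw >= 0 & bw <= 1))
})

test_that("dendrograms merge nearest pairs first and match manual UPGMA", {
  d3 <- distance_matrix(matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3),
                        c("a", "b", "c"))
  dd <- cluster_dendrogram(d3, "upgma")
  first <- dd$hclust$merge[1, ]
  expect_setequal(abs(first), c(1, 2))                   # {a,b} merged first
  # manual UPGMA (heights = average cluster distances): merge {a,b} at 2,
  # then {c,d} at 4 (vs d(ab,c)=7, d(ab,d)=11), final mean(6,8,10,12) = 9
  m <- matrix(c(0, 2, 6, 10,
                2, 0, 8, 12,
                6, 8, 0, 4,
                10, 12, 4, 0), 4, 4)
  d4 <- distance_matrix(m, c("a", "b", "c", "d"))
  h <- cluster_dendrogram(d4, "upgma")$hclust$height
  expect_equal(sort(h), c(2, 4, 9))
  perm <- c(3, 1, 4, 2)
  hp <- cluster_dendrogram(distance_matrix(m[perm, perm],
                                           c("a", "b", "c", "d")[perm]),
                           "upgma")$hclust$height
  expect_equal(sort(hp), sort(h))                        # order invariance
  expect_error(cluster_dendrogram(distance_matrix(matrix(0, 1, 1), "z")), "2 items")
})
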