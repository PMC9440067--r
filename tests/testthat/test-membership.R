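test_that("greedy clustering honours the identity threshold", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT")
  expect_equal(length(unique(cluster_features(seqs, 0.9))), 1)
  pair <- c(a = "ACGTACGT", b = "ACGTACGA")       # 7/8 = 0.875 identity
  expect_equal(length(unique(cluster_features(pair, 0.87))), 1)
  expect_equal(length(unique(cluster_features(pair, 0.90))), 2)
  three <- c(x = "AAAAAAAA", y = "CCCCCCCC", z = "GGGGGGGG")
  expect_equal(length(unique(cluster_features(three, 1.0))), 3)
  expect_error(cluster_features(character(0), 0.9), "no sequences")
  expect_error(cluster_features(c(q = "ACGU"), 0.9), "non-ACGTN")
})

test_that("membership boundaries and categories follow the strict 70% rule", {
  b <- membership_boundaries(931, 0.7)
  expect_equal(b$core_min, 652L)
  expect_equal(b$variable_max, 651L)
  tab <- feature_table(matrix(c(1, 0, 0, 0, 0,
                                1, 1, 0, 0, 0,
                                1, 1, 1, 1, 0,
                                1, 1, 1, 1, 1), nrow = 4, byrow = TRUE,
                              dimnames = list(paste0("f", 1:4), paste0("s", 1:5))))
  mem <- classify_membership(tab, 0.7)
  expect_equal(mem$category, c("individual", "variable", "core", "core"))
  # occurrence 4 > 0.7*5 = 3.5 -> core; exactly floor is variable:
  mem10 <- classify_membership(feature_table(
    matrix(c(rep(1, 7), 0, 0, 0), 1, 10,
           dimnames = list("f", paste0("s", 1:10)))), 0.7)
  expect_equal(mem10$category, "variable")               # 7 of 10 is not > 70%
})

test_that("membership matches a brute-force occupancy oracle and partitions features", {
  set.seed(31)
  tab <- feature_table(matrix(rbinom(200, 1, 0.4) * rpois(200, 9), nrow = 20,
                              dimnames = list(paste0("f", 1:20), paste0("s", 1:10))))
  tab <- tab[rowSums(tab) > 0, ]
  mem <- classify_membership(tab, 0.7)
  for (i in seq_len(nrow(mem))) {
    occ <- sum(tab[mem$unit[i], ] > 0)                    # independent count
    expect_equal(mem$occurrence[i], occ)
    expect_equal(mem$category[i],
                 if (occ == 1) "individual" else if (occ > 7) "core" else "variable")
  }
  expect_setequal(mem$unit, rownames(tab))                # partition
  expect_error(classify_membership(tab[0, ]), "empty")
})

test_that("coarser clustering thresholds never increase the unit count", {
  set.seed(77)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    v[pos] <- sapply(v[pos], function(ch) sample(setdiff(c("A", "C", "G", "T"), ch), 1))
    paste(v, collapse = "")
  }
  seqs <- c(base, sapply(c(1, 2, 4, 8, 15, 25), function(k) mutate(base, k)),
            paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""))
  names(seqs) <- paste0("f", seq_along(seqs))
  tab <- feature_table(matrix(rpois(length(seqs) * 6, 10) + 1,
                              nrow = length(seqs),
                              dimnames = list(names(seqs), paste0("s", 1:6))))
  mems <- membership_across_thresholds(tab, seqs,
                                       thresholds = c(1.0, 0.99, 0.97, 0.95, 0.90))
  units <- vapply(mems, nrow, 0L)
  expect_true(all(diff(units) <= 0))                      # monotone coarsening
  for (m in mems) {
    expect_true(all(m$category %in% c("individual", "variable", "core")))
    expect_equal(sum(table(m$category)), nrow(m))
  }
})

test_that("sample-type sharing reproduces set algebra on a known pattern", {
  # 6 ASVs across 3 groups (2 samples each): presence by construction
  tab <- feature_table(matrix(c(
    1, 1, 1, 1, 1, 1,     # f1 everywhere -> all
    1, 1, 0, 0, 0, 0,     # f2 only A
    0, 0, 1, 0, 0, 0,     # f3 only B
    1, 0, 1, 0, 0, 0,     # f4 A+B
    0, 0, 1, 1, 1, 1,     # f5 B+C
    0, 0, 0, 0, 0, 0),    # f6 nowhere -> excluded
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("f", 1:6), paste0("s", 1:6))))
  groups <- setNames(rep(c("A", "B", "C"), each = 2), paste0("s", 1:6))
  expect_warning(sh <- sample_type_sharing(tab, groups), "all-zero")
  expect_equal(sh$n_asvs, 5)
  expect_equal(sh$asv_groups[["f1"]], "A+B+C")
  expect_equal(sh$pct_all, 100 * 1 / 5)
  expect_equal(sh$pct_single, 100 * 2 / 5)
  pw <- sh$pairwise
  expect_equal(pw$pct_shared[pw$group1 == "A" & pw$group2 == "B"], 100 * 2 / 5)
  expect_equal(pw$pct_shared[pw$group1 == "B" & pw$group2 == "C"], 100 * 2 / 5)
  expect_equal(pw$pct_shared[pw$group1 == "A" & pw$group2 == "C"], 100 * 1 / 5)
  expect_error(sample_type_sharing(tab, groups[-1]), "without a group")
})

test_that("abundance-occupancy rho matches the rank oracle and detects nulls", {
  # strong positive relationship by construction
  tab <- feature_table(matrix(c(50, 60, 55, 45, 1, 0, 0, 0), nrow = 2,
                              byrow = TRUE,
                              dimnames = list(c("hi", "lo"), paste0("s", 1:4))))
  tab <- rbind(tab, feature_table(matrix(c(20, 25, 0, 0), 1, 4,
                                         dimnames = list("mid", paste0("s", 1:4)))))
  ao <- abundance_occupancy(tab, paste0("s", 1:4), n_permutations = 199, seed = 1)
  expect_gt(ao$rho, 0)
  expect_equal(ao$rho,
               unname(stats::cor(ao$per_feature$mean_rel_abundance,
                                 ao$per_feature$occupancy, method = "spearman")))
  # abundance independent of occupancy by construction: per-sample
  # intensity ~ 600/k keeps the zero-inclusive mean flat in occupancy k.
  # Many features are needed because closure couples each feature to its
  # own column denominator at order 1/n_features.
  set.seed(1)
  nf <- 1000
  m <- matrix(0, nf, 10, dimnames = list(paste0("f", 1:nf), paste0("s", 1:10)))
  for (i in seq_len(nf)) {
    k <- sample(2:9, 1)                                  # occupancy
    m[i, sample(10, k)] <- rpois(k, 600 / k - 1) + 1
  }
  ao2 <- abundance_occupancy(feature_table(m), paste0("s", 1:10),
                             n_permutations = 999, seed = 2)
  expect_lt(abs(ao2$rho), 0.2)
  expect_gt(ao2$p_value, 0.05)
})
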