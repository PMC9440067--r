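toy_table <- function() {
  feature_table(matrix(c(5, 0, 3, 1, 2, 0), nrow = 3,
                       dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
}

test_that("bundle write then read is identity on content", {
  dir <- withr::local_tempdir()
  tab <- toy_table()
  md <- data.frame(sample_id = c("s1", "s2"), sample_type = "sponge",
                   sponge_type = "HMA", host_species = "sp1",
                   stringsAsFactors = FALSE)
  tax <- data.frame(feature_id = c("a", "b", "c"), domain = "Bacteria",
                    phylum = c("P1", "P1", NA), class = NA_character_,
                    order = NA_character_, family = NA_character_,
                    genus = NA_character_, stringsAsFactors = FALSE)
  tree <- generate_tree(c("a", "b", "c"), seed = 1)
  write_bundle(list(table = tab, metadata = md, taxonomy = tax, tree = tree), dir)
  back <- read_bundle(list(table = file.path(dir, "feature_table.tsv"),
                           metadata = file.path(dir, "metadata.tsv"),
                           taxonomy = file.path(dir, "taxonomy.tsv"),
                           tree = file.path(dir, "tree.nwk")))
  expect_equal(back$table, tab)
  expect_equal(back$metadata$sample_id, md$sample_id)
  expect_equal(back$taxonomy$phylum, tax$phylum)
  expect_setequal(back$tree$tip.label, rownames(tab))
})

test_that("sample mismatches resolve by inner join with a warning", {
  tab <- toy_table()
  md <- data.frame(sample_id = "s1", sample_type = "sponge",
                   sponge_type = "HMA", stringsAsFactors = FALSE)
  expect_warning(rec <- reconcile_samples(tab, md), "dropping")
  expect_identical(colnames(rec$table), "s1")
  expect_equal(nrow(rec$metadata), 1)
})

test_that("malformed counts are rejected with a location", {
  path <- withr::local_tempfile()
  writeLines(c("#FeatureID\ts1\ts2", "a\t5\t1", "b\t-3\t0"), path)
  expect_error(read_feature_table(path), "'b'.*'s1'")
  m <- matrix(c(1, 2.5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(feature_table(m), "integers")
  expect_error(feature_table(matrix(1, 1, 1)), "names")
})

test_that("min-read filter is strict at the boundary and prunes empty rows", {
  tab <- feature_table(matrix(c(4999, 0, 5000, 0, 5500, 500), nrow = 2,
                              dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
  md <- data.frame(sample_id = c("s1", "s2", "s3"), sample_type = "sponge",
                   sponge_type = "HMA", stringsAsFactors = FALSE)
  fl <- filter_samples(tab, md, 5000)
  expect_identical(colnames(fl$table), c("s2", "s3"))     # exactly 5000 passes
  expect_identical(fl$removed_samples, "s1")
  # min_reads 0 is the identity
  fl0 <- filter_samples(tab, md, 0)
  expect_equal(fl0$table, tab)
  # toy enumeration: sums (1,2,3,4), min 3 keeps 2 samples, prunes row "q"
  t2 <- feature_table(matrix(c(1, 0, 2, 0, 0, 3, 0, 4), nrow = 2,
                             dimnames = list(c("p", "q"),
                                             c("w", "x", "y", "z"))))
  md2 <- data.frame(sample_id = c("w", "x", "y", "z"), sample_type = "seawater",
                    stringsAsFactors = FALSE)
  fl2 <- filter_samples(t2, md2, 3)
  expect_identical(colnames(fl2$table), c("y", "z"))
  expect_identical(rownames(fl2$table), "q")
  expect_identical(fl2$removed_features, "p")
  expect_error(filter_samples(tab, md, 1e9), "every sample")
})

test_that("taxonomic aggregation conserves column sums and pools unassigned", {
  set.seed(42)
  m <- feature_table(matrix(rpois(40, 8), nrow = 8,
                            dimnames = list(paste0("f", 1:8), paste0("s", 1:5))))
  tax <- data.frame(feature_id = paste0("f", 1:8),
                    domain = "Bacteria",
                    phylum = c("P1", "P1", "P2", NA, "P2", "P3", NA, "P1"),
                    class = NA_character_, order = NA_character_,
                    family = NA_character_, genus = NA_character_,
                    stringsAsFactors = FALSE)
  agg <- aggregate_taxa(m, tax, "phylum")
  expect_equal(colSums(agg), colSums(m))
  expect_true("unclassified@phylum" %in% rownames(agg))
  expect_equal(unname(agg["unclassified@phylum", ]), unname(m["f4", ] + m["f7", ]))
  expect_equal(unname(agg["Bacteria;P1", ]), unname(colSums(m[c("f1", "f2", "f8"), ])))
  expect_error(aggregate_taxa(m, tax, "kingdom"), "unknown rank")
})

test_that("pipeline runs stages in order, logs the seed, and is idempotent", {
  cfg <- list(sim = list(seed = 7L,
                         n_species_per_type = c(HMA = 2L, LMA_demo = 2L, LMA_glass = 2L),
                         samples_per_species = 3L,
                         n_reference_samples = c(seawater = 4L, sediment = 3L),
                         n_background_asvs = 50L, n_locations = 3L),
              analysis = list(seed = 7L, min_reads = 100))
  out1 <- withr::local_tempdir()
  run_pipeline(cfg, out1, stages = c("simulate", "filter", "membership"))
  expect_true(file.exists(file.path(out1, "simulate", "feature_table.tsv")))
  expect_true(file.exists(file.path(out1, "membership", "membership.tsv")))
  log <- jsonlite::read_json(file.path(out1, "membership", "log.json"))
  expect_equal(log$seed, 7)
  out2 <- withr::local_tempdir()
  run_pipeline(cfg, out2, stages = c("simulate", "filter", "membership"))
  for (f in c("simulate/feature_table.tsv", "membership/membership.tsv"))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  expect_error(run_pipeline(cfg, out1, stages = "fluxcapacitor"),
               "valid stages")
  expect_error(run_pipeline(cfg, out1, stages = "membership"),
               "requires output")
})
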