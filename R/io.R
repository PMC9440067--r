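#' Read a feature-count TSV
#'
#' Features as rows, samples as columns, tab-separated, first header field
#' `#FeatureID` (common amplicon-export convention).
#'
#' @param path TSV path.
#' @return validated count matrix.
#' @export
read_feature_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "feature_id"
  if (!identical(header[1], "#FeatureID") && !identical(header[1], "feature_id"))
    warning("first header field is '", header[1], "', expected '#FeatureID'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  feature_table(m)
}

#' Write a feature-count TSV (inverse of [read_feature_table()])
#' @param table count matrix. @param path destination.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(`#FeatureID` = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV (first column `sample-id` or `sample_id`)
#' @param path TSV path.
#' @return data.frame with a `sample_id` first column; extra columns kept.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df)[1] <- "sample_id"
  df
}

#' Write sample metadata TSV
#' @param metadata data.frame. @param path destination.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  names(out)[names(out) == "sample_id"][1] <- "sample-id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy TSV (feature_id, taxonomy as semicolon-ranked lineage)
#' @param path TSV path.
#' @return data.frame feature_id plus one column per rank
#'   (domain...genus); unassigned ranks are NA.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("feature_id", "taxonomy")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(df$taxonomy, ";\\s*")
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p); p[p == "" | p == "NA"] <- NA_character_
    length(p) <- length(ranks); p
  }, character(length(ranks))))
  colnames(mat) <- ranks
  cbind(df[, "feature_id", drop = FALSE], as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Write a taxonomy TSV from a ranked data.frame
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path destination.
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- setdiff(names(taxonomy), "feature_id")
  lineage <- apply(taxonomy[, ranks, drop = FALSE], 1, function(x)
    paste(ifelse(is.na(x), "NA", x), collapse = ";"))
  utils::write.table(data.frame(feature_id = taxonomy$feature_id,
                                taxonomy = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the standard data bundle
#'
#' Expects `paths` to be a named list/vector with elements `table`,
#' `metadata`, and optionally `taxonomy`, `tree` (newick). Sample sets of
#' table and metadata are reconciled by inner join (with a warning on
#' drops); tree leaves must cover all table features.
#'
#' @param paths named list of file paths.
#' @return list(table, metadata, taxonomy, tree).
#' @export
read_bundle <- function(paths) {
  paths <- as.list(paths)
  table <- read_feature_table(paths$table)
  metadata <- read_metadata(paths$metadata)
  rec <- reconcile_samples(table, metadata)
  taxonomy <- if (!is.null(paths$taxonomy)) read_taxonomy(paths$taxonomy) else NULL
  tree <- NULL
  if (!is.null(paths$tree)) {
    tree <- ape::read.tree(paths$tree)
    missing <- setdiff(rownames(rec$table), tree$tip.label)
    if (length(missing))
      stop("tree is missing table feature(s): ", paste(missing, collapse = ", "))
  }
  list(table = rec$table, metadata = rec$metadata, taxonomy = taxonomy, tree = tree)
}

#' Write the standard data bundle into a directory
#' @param bundle list with table/metadata and optional taxonomy, tree,
#'   ground_truth (written as JSON), bathymetry (ESRI ASCII grid).
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$table, file.path(dir, "feature_table.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(bundle$taxonomy))
    write_taxonomy(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(bundle$tree))
    ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  if (!is.null(bundle$ground_truth))
    jsonlite::write_json(ground_truth_serializable(bundle$ground_truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$bathymetry))
    write_esri_grid(bundle$bathymetry, file.path(dir, "bathymetry.asc"))
  invisible(dir)
}

ground_truth_serializable <- function(gt) {
  gt$location_coordinates <- as.data.frame(gt$location_coordinates)
  gt
}

#' Remove low-depth samples and empty features
#'
#' Samples whose library size is strictly less than `min_reads` are removed
#' from table and metadata (exactly `min_reads` reads passes); features left
#' with all-zero rows are pruned afterwards.
#'
#' @param table count matrix. @param metadata matching metadata.
#' @param min_reads minimum library size (default 5000).
#' @return list(table, metadata, removed_samples, removed_features).
#' @export
filter_samples <- function(table, metadata, min_reads = 5000) {
  stopifnot(min_reads >= 0)
  sums <- colSums(table)
  keep <- sums >= min_reads
  if (!any(keep)) stop("min_reads filter removed every sample")
  removed <- colnames(table)[!keep]
  table <- table[, keep, drop = FALSE]
  metadata <- metadata[metadata$sample_id %in% colnames(table), , drop = FALSE]
  metadata <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  empty <- rowSums(table) == 0
  list(table = table[!empty, , drop = FALSE],
       metadata = metadata,
       removed_samples = removed,
       removed_features = rownames(table)[empty])
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts are summed per lineage prefix up to `rank`; features unassigned
#' at that rank are pooled into an explicit `unclassified@rank` row.
#' Column sums are preserved exactly.
#'
#' @param table count matrix. @param taxonomy ranked taxonomy data.frame.
#' @param rank one of domain/phylum/class/order/family/genus.
#' @return aggregated count matrix with lineage-prefix rownames.
#' @export
aggregate_taxa <- function(table, taxonomy, rank) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) stop("unknown rank '", rank, "'; valid: ",
                             paste(ranks, collapse = ", "))
  upto <- ranks[seq_len(match(rank, ranks))]
  tax <- taxonomy[match(rownames(table), taxonomy$feature_id), , drop = FALSE]
  lineage <- apply(tax[, upto, drop = FALSE], 1, function(x) {
    if (any(is.na(x))) NA_character_ else paste(x, collapse = ";")
  })
  lineage[is.na(lineage)] <- paste0("unclassified@", rank)
  agg <- rowsum(table, group = lineage)
  feature_table(agg)
}
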