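#' Construct and validate a feature table
#'
#' The pipeline's central object: a non-negative integer count matrix with
#' features (ASVs or OTUs) as rows and samples as columns, both uniquely
#' named. Stored as a plain base matrix so that all of R's matrix algebra
#' applies; this constructor only validates.
#'
#' @param counts numeric matrix, features x samples, unique dimnames.
#' @return the validated integer matrix.
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)))
    stop("feature table contains missing counts")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  if (any(counts != round(counts)))
    stop("feature table counts must be integers")
  storage.mode(counts) <- "double"   # doubles hold integer counts > .Machine$integer.max safely
  counts
}

#' Validate sample metadata against a feature table
#'
#' Reconciles the sample sets of a count table and a metadata frame by
#' inner join (real bundles are messy); samples present in only one of the
#' two are dropped with a warning. Metadata must carry a `sample_id`
#' column; `sample_type` is one of sponge/seawater/sediment and
#' `sponge_type` (HMA, LMA_demo, LMA_glass) must be non-missing exactly
#' for sponge samples.
#'
#' @param table feature table matrix.
#' @param metadata data.frame with at least `sample_id` and `sample_type`.
#' @return list(table, metadata) restricted to the common samples, metadata
#'   re-ordered to the table's column order.
#' @export
reconcile_samples <- function(table, metadata) {
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  common <- intersect(colnames(table), metadata$sample_id)
  drop_tab <- setdiff(colnames(table), common)
  drop_md <- setdiff(metadata$sample_id, common)
  if (length(drop_tab) || length(drop_md))
    warning(sprintf("dropping %d table sample(s) and %d metadata row(s) without a match",
                    length(drop_tab), length(drop_md)))
  if (length(common) == 0L) stop("no samples shared between table and metadata")
  table <- table[, common, drop = FALSE]
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if ("sample_type" %in% names(metadata)) {
    bad <- setdiff(unique(metadata$sample_type), c("sponge", "seawater", "sediment"))
    if (length(bad)) stop("unknown sample_type value(s): ", paste(bad, collapse = ", "))
    if ("sponge_type" %in% names(metadata)) {
      is_sponge <- metadata$sample_type == "sponge"
      if (any(is_sponge & is.na(metadata$sponge_type)))
        stop("sponge samples must carry a sponge_type")
      if (any(!is_sponge & !is.na(metadata$sponge_type)))
        stop("non-sponge samples must not carry a sponge_type")
    }
  }
  list(table = table, metadata = metadata)
}

#' Construct a distance matrix object
#'
#' Square symmetric matrix with zero diagonal and shared ordered ids.
#'
#' @param values square numeric matrix.
#' @param ids optional ids (defaults to existing dimnames).
#' @return validated symmetric matrix with dimnames.
#' @export
distance_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("distance matrix needs ids")
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  dimnames(values) <- list(ids, ids)
  if (any(values < -1e-12)) stop("distances must be non-negative")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix is not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values
}

#' Off-diagonal lower-triangle vector of a distance matrix
#' @param d distance matrix.
#' @return numeric vector, column-major lower triangle.
#' @export
dist_vector <- function(d) d[lower.tri(d)]
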