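#' Great-circle (haversine) distance in kilometres
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to <- pi / 180
  dphi <- (lat2 - lat1) * to
  dlam <- (lon2 - lon1) * to
  a <- sin(dphi / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise haversine distance matrix
#' @param lat,lon coordinate vectors in degrees.
#' @return symmetric km matrix.
#' @export
haversine_matrix <- function(lat, lon) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n))
    m[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  (m + t(m)) / 2
}

#' Read an ESRI ASCII grid
#'
#' Standard 6-line header (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value) followed by rows from north to south.
#'
#' @param path file path.
#' @return a `bathymetry` list (`lat` descending, `lon` ascending,
#'   `elevation`, `nodata`).
#' @export
read_esri_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI grid header incomplete; need ", paste(need, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ESRI grid has wrong number of values")
  elev <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  elev[elev == nodata] <- NA
  lat <- hdr$yllcorner + hdr$cellsize * (nr - seq_len(nr) + 0.5)
  lon <- hdr$xllcorner + hdr$cellsize * (seq_len(nc) - 0.5)
  structure(list(lat = lat, lon = lon, elevation = elev, nodata = nodata),
            class = "bathymetry")
}

#' Write an ESRI ASCII grid
#' @param grid a `bathymetry` list with square cells.
#' @param path destination.
#' @export
write_esri_grid <- function(grid, path) {
  cs_lat <- abs(mean(diff(grid$lat)))
  cs_lon <- mean(diff(grid$lon))
  if (abs(cs_lat - cs_lon) > 1e-9 * max(cs_lat, cs_lon))
    stop("ESRI ASCII requires square cells (equal lat/lon spacing)")
  nr <- length(grid$lat); nc <- length(grid$lon)
  elev <- grid$elevation
  elev[is.na(elev)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", min(grid$lon) - cs_lon / 2),
           sprintf("yllcorner %.10f", min(grid$lat) - cs_lat / 2),
           sprintf("cellsize %.10f", cs_lon),
           sprintf("NODATA_value %s", format(grid$nodata)))
  body <- apply(elev, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Navigable-sea graph from a bathymetry grid
#'
#' Cells with elevation <= -`depth_threshold_m` are navigable; edges join
#' 8-neighbours (or 16: additionally knight moves) whose endpoints are both
#' navigable, weighted by the great-circle distance between cell centres.
#'
#' @param grid `bathymetry` object.
#' @param depth_threshold_m minimum water depth in metres (default 200).
#' @param neighbourhood 8 or 16.
#' @return list(graph: igraph, cells: data.frame(row, col, lat, lon) of
#'   navigable cells, node id = row index in `cells`).
#' @export
sea_graph <- function(grid, depth_threshold_m = 200, neighbourhood = 16) {
  stopifnot(neighbourhood %in% c(8, 16))
  nav <- !is.na(grid$elevation) & grid$elevation <= -depth_threshold_m
  nr <- nrow(nav); nc <- ncol(nav)
  idx <- matrix(NA_integer_, nr, nc)
  cells <- which(nav, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no navigable cells at this depth threshold")
  idx[cells] <- seq_len(nrow(cells))
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (neighbourhood == 16)
    offs <- rbind(offs, c(1, 2), c(2, 1), c(-1, 2), c(-2, 1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  cl <- grid$lat[cells[, 1]]; cn <- grid$lon[cells[, 2]]
  for (k in seq_len(nrow(offs))) {
    r2 <- cells[, 1] + offs[k, 1]
    c2 <- cells[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- nav[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    j <- idx[cbind(r2[ok], c2[ok])]
    i <- idx[cells[ok, , drop = FALSE]]
    from <- c(from, i); to <- c(to, j)
    w <- c(w, haversine_km(cl[ok], cn[ok], grid$lat[r2[ok]], grid$lon[c2[ok]]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(cells))))
  list(graph = g,
       cells = data.frame(row = cells[, 1], col = cells[, 2],
                          lat = cl, lon = cn))
}

#' Depth-constrained least-cost sea distances between sites
#'
#' Each site is snapped to its nearest navigable cell (haversine); pairwise
#' distances are shortest paths on the navigable-sea graph (Dijkstra).
#' Pairs in different connected components get `Inf` with a warning.
#'
#' @param grid `bathymetry` object.
#' @param sites data.frame with `site_id` (optional), `lat`, `lon`.
#' @param depth_threshold_m minimum water depth (m), default 200.
#' @param neighbourhood 8 or 16 (default 16).
#' @param max_snap_km maximum snapping distance; a site farther than this
#'   from any navigable cell is an error.
#' @return km distance matrix with site ids.
#' @export
least_cost_distances <- function(grid, sites, depth_threshold_m = 200,
                                 neighbourhood = 16, max_snap_km = 100) {
  stopifnot(nrow(sites) >= 2)
  ids <- if ("site_id" %in% names(sites)) as.character(sites$site_id)
         else sprintf("site%02d", seq_len(nrow(sites)))
  sg <- sea_graph(grid, depth_threshold_m, neighbourhood)
  snap <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    d <- haversine_km(sites$lat[i], sites$lon[i], sg$cells$lat, sg$cells$lon)
    j <- which.min(d)
    if (d[j] > max_snap_km)
      stop(sprintf("site '%s' is %.1f km from the nearest navigable cell (max_snap_km = %g)",
                   ids[i], d[j], max_snap_km))
    snap[i] <- j
  }
  dm <- igraph::distances(sg$graph, v = as.character(snap),
                          to = as.character(snap), algorithm = "dijkstra")
  dimnames(dm) <- list(ids, ids)
  if (any(!is.finite(dm[lower.tri(dm)])))
    warning("some site pairs are not connected by sea at this depth threshold")
  dm
}

#' Distance-decay regression and Mantel test
#'
#' Ordinary least squares of log10(community dissimilarity) on
#' log10(geographic distance) over site pairs, plus a two-sided Mantel
#' permutation test between the raw matrices. Pairs with zero or
#' non-finite geographic distance (or non-positive dissimilarity) are
#' excluded from the log-log fit; their count is reported.
#'
#' @param community_dist,geo_dist distance matrices with matching ids.
#' @param n_permutations Mantel permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param method Mantel correlation, "pearson" (default) or "spearman".
#' @return list(slope, intercept, r_squared, adj_r_squared, mantel_r,
#'   mantel_p, n_pairs, n_dropped).
#' @export
distance_decay <- function(community_dist, geo_dist, n_permutations = 999,
                           seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(rownames(community_dist), rownames(geo_dist)))
    stop("distance matrices must share identical ids in identical order")
  cd <- dist_vector(community_dist)
  gd <- dist_vector(geo_dist)
  use <- is.finite(gd) & gd > 0 & is.finite(cd) & cd > 0
  if (sum(use) < 3) stop("fewer than 3 usable pairs for the log-log fit")
  fit <- stats::lm(log10(cd[use]) ~ log10(gd[use]))
  sm <- summary(fit)
  mt <- mantel_test(community_dist, geo_dist, n_permutations = n_permutations,
                    seed = seed, method = method)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       adj_r_squared = sm$adj.r.squared,
       mantel_r = mt$statistic,
       mantel_p = mt$p_value,
       n_pairs = sum(use),
       n_dropped = sum(!use))
}
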