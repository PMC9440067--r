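#' Simulation configuration for the synthetic sponge-ground dataset
#'
#' The generator emulates the sampling design of a multi-expedition
#' deep-sea sponge survey at desk scale: three sponge types (HMA, LMA
#' demosponges, LMA glass sponges) with a balanced host taxonomy
#' (species-genus-family-order-class), seawater and sediment reference
#' samples, several sponge-ground locations along a transect, planted
#' species-specific and exclusive ASVs, planted core ASVs, exponential
#' compositional turnover with distance, and log-linear environmental
#' effects on designated taxa. Counts are Dirichlet-multinomial.
#'
#' @param seed integer; identical seed and config give bit-identical output.
#' @param n_species_per_type named integer vector (HMA, LMA_demo, LMA_glass).
#' @param samples_per_species sponge individuals sampled per species.
#' @param n_reference_samples named vector (seawater, sediment).
#' @param n_locations number of sponge-ground locations (>= 2 when
#'   `decay_rate > 0`).
#' @param location_spacing_km along-transect distance between neighbours.
#' @param n_background_asvs size of the shared environmental ASV pool.
#' @param n_specific_asvs_per_species planted private ASVs per species
#'   (half planted exclusive, half sporadic).
#' @param n_core_asvs ASVs planted in every sponge sample (prevalence 1).
#' @param exclusive_prevalence per-sample presence probability of planted
#'   exclusive ASVs within their species, in (0, 1].
#' @param richness_mean_by_type expected baseline ASVs per sample by type;
#'   HMA larger than LMA reproduces the richness dichotomy.
#' @param decay_rate per-km exponential attenuation of an ASV's expected
#'   abundance away from its origin location (>= 0).
#' @param env_effect_size log-scale slope per standardised environmental
#'   covariate for responder taxa.
#' @param depth_distribution c(meanlog, sdlog) of the lognormal library size.
#' @param dispersion Dirichlet concentration (> 0); `Inf` = no
#'   compositional overdispersion.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species_per_type = c(HMA = 6L, LMA_demo = 6L, LMA_glass = 4L),
                       samples_per_species = 6L,
                       n_reference_samples = c(seawater = 20L, sediment = 10L),
                       n_locations = 8L,
                       location_spacing_km = 300,
                       n_background_asvs = 300L,
                       n_specific_asvs_per_species = 8L,
                       n_core_asvs = 3L,
                       exclusive_prevalence = 1,
                       richness_mean_by_type = c(HMA = 120, LMA_demo = 50, LMA_glass = 40),
                       decay_rate = 0.001,
                       env_effect_size = 0.5,
                       depth_distribution = c(meanlog = log(2e4), sdlog = 0.4),
                       dispersion = 200) {
  stopifnot(all(n_species_per_type >= 1), samples_per_species >= 1,
            all(n_reference_samples >= 0), n_background_asvs >= 10,
            n_specific_asvs_per_species >= 0, n_core_asvs >= 0,
            exclusive_prevalence > 0, exclusive_prevalence <= 1,
            decay_rate >= 0, location_spacing_km > 0)
  if (!is.finite(dispersion) && !is.infinite(dispersion) || dispersion <= 0)
    stop("dispersion must be a positive number (Inf allowed)")
  if (n_locations < 2 && decay_rate > 0)
    stop("decay_rate > 0 requires at least 2 locations")
  if (!all(c("HMA", "LMA_demo", "LMA_glass") %in% names(n_species_per_type)))
    stop("n_species_per_type must name HMA, LMA_demo and LMA_glass")
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

env_param_names <- function() {
  c("depth", "temperature", "salinity", "nitrate", "phosphate", "silicate",
    "oxygen", "doc", "poc", "chlorophyll", "current_speed",
    "mixed_layer_depth", "sigma_theta", "pressure", "turbidity", "ph",
    "alkalinity", "aou", "par", "bottom_slope", "distance_to_coast",
    "sst", "poc_flux", "ice_cover")
}

# Deterministic generation plan: everything except the count draws.
# Consumes the RNG stream opened by the caller (under config$seed).
simulate_plan <- function(config) {
  types <- c("HMA", "LMA_demo", "LMA_glass")
  nsp <- config$n_species_per_type[types]
  species <- unlist(lapply(types, function(t)
    sprintf("%s_sp%02d", t, seq_len(nsp[[t]]))))
  sp_type <- setNames(rep(types, nsp), species)

  # balanced host taxonomy within each type; glass sponges form their own class
  host_tax <- do.call(rbind, lapply(types, function(t) {
    sp <- species[sp_type == t]
    i <- seq_along(sp)
    data.frame(species = sp,
               genus = sprintf("%s_gen%02d", t, ceiling(i / 2)),
               family = sprintf("%s_fam%02d", t, ceiling(i / 4)),
               order = sprintf("%s_ord%02d", t, ceiling(i / 8)),
               class = if (t == "LMA_glass") "Hexactinellida" else "Demospongiae",
               stringsAsFactors = FALSE)
  }))

  # locations on a constant-latitude transect
  lat0 <- 60
  dlon <- config$location_spacing_km / (111.32 * cos(lat0 * pi / 180))
  loc <- data.frame(location_id = sprintf("loc%02d", seq_len(config$n_locations)),
                    lat = lat0,
                    lon = -40 + (seq_len(config$n_locations) - 1) * dlon,
                    stringsAsFactors = FALSE)
  loc_dist <- haversine_matrix(loc$lat, loc$lon)
  dimnames(loc_dist) <- list(loc$location_id, loc$location_id)

  B <- config$n_background_asvs
  bg_ids <- sprintf("bg%04d", seq_len(B))
  bg_abund <- rlnorm(B, 0, 1)                       # pool-level base intensity
  bg_origin <- sample.int(config$n_locations, B, replace = TRUE)
  decay_factor <- exp(-config$decay_rate * loc_dist[bg_origin, , drop = FALSE])

  # type/reference baselines: overlapping subsets of the shared pool
  incl_p <- pmin(config$richness_mean_by_type[types] / B, 1)
  type_incl <- sapply(types, function(t) runif(B) < incl_p[[t]])
  sw_incl <- runif(B) < 0.5
  sed_incl <- runif(B) < 0.4
  # every background ASV reaches a reference community, so only planted
  # private ASVs can ever satisfy the host-specificity definition
  sed_incl <- sed_incl | !sw_incl

  # environmental responders among the background pool
  n_resp <- min(40L, B)
  responders <- sort(sample.int(B, n_resp))
  resp_param <- sample(c("temperature", "salinity", "depth", "nitrate", "oxygen"),
                       n_resp, replace = TRUE)
  resp_sign <- sample(c(-1, 1), n_resp, replace = TRUE)

  # planted private ASVs per species (half exclusive, half sporadic)
  nspec <- config$n_specific_asvs_per_species
  spec_ids <- if (nspec > 0)
    unlist(lapply(species, function(s) sprintf("%s_asv%02d", s, seq_len(nspec))))
  else character(0)
  spec_owner <- setNames(rep(species, each = nspec), spec_ids)
  n_excl <- ceiling(nspec / 2)
  spec_role <- setNames(rep(rep(c("exclusive", "sporadic"),
                                c(n_excl, nspec - n_excl)), length(species)),
                        spec_ids)
  core_ids <- if (config$n_core_asvs > 0)
    sprintf("core%02d", seq_len(config$n_core_asvs)) else character(0)
  feature_ids <- c(bg_ids, spec_ids, core_ids)

  # samples: sponges then references, locations assigned uniformly
  sponge_samples <- data.frame(
    sample_id = sprintf("sp_%03d", seq_len(length(species) * config$samples_per_species)),
    sample_type = "sponge",
    species = rep(species, each = config$samples_per_species),
    stringsAsFactors = FALSE)
  n_ref <- config$n_reference_samples
  ref_samples <- data.frame(
    sample_id = c(sprintf("sw_%03d", seq_len(n_ref[["seawater"]])),
                  sprintf("sd_%03d", seq_len(n_ref[["sediment"]]))),
    sample_type = rep(c("seawater", "sediment"), n_ref[c("seawater", "sediment")]),
    species = NA_character_, stringsAsFactors = FALSE)
  samples <- rbind(sponge_samples, ref_samples)
  samples$location_id <- loc$location_id[
    sample.int(config$n_locations, nrow(samples), replace = TRUE)]

  # environmental parameters: location-driven gradients + sample noise
  li <- match(samples$location_id, loc$location_id)
  grad <- scale(li)[, 1]
  env <- sapply(env_param_names(), function(p) {
    slope <- switch(p, temperature = -1, salinity = 0.8, depth = 1.2,
                    nitrate = 0.9, phosphate = 0.85, silicate = 0.9,
                    oxygen = -0.7, pressure = 1.2, sigma_theta = 0.6,
                    runif(1, -0.5, 0.5))
    base <- switch(p, temperature = 4, salinity = 35, depth = 800,
                   oxygen = 280, 0)
    sd_ <- switch(p, depth = 250, oxygen = 25, 1)
    base + sd_ * (slope * grad + rnorm(nrow(samples), 0, 0.3))
  })
  rownames(env) <- samples$sample_id
  env_z <- scale(env)

  # presence plans for planted ASVs (deterministic per sample)
  ns <- config$samples_per_species
  presence <- matrix(FALSE, nrow = length(spec_ids), ncol = nrow(samples),
                     dimnames = list(spec_ids, samples$sample_id))
  for (s in species) {
    rows_here <- which(samples$species %in% s)
    for (a in spec_ids[spec_owner == s]) {
      if (spec_role[[a]] == "exclusive") {
        presence[a, rows_here] <- if (config$exclusive_prevalence >= 1) TRUE
          else runif(ns) < config$exclusive_prevalence
      } else {
        presence[a, rows_here[seq_len(ceiling(ns / 2))]] <- TRUE   # fixed prevalence ~0.5, never > 0.9
      }
    }
  }

  leak <- c(HMA = 0.05, LMA_demo = 0.25, LMA_glass = 0.25)
  w_excl <- 5; w_spor <- 2; w_core <- 8

  # per-sample expected (unnormalised) intensity over all features
  mean_intensity <- matrix(0, nrow = length(feature_ids), ncol = nrow(samples),
                           dimnames = list(feature_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    lj <- li[j]
    att <- decay_factor[, lj]
    envf <- rep(1, B)
    z <- env_z[j, resp_param]
    envf[responders] <- exp(config$env_effect_size * resp_sign * z)
    bg <- bg_abund * att * envf
    stype <- samples$sample_type[j]
    if (stype == "sponge") {
      t <- sp_type[[samples$species[j]]]
      m_bg <- (1 - leak[[t]]) * bg * type_incl[, t] + leak[[t]] * bg * sw_incl
      m <- c(m_bg, numeric(length(spec_ids)), rep(w_core, length(core_ids)))
      names(m) <- feature_ids
      pres <- presence[, j]
      if (length(spec_ids))
        m[spec_ids] <- ifelse(pres, ifelse(spec_role == "exclusive", w_excl, w_spor), 0)
    } else if (stype == "seawater") {
      m <- c(bg * sw_incl, numeric(length(spec_ids) + length(core_ids)))
    } else {
      m <- c(bg * sed_incl, numeric(length(spec_ids) + length(core_ids)))
    }
    mean_intensity[, j] <- m
  }

  list(config = config, species = species, sp_type = sp_type,
       host_tax = host_tax, locations = loc, loc_dist = loc_dist,
       samples = samples, env = env, feature_ids = feature_ids,
       bg_ids = bg_ids, bg_abund = bg_abund, bg_origin = bg_origin,
       spec_ids = spec_ids, spec_owner = spec_owner, spec_role = spec_role,
       core_ids = core_ids, presence = presence,
       mean_intensity = mean_intensity,
       responders = bg_ids[responders], resp_param = resp_param)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic sponge-ground dataset with ground truth
#'
#' Draws per-sample counts as library-size-many Dirichlet-multinomial draws
#' around the configured expected composition. See [sim_config()] for the
#' generative model. The returned ground truth records every planted label.
#'
#' @param config a [sim_config()].
#' @return list with `table` (feature x sample counts), `metadata`,
#'   `taxonomy`, `tree` (`ape::phylo`), and `ground_truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    plan <- simulate_plan(config)
    n_samp <- nrow(plan$samples)
    libsize <- pmax(1, round(rlnorm(n_samp, config$depth_distribution[["meanlog"]],
                                    config$depth_distribution[["sdlog"]])))
    counts <- matrix(0, nrow = length(plan$feature_ids), ncol = n_samp,
                     dimnames = list(plan$feature_ids, plan$samples$sample_id))
    for (j in seq_len(n_samp)) {
      m <- plan$mean_intensity[, j]
      pos <- which(m > 0)
      p <- m[pos] / sum(m[pos])
      if (is.finite(config$dispersion))
        p <- rdirichlet1(config$dispersion * p)
      counts[pos, j] <- rmultinom(1, libsize[j], p)[, 1]
    }

    md <- plan$samples
    ht <- plan$host_tax[match(md$species, plan$host_tax$species), ]
    md$sponge_type <- ifelse(md$sample_type == "sponge",
                             unname(plan$sp_type[md$species]), NA_character_)
    md$host_species <- md$species
    md$host_genus <- ht$genus; md$host_family <- ht$family
    md$host_order <- ht$order; md$host_class <- ht$class
    md$species <- NULL
    md$lat <- plan$locations$lat[match(md$location_id, plan$locations$location_id)]
    md$lon <- plan$locations$lon[match(md$location_id, plan$locations$location_id)]
    md <- cbind(md, as.data.frame(plan$env))

    taxonomy <- synth_taxonomy(plan$feature_ids)
    tree <- generate_tree(plan$feature_ids, seed = config$seed + 1L)
    gt <- ground_truth_from_plan(plan)
    list(table = feature_table(counts), metadata = md, taxonomy = taxonomy,
         tree = tree, ground_truth = gt)
  })
}

# planted labels at every host rank, mapped upward from the species plants
ground_truth_from_plan <- function(plan) {
  ranks <- c("species", "genus", "family", "order", "class")
  spec_by_rank <- lapply(ranks, function(r) {
    grp <- if (r == "species") plan$host_tax$species else plan$host_tax[[r]]
    owners_grp <- setNames(grp[match(plan$spec_owner, plan$host_tax$species)],
                           names(plan$spec_owner))
    split(names(owners_grp), owners_grp)
  })
  names(spec_by_rank) <- ranks
  excl_ids <- names(plan$spec_role)[plan$spec_role == "exclusive"]
  # exclusivity (>90% within-group prevalence) only survives to a coarser
  # rank when the group still consists of the single owner species
  excl_by_rank <- lapply(ranks, function(r) {
    grp <- if (r == "species") plan$host_tax$species else plan$host_tax[[r]]
    singles <- names(which(table(grp) == 1))
    owners_grp <- setNames(grp[match(plan$spec_owner, plan$host_tax$species)],
                           names(plan$spec_owner))
    keep <- owners_grp %in% singles & names(owners_grp) %in% excl_ids
    split(names(owners_grp)[keep], owners_grp[keep])
  })
  names(excl_by_rank) <- ranks
  list(specific_asv_labels = spec_by_rank,
       exclusive_asv_labels = excl_by_rank,
       membership_labels = setNames(rep("core", length(plan$core_ids)), plan$core_ids),
       hma_lma_labels = setNames(ifelse(plan$sp_type == "HMA", "HMA", "LMA"),
                                 names(plan$sp_type)),
       sponge_type_labels = plan$sp_type,
       location_coordinates = plan$locations,
       planted_decay_rate = plan$config$decay_rate,
       env_responders = plan$responders)
}

synth_taxonomy <- function(feature_ids) {
  phyla <- c("Proteobacteria", "Chloroflexi", "Acidobacteriota",
             "Actinobacteriota", "Bacteroidota", "Dadabacteria",
             "Nitrospirota", "Spirochaetota", "Poribacteria",
             "Planctomycetota", "Verrucomicrobiota", "Patescibacteria",
             "Gemmatimonadota", "Myxococcota", "Entotheonellaeota")
  n <- length(feature_ids)
  ph <- sample(phyla, n, replace = TRUE)
  cl <- paste0(ph, "_c", sample.int(2, n, replace = TRUE))
  or <- paste0(cl, "_o", sample.int(2, n, replace = TRUE))
  fam <- ifelse(runif(n) < 0.4, NA_character_,
                paste0(or, "_f", sample.int(2, n, replace = TRUE)))
  gen <- ifelse(is.na(fam) | runif(n) < 0.3, NA_character_, paste0(fam, "_g1"))
  unph <- runif(n) < 0.05                          # some unclassified at phylum
  data.frame(feature_id = feature_ids,
             domain = "Bacteria",
             phylum = ifelse(unph, NA_character_, ph),
             class = ifelse(unph, NA_character_, cl),
             order = ifelse(unph, NA_character_, or),
             family = ifelse(unph, NA_character_, fam),
             genus = ifelse(unph, NA_character_, gen),
             stringsAsFactors = FALSE)
}

#' Expected composition under a simulation configuration
#'
#' Evaluates the generative mean without drawing counts: the per-sample
#' expected relative abundances (closed form of the Dirichlet-multinomial
#' mean), plus the per-location expected background composition used by
#' distance-decay oracles.
#'
#' @param config a [sim_config()].
#' @return list(sample_composition: features x samples proportions,
#'   location_composition: background features x locations proportions,
#'   samples, locations, loc_dist).
#' @export
expected_composition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    plan <- simulate_plan(config)
    comp <- sweep(plan$mean_intensity, 2, colSums(plan$mean_intensity), "/")
    att <- exp(-config$decay_rate *
                 plan$loc_dist[plan$bg_origin, , drop = FALSE])
    locmat <- plan$bg_abund * att
    locmat <- sweep(locmat, 2, colSums(locmat), "/")
    rownames(locmat) <- plan$bg_ids
    list(sample_composition = comp, location_composition = locmat,
         samples = plan$samples, locations = plan$locations,
         loc_dist = plan$loc_dist)
  })
}

#' Generate a synthetic bathymetry raster
#'
#' Regular lat/lon elevation grid (metres, negative below sea level) built
#' from a flat abyssal base plus requested primitives, in order: `shelf`
#' (raise a margin of the grid), `ridge` (raise one full row or column,
#' optionally leaving a gap cell open), `basin` (deepen a disc).
#' Deterministic for a seed.
#'
#' @param extent c(lat_min, lat_max, lon_min, lon_max), degrees.
#' @param shape c(nrows, ncols).
#' @param features list of primitives, each a list with `type` and
#'   type-specific fields (see Details in the source).
#' @param seed integer seed for the small roughness field.
#' @param base_elevation abyssal base (m), default -4000.
#' @param noise_sd roughness standard deviation (m), 0 for none.
#' @return a `bathymetry` list: `lat` (descending centres), `lon`
#'   (ascending centres), `elevation` (nrows x ncols), `nodata`.
#' @export
generate_bathymetry <- function(extent, shape, features = list(), seed = 1L,
                                base_elevation = -4000, noise_sd = 0) {
  stopifnot(length(extent) == 4, length(shape) == 2, all(shape >= 2))
  if (extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("extent must be c(lat_min, lat_max, lon_min, lon_max) with min < max")
  nr <- shape[1]; nc <- shape[2]
  cs_lat <- (extent[2] - extent[1]) / nr
  cs_lon <- (extent[4] - extent[3]) / nc
  lat <- extent[2] - cs_lat * (seq_len(nr) - 0.5)   # north to south
  lon <- extent[3] + cs_lon * (seq_len(nc) - 0.5)
  with_seed(seed, {
    elev <- matrix(base_elevation, nr, nc)
    if (noise_sd > 0) elev <- elev + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    for (f in features) {
      elev <- switch(f$type,
        shelf = {
          w <- f$width_cells
          switch(f$side,
                 W = {elev[, seq_len(w)] <- f$elevation; elev},
                 E = {elev[, nc - seq_len(w) + 1] <- f$elevation; elev},
                 N = {elev[seq_len(w), ] <- f$elevation; elev},
                 S = {elev[nr - seq_len(w) + 1, ] <- f$elevation; elev},
                 stop("shelf side must be one of W/E/N/S"))
        },
        ridge = {
          if (f$orientation == "EW") {
            elev[f$index, ] <- f$elevation
            if (!is.null(f$gap)) elev[f$index, f$gap] <- base_elevation
          } else {
            elev[, f$index] <- f$elevation
            if (!is.null(f$gap)) elev[f$gap, f$index] <- base_elevation
          }
          elev
        },
        basin = {
          for (i in seq_len(nr)) for (j in seq_len(nc))
            if ((i - f$center[1])^2 + (j - f$center[2])^2 <= f$radius_cells^2)
              elev[i, j] <- f$elevation
          elev
        },
        stop("unknown bathymetry primitive '", f$type, "'"))
    }
    structure(list(lat = lat, lon = lon, elevation = elev, nodata = -9999),
              class = "bathymetry")
  })
}

#' Generate a random rooted binary tree over feature ids
#'
#' Coalescent-style: lineages are joined uniformly at random until one
#' remains; every branch length is an independent Exponential(`rate`) draw.
#'
#' @param feature_ids unique leaf labels (>= 2).
#' @param seed integer seed.
#' @param rate exponential rate for branch lengths.
#' @return an `ape::phylo` rooted binary tree with `length(feature_ids)`
#'   tips and `length(feature_ids) - 1` internal nodes.
#' @export
generate_tree <- function(feature_ids, seed = 1L, rate = 1) {
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  n <- length(feature_ids)
  if (n < 2) stop("need at least 2 features")
  with_seed(seed, {
    nodes <- as.list(feature_ids)
    while (length(nodes) > 1) {
      pick <- sample.int(length(nodes), 2)
      len <- rexp(2, rate)
      merged <- sprintf("(%s:%.10f,%s:%.10f)",
                        nodes[[pick[1]]], len[1], nodes[[pick[2]]], len[2])
      nodes <- c(nodes[-pick], merged)
    }
    ape::read.tree(text = paste0(nodes[[1]], ";"))
  })
}
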