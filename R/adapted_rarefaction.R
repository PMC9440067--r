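#' Adapted rarefaction: microbial richness versus number of host species
#'
#' For a sponge type with S species: for each n in 1..S and each replicate,
#' draw n species uniformly without replacement from the type's full
#' species set (each step is independent of the previous one), pool all
#' their samples, and count the features with pooled count > 0. The curve
#' plateau is the type's "microbiome carrying capacity".
#'
#' @param table count matrix. @param metadata matching metadata with
#'   `sponge_type` and `host_species`.
#' @param sponge_type one of the types present in the metadata.
#' @param replicates resampling replicates per step (default 100).
#' @param seed RNG seed.
#' @return data.frame(n_species, mean_richness, sd, q025, q975) with
#'   attribute `replicates`; the value at n = S is the type's total
#'   richness with zero variance.
#' @export
adapted_rarefaction <- function(table, metadata, sponge_type,
                                replicates = 100, seed = 1L) {
  stopifnot(replicates >= 1)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sel <- md$sample_type == "sponge" & !is.na(md$sponge_type) &
    md$sponge_type == sponge_type
  if (!any(sel)) stop("unknown or empty sponge type '", sponge_type, "'")
  spp <- md$host_species[sel]
  species <- unique(spp)
  S <- length(species)
  # presence of each feature per species (pooled over the species' samples)
  sub <- table[, sel, drop = FALSE] > 0
  sp_pres <- sapply(species, function(s)
    rowSums(sub[, spp == s, drop = FALSE]) > 0)
  with_seed(seed, {
    rows <- lapply(seq_len(S), function(n) {
      rich <- replicate(replicates, {
        pick <- sample.int(S, n)
        sum(rowSums(sp_pres[, pick, drop = FALSE]) > 0)
      })
      data.frame(n_species = n, mean_richness = mean(rich),
                 sd = stats::sd(rich),
                 q025 = unname(stats::quantile(rich, 0.025)),
                 q975 = unname(stats::quantile(rich, 0.975)))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- replicates
  attr(out, "total_richness") <- sum(rowSums(sp_pres) > 0)
  out
}

#' Michaelis-Menten style asymptote estimate for a rarefaction curve
#'
#' Convenience extension (not part of the original procedure): fits
#' richness ~ a * n / (b + n) by `nls` and reports the asymptote `a`.
#'
#' @param curve output of [adapted_rarefaction()].
#' @return list(asymptote, half_saturation) or NULL if the fit fails.
#' @export
rarefaction_asymptote <- function(curve) {
  fit <- try(stats::nls(mean_richness ~ a * n_species / (b + n_species),
                        data = curve,
                        start = list(a = max(curve$mean_richness) * 1.2, b = 1)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  co <- stats::coef(fit)
  list(asymptote = unname(co["a"]), half_saturation = unname(co["b"]))
}
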