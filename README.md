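# spongiome

An R package for analysing host-associated 16S amplicon data from
deep-sea sponge grounds — the dense sponge-dominated habitats of the deep
ocean whose holobionts (sponge + microbiome) are both biodiversity
hotspots and conservation targets. The package takes an ASV count table,
sample metadata (host taxonomy, sponge type, location, environment), a
feature phylogeny and a bathymetry raster, and computes the full analysis
arc of a basin-scale sponge microbiome survey:

* alpha/beta diversity: Shannon (bits), Pielou, Faith's PD, weighted
  UniFrac `D(A,B) = Σ_b l_b |p_Ab − p_Bb|`, Jaccard, Bray–Curtis;
* core/variable/individual membership across sequence-clustering
  thresholds (ASV, 99/97/95/90% OTUs), with the strict ">70% of sponge
  samples" core rule;
* host-specific ASVs (present in exactly one group at a host rank, absent
  from seawater/sediment references) and exclusive ASVs (specific with
  within-group prevalence > 90%);
* adapted rarefaction — richness versus number of host species — whose
  plateau is a sponge type's "microbiome carrying capacity";
* least-cost sea distances below 200 m water depth (Dijkstra on a
  navigable bathymetry graph) and log–log distance-decay with Mantel
  tests;
* permutation statistics from first principles: Dunn's rank test,
  PERMANOVA (pseudo-F = (SS_B/(k−1))/(SS_W/(N−k))), Mantel, RDA adjusted
  R², and variation partitioning over up to four predictor sets with
  exact inclusion–exclusion fractions — the "driver ranking";
* similarity/bipartite/weighted-correlation networks (betweenness, Zi–Pi
  roles, topological-overlap modules, kME, module–trait correlations) and
  a LEfSe-like indicator-taxon screen;
* an HMA/LMA (high/low microbial abundance) status classifier — a
  self-contained random forest on phylum+class profiles — and
  temperature–salinity water-mass classification;
* a seeded synthetic-data generator (`sim_config()`, `generate_dataset()`)
  that emulates the survey design (3 sponge types, host taxonomy
  hierarchy, reference samples, planted specific/exclusive/core ASVs,
  spatial decay, environmental effects) with full ground-truth labels, so
  every stage is testable without any download.

## Worked example

```r
library(spongiome)

ds <- generate_dataset(sim_config(seed = 42))   # synthetic survey + truth
fl <- filter_samples(ds$table, ds$metadata, min_reads = 5000)

rt <- rarefy(fl$table, 5000, seed = 42)
al <- alpha_diversity(rt, ds$tree)
md <- fl$metadata[match(colnames(rt), fl$metadata$sample_id), ]
tapply(al$shannon, md$sample_type, function(x) round(mean(x), 2))
#> seawater sediment   sponge
#>     5.86     6.34     5.45

sponge <- md$sample_type == "sponge"
mem <- classify_membership(fl$table[, md$sample_id[sponge]], core_fraction = 0.7)
table(mem$category)                       # 110 sponge samples -> core means
#>     core variable                      # occurrence >= 68 (floor(0.7*110)+1)
#>       47      317

sp <- host_specific_asvs(fl$table, fl$metadata, "species")
sp <- exclusive_asvs(sp, fl$table, fl$metadata, prevalence_threshold = 0.9)
length(unlist(sp$specific)); length(unlist(sp$exclusive))
#> [1] 128
#> [1] 64

y <- hellinger(t(fl$table[, md$sample_id[sponge]]))
sets <- list(status      = dummy_code(md$sponge_type[sponge], "st"),
             location    = dummy_code(md$location_id[sponge], "loc"),
             environment = scale(as.matrix(md[sponge,
                             c("temperature", "salinity", "depth",
                               "nitrate", "oxygen")])))
vp <- variation_partitioning(y, sets, n_permutations = 999, seed = 42)
round(100 * vp$unique_fractions, 1); vp$ranking
#>      status    location environment
#>        31.0         1.3         0.4
#> [1] "status"      "location"    "environment"
```

Reading the output: sponge samples carry a lower mean Shannon diversity
than their reference environment; 317 of the classified units are
"variable" and 47 "core" under the strict 70% rule (for this 110-sample
synthetic survey the core boundary is 68 occurrences); all 128 planted
host-specific ASVs are found, 64 of them exclusive; and the variation
partitioning ranks sponge HMA/LMA status far above location above
environment — the planted driver ordering (all three marginal models
significant at p = 0.001 with 999 permutations).

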