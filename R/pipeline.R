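pipeline_stages <- function() {
  c("simulate", "filter", "diversity", "membership", "specificity",
    "rarefaction")
}

stage_deps <- function() {
  list(simulate = character(0),
       filter = "simulate",
       diversity = "filter",
       membership = "filter",
       specificity = "filter",
       rarefaction = "filter")
}

#' Run pipeline stages into a report directory
#'
#' Executes the requested stages in dependency order. Every stage writes
#' its TSV/JSON outputs into `<out>/<stage>/` together with a `log.json`
#' recording the seed and an md5 hash of the configuration. Re-running
#' with the same seed reproduces identical numeric outputs.
#'
#' @param config either a path to a JSON config file or a list with
#'   elements `sim` (arguments for [sim_config()]) and `analysis`
#'   (arguments for [analysis_config()]).
#' @param out output directory.
#' @param stages character vector of stages (see `spongiome:::pipeline_stages`).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, out, stages = pipeline_stages()) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(stages, pipeline_stages())
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; valid stages: ", paste(pipeline_stages(), collapse = ", "))
  if (length(stages) == 0) stop("stage list is empty")
  deps <- stage_deps()
  ordered <- intersect(pipeline_stages(), stages)
  simc <- do.call(sim_config, as.list(config$sim %||% list()))
  anc <- do.call(analysis_config, as.list(config$analysis %||% list()))
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(sim = unclass(simc), analysis = unclass(anc)),
                       cfg_file, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())

  need <- function(stage, what) {
    if (!exists(what, envir = state))
      stop("stage '", stage, "' requires output of stage '",
           deps[[stage]], "' which has not been run")
    get(what, envir = state)
  }
  log_stage <- function(stage, dir) {
    jsonlite::write_json(list(stage = stage, seed = anc$seed,
                              config_md5 = cfg_hash,
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         file.path(dir, "log.json"), auto_unbox = TRUE)
  }
  for (stage in ordered) {
    sdir <- file.path(out, stage)
    dir.create(sdir, showWarnings = FALSE)
    if (stage == "simulate") {
      ds <- generate_dataset(simc)
      write_bundle(ds, sdir)
      assign("dataset", ds, envir = state)
    } else if (stage == "filter") {
      ds <- need(stage, "dataset")
      fl <- filter_samples(ds$table, ds$metadata, anc$min_reads)
      write_feature_table(fl$table, file.path(sdir, "feature_table.tsv"))
      write_metadata(fl$metadata, file.path(sdir, "metadata.tsv"))
      assign("filtered", fl, envir = state)
    } else if (stage == "diversity") {
      fl <- need(stage, "filtered"); ds <- get("dataset", envir = state)
      rt <- rarefy(fl$table, min(anc$rarefaction_depth, min(colSums(fl$table))),
                   seed = anc$seed)
      al <- alpha_diversity(rt, ds$tree)
      utils::write.table(al, file.path(sdir, "alpha.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      bd <- beta_diversity(rt, "weighted_unifrac", tree = ds$tree)
      utils::write.table(data.frame(sample_id = rownames(bd), bd,
                                    check.names = FALSE),
                         file.path(sdir, "weighted_unifrac.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (stage == "membership") {
      fl <- need(stage, "filtered")
      sponge <- fl$metadata$sample_id[fl$metadata$sample_type == "sponge"]
      mem <- classify_membership(fl$table[, sponge, drop = FALSE],
                                 anc$core_fraction)
      utils::write.table(mem, file.path(sdir, "membership.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (stage == "specificity") {
      fl <- need(stage, "filtered")
      rows <- lapply(c("species", "genus", "family", "order", "class"),
                     function(r) {
        sp <- host_specific_asvs(fl$table, fl$metadata, r)
        sp <- exclusive_asvs(sp, fl$table, fl$metadata,
                             anc$exclusive_prevalence)
        do.call(rbind, lapply(names(sp$specific), function(g)
          if (length(sp$specific[[g]]))
            data.frame(rank = r, group = g, asv = sp$specific[[g]],
                       exclusive = sp$specific[[g]] %in% sp$exclusive[[g]],
                       stringsAsFactors = FALSE)))
      })
      utils::write.table(do.call(rbind, rows),
                         file.path(sdir, "specificity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (stage == "rarefaction") {
      fl <- need(stage, "filtered")
      types <- unique(stats::na.omit(fl$metadata$sponge_type))
      cur <- do.call(rbind, lapply(types, function(t)
        cbind(sponge_type = t,
              adapted_rarefaction(fl$table, fl$metadata, t, replicates = 50,
                                  seed = anc$seed))))
      utils::write.table(cur, file.path(sdir, "adapted_rarefaction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_stage(stage, sdir)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study design bookkeeping table
#'
#' The deep-sea survey's printed sampling-design totals (analysed samples
#' per sample type after quality filtering; sponge species per host
#' class), shipped as a plain-text input for boundary arithmetic and
#' report scripts.
#'
#' @return data.frame(quantity, group, count).
#' @export
study_design <- function() {
  utils::read.table(system.file("extdata", "study_design.tsv",
                                package = "spongiome"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
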