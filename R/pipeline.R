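#' Pipeline configuration
#'
#' One document configuring the end-to-end run
#' (synth -> train -> predict -> measure -> analyze). A single global seed
#' fans out to per-section seeds through the counter scheme of
#' [generate_cohort()], so enlarging a cohort never reshuffles existing
#' sections.
#'
#' @param synth A [synthesis_config()].
#' @param effects Effect table data frame, or path to a CSV with the
#'   columns of [default_effect_table()]; `NULL` uses the default table.
#' @param n_mice_per_group Mice per (genotype, age) group.
#' @param molecules Molecules to simulate.
#' @param spec A [unet_spec()].
#' @param train A [train_config()].
#' @param family_size Bonferroni family size for the report statistics.
#' @param stages Character vector of enabled stages, in order, from
#'   `c("synth", "train", "predict", "measure", "analyze")`. When
#'   `"train"`/`"predict"` are disabled, densitometry falls back to the
#'   ground-truth masks.
#' @param seed Global seed; overrides the seeds in `synth` and `train`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(synth = synthesis_config(),
                            effects = NULL,
                            n_mice_per_group = 8L,
                            molecules = striatal_molecules(),
                            spec = unet_spec(),
                            train = train_config(),
                            family_size = 10L,
                            stages = c("synth", "train", "predict",
                                       "measure", "analyze"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  synth$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  if (is.character(effects)) effects <- read.csv(effects,
                                                 stringsAsFactors = FALSE)
  if (!is.null(effects)) validate_effect_table(effects)
  structure(list(synth = synth, effects = effects,
                 n_mice_per_group = as.integer(n_mice_per_group),
                 molecules = molecules, spec = spec, train = train,
                 family_size = as.integer(family_size), stages = stages,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML document
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `seed`,
#' `n_mice_per_group`, `molecules`, `family_size`, `stages`, and sections
#' `synth`, `spec`, `train` whose keys are the corresponding constructor
#' arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synthesis_config, y$synth)
  if (!is.null(y$spec)) args$spec <- do.call(unet_spec, y$spec)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$effects_csv)) args$effects <- y$effects_csv
  for (k in c("n_mice_per_group", "molecules", "family_size", "stages",
              "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

# internal: cohort <-> disk round trip for restartable stages
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- attr(cohort, "meta")
  meta$id <- sprintf("sec%04d", seq_len(nrow(meta)))
  for (i in seq_along(cohort)) {
    write_section(cohort[[i]]$section, file.path(dir, meta$id[i]))
    write_label_map(cohort[[i]]$labels,
                    file.path(dir, paste0(meta$id[i], "_labels.png")))
  }
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

read_cohort <- function(dir, bit_depth = 8L) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  records <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sec <- read_section(file.path(dir, meta$id[i]), bit_depth = bit_depth,
                        channel_names = c("MOR1", meta$molecule[i]))
    lab <- read_label_map(file.path(dir, paste0(meta$id[i], "_labels.png")))
    records[[i]] <- list(section = sec, labels = lab,
                         meta = meta[i, , drop = FALSE])
  }
  structure(records, meta = meta, class = "cohort")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order, each reading only the previous
#' stage's serialized outputs, so a run is restartable: stages whose
#' outputs already exist are skipped unless `force`. Writes a manifest
#' (config hash, package version, per-stage wall time) into the output
#' directory. Identical configuration and seed reproduce all CSV outputs
#' bit-identically.
#'
#' @param config A [pipeline_config()] or path to its YAML document.
#' @param out_dir Output directory.
#' @param force Re-run stages whose outputs already exist.
#' @param verbose Print stage progress.
#' @return Invisibly, the report directory path.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timing <- list()
  stage_on <- function(s) s %in% config$stages
  say <- function(...) if (verbose) message(...)

  synth_dir <- file.path(out_dir, "synth")
  train_dir <- file.path(out_dir, "train")
  pred_dir <- file.path(out_dir, "predict")
  meas_dir <- file.path(out_dir, "measure")
  rep_dir <- file.path(out_dir, "report")

  if (stage_on("synth") &&
      (force || !file.exists(file.path(synth_dir, "metadata.csv")))) {
    say("stage synth")
    timing$synth <- system.time({
      eff <- if (is.null(config$effects)) default_effect_table()
             else config$effects
      cohort <- generate_cohort(eff, config$n_mice_per_group, config$synth,
                                molecules = config$molecules)
      write_cohort(cohort, synth_dir)
    })[["elapsed"]]
  }

  model_path <- file.path(train_dir, "model.rds")
  if (stage_on("train") && (force || !file.exists(model_path))) {
    say("stage train")
    timing$train <- system.time({
      cohort <- read_cohort(synth_dir, config$synth$bit_depth)
      model <- train_striosome_unet(cohort, config$spec, config$train)
      dir.create(train_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(model, model_path)
      write_training_curve(model$curve, file.path(train_dir, "curve.csv"))
      jsonlite::write_json(list(spec = unclass(config$spec),
                                train = unclass(config$train),
                                selected_epoch = model$selected_epoch),
                           file.path(train_dir, "model.json"),
                           auto_unbox = TRUE, null = "null")
    })[["elapsed"]]
  }

  if (stage_on("predict") &&
      (force || length(list.files(pred_dir, pattern = "mask")) == 0)) {
    say("stage predict")
    timing$predict <- system.time({
      cohort <- read_cohort(synth_dir, config$synth$bit_depth)
      model <- readRDS(model_path)
      dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)
      meta <- attr(cohort, "meta")
      for (i in seq_along(cohort)) {
        pred <- predict_striosomes(model, cohort[[i]]$section,
                                   tissue = striatal_mask(cohort[[i]]$labels))
        write_label_map(pred$labels,
                        file.path(pred_dir,
                                  paste0(meta$id[i], "_mask.png")))
      }
    })[["elapsed"]]
  }

  records_path <- file.path(meas_dir, "records.csv")
  if (stage_on("measure") && (force || !file.exists(records_path))) {
    say("stage measure")
    timing$measure <- system.time({
      cohort <- read_cohort(synth_dir, config$synth$bit_depth)
      meta <- attr(cohort, "meta")
      use_pred <- stage_on("predict") && dir.exists(pred_dir)
      out <- vector("list", length(cohort))
      for (i in seq_along(cohort)) {
        labels <- cohort[[i]]$labels
        comp <- labels
        if (use_pred) {
          mask <- read_label_map(file.path(pred_dir,
                                           paste0(meta$id[i], "_mask.png")))
          sm <- striatal_mask(labels)
          comp[sm] <- mask[sm]
        }
        parts <- partition_segments(striatal_mask(labels),
                                    hemisphere = meta$hemisphere[i])
        out[[i]] <- measure_densitometry(
          cohort[[i]]$section, comp, parts,
          exclusions = labels == 3L | labels == 4L,
          background_region = labels == 0L,
          meta = meta[i, c("animal", "hemisphere", "molecule", "genotype",
                           "age")])
      }
      dir.create(meas_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(do.call(rbind, out), records_path, row.names = FALSE)
    })[["elapsed"]]
  }

  if (stage_on("analyze") &&
      (force || !file.exists(file.path(rep_dir, "heatmap_RI.csv")))) {
    say("stage analyze")
    timing$analyze <- system.time({
      records <- read.csv(records_path, stringsAsFactors = FALSE)
      ri <- compute_RI(records)
      ismp <- compute_ISMP(records)
      strio <- records[records$compartment == "striosome" &
                         !records$qc_excluded, ]
      strio$value <- strio$mean_intensity
      st <- genotype_stats(strio, family_size = config$family_size)
      heatmap_tables(ri, summarize_ISMP(ismp), st, out_dir = rep_dir)
      write.csv(ri, file.path(rep_dir, "RI.csv"), row.names = FALSE)
      write.csv(ismp, file.path(rep_dir, "ISMP.csv"), row.names = FALSE)
      write.csv(st, file.path(rep_dir, "stats.csv"), row.names = FALSE)
    })[["elapsed"]]
  }

  strip_classes <- function(x) if (is.list(x)) lapply(unclass(x), strip_classes) else x
  cfg_json <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   package_version =
                     as.character(utils::packageVersion("striocompart")),
                   stages = config$stages, seed = config$seed,
                   wall_time_s = timing)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(rep_dir)
}
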