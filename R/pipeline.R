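# End-to-end orchestration: flow calculations, synthetic cohorts,
# morphometry and statistics under one validated configuration.

#' Validate a pipeline configuration
#'
#' Checks a configuration (a named list, or a YAML/JSON file path) against
#' the schema of its `mode` before any computation, reporting the missing or
#' invalid field by name.
#'
#' @param config named list or path to a YAML/JSON file.
#' @return the validated configuration (invisibly), with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  modes <- c("flow", "synth", "morph", "stats", "end_to_end")
  if (is.null(config$mode) || !config$mode %in% modes) {
    stop("validation error: `mode` must be one of ",
         paste(modes, collapse = ", "), call. = FALSE)
  }
  need <- function(block, fields) {
    if (is.null(config[[block]])) {
      stop("validation error: missing `", block, "` block", call. = FALSE)
    }
    for (f in fields) {
      if (is.null(config[[block]][[f]])) {
        stop("validation error: missing field `", block, ".", f, "`",
             call. = FALSE)
      }
    }
  }
  switch(config$mode,
    flow = need("flow", c("rate", "rate_unit")),
    synth = need("synth", "groups"),
    morph = need("morph", "in_dir"),
    stats = need("stats", "chips_csv"),
    end_to_end = need("synth", "groups")
  )
  if (config$mode == "morph" && is.null(config$morph$channel_map) &&
      is.null(config$morph$use_sidecar)) {
    stop("validation error: missing field `morph.channel_map` ",
         "(or set `morph.use_sidecar: true` to read JSON sidecars)",
         call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  invisible(config)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) return(ibidi_slide_geometry())
  channel_geometry(height = g$height_mm * 1e-3, width = g$width_mm * 1e-3,
                   length = g$length_mm * 1e-3,
                   inlet_diameter = g$inlet_diameter_mm * 1e-3,
                   plan_shape = if (is.null(g$plan_shape)) "ellipse"
                                else g$plan_shape)
}

config_fluid <- function(cfg) {
  f <- cfg$fluid
  if (is.null(f)) return(fluid_properties())
  fluid_properties(dynamic_viscosity = f$dynamic_viscosity,
                   density = f$density)
}

config_tissue_params <- function(lst) {
  do.call(tissue_params, lst[names(lst) %in% names(formals(tissue_params))])
}

config_stack_spec <- function(cfg) {
  s <- cfg$stack
  if (is.null(s)) return(stack_spec())
  args <- list()
  if (!is.null(s$shape)) args$shape <- as.integer(s$shape)
  if (!is.null(s$voxel_size_um)) args$voxel_size <- as.numeric(s$voxel_size_um)
  if (!is.null(s$channels)) args$channels <- s$channels
  if (!is.null(s$bit_depth)) args$bit_depth <- s$bit_depth
  do.call(stack_spec, args)
}

#' Run the pipeline
#'
#' Executes one configured stage (or the whole chain) and writes results plus
#' a JSON manifest recording inputs, parameters, seed, package version and
#' per-output checksums. All randomness flows from the single seed, so
#' re-running an identical configuration reproduces identical CSV outputs.
#'
#' Modes: `flow` (shear profile CSV for a geometry and flow rate), `synth`
#' (write a synthetic cohort to disk), `morph` (measure stacks in a
#' directory into FOV- and chip-level CSVs), `stats` (two-group comparisons
#' from a chip CSV), `end_to_end` (synthetic cohort streamed through
#' morphometry and statistics without intermediate TIFFs).
#'
#' @param config named list or YAML/JSON path; see [validate_config()].
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return list of stage results (invisibly); files and `manifest.json` are
#'   written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$mode,
    flow = run_flow_stage(config, out_dir),
    synth = run_synth_stage(config, out_dir),
    morph = run_morph_stage(config, out_dir),
    stats = run_stats_stage(config, out_dir),
    end_to_end = run_end_to_end(config, out_dir)
  )
  manifest <- list(
    mode = config$mode, seed = config$seed,
    package_version = as.character(utils::packageVersion("shearscope")),
    parameters = config[setdiff(names(config), "mode")],
    outputs = res$outputs,
    checksums = as.list(tools::md5sum(file.path(out_dir, res$outputs)))
  )
  names(manifest$checksums) <- res$outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_flow_stage <- function(config, out_dir) {
  geom <- config_geometry(config)
  fluid <- config_fluid(config)
  cond <- flow_condition(config$flow$rate, config$flow$rate_unit, fluid)
  model <- config$flow$model %||% "plate"
  prof <- plan_shear_profile(cond, geom,
                             n_positions = config$flow$n_positions %||% 101,
                             duct_correction = identical(model, "rect_duct"))
  df <- as.data.frame(prof)
  utils::write.csv(df, file.path(out_dir, "shear_profile.csv"),
                   row.names = FALSE)
  summary <- list(
    inlet_velocity_m_s = inlet_velocity(cond, geom),
    plate_shear_dyn_cm2 = pa_to_dyn_cm2(plate_shear(cond, geom)),
    rect_duct_shear_dyn_cm2 = pa_to_dyn_cm2(rect_duct_shear(cond, geom)),
    midline_shear_dyn_cm2 = pa_to_dyn_cm2(prof$summary))
  jsonlite::write_json(summary, file.path(out_dir, "flow_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(profile = prof, summary = summary,
       outputs = c("shear_profile.csv", "flow_summary.json"))
}

synth_group_params <- function(config) {
  lapply(config$synth$groups, config_tissue_params)
}

run_synth_stage <- function(config, out_dir) {
  spec <- config_stack_spec(config)
  cohort <- generate_cohort(
    spec, synth_group_params(config),
    chips_per_group = config$synth$chips_per_group %||% 4,
    fovs_per_chip = config$synth$fovs_per_chip %||% 5,
    seed = config$seed, out_dir = out_dir)
  utils::write.csv(cohort$chip_truth, file.path(out_dir, "chip_truth.csv"),
                   row.names = FALSE)
  list(cohort = cohort,
       outputs = c("chip_truth.csv", "cohort_manifest.json"))
}

run_morph_stage <- function(config, out_dir) {
  in_dir <- config$morph$in_dir
  paths <- sort(list.files(in_dir, pattern = "\\.tif$", full.names = TRUE))
  if (!length(paths)) stop("no TIFF stacks found in ", in_dir, call. = FALSE)
  params <- do.call(morphometry_params,
                    config$morph$params %||% list())
  fov_rows <- lapply(paths, function(p) {
    stack <- read_stack(p)
    cbind(data.frame(path = basename(p)), analyze_fov(stack, params))
  })
  fov_df <- do.call(rbind, fov_rows)
  # chip id from the file name convention <group>_chip<k>_fov<j>.tif
  ids <- sub("_fov[0-9]+\\.tif$", "", basename(paths))
  groups <- sub("_chip[0-9]+$", "", ids)
  chips <- do.call(rbind, lapply(split(seq_along(paths), ids), function(i) {
    chip_summary(fov_df[i, -1], ids[i[1]], groups[i[1]])
  }))
  rownames(chips) <- NULL
  utils::write.csv(fov_df, file.path(out_dir, "fov_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(chips, file.path(out_dir, "chip_metrics.csv"),
                   row.names = FALSE)
  list(fov_metrics = fov_df, chip_metrics = chips,
       outputs = c("fov_metrics.csv", "chip_metrics.csv"))
}

run_stats_stage <- function(config, out_dir) {
  records <- utils::read.csv(config$stats$chips_csv)
  cmp <- compare_metrics(records,
                         group_col = config$stats$group_col %||% "group")
  utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  writeLines(c(
    sprintf("Two-group comparisons (%s vs %s); per-metric p-values,",
            attr(cmp, "groups")[1], attr(cmp, "groups")[2]),
    "no multiple-testing correction applied.",
    utils::capture.output(print(cmp))),
    file.path(out_dir, "comparisons.txt"))
  list(comparisons = cmp, outputs = c("comparisons.csv", "comparisons.txt"))
}

run_end_to_end <- function(config, out_dir) {
  spec <- config_stack_spec(config)
  sim <- simulate_and_measure_cohort(
    spec, synth_group_params(config),
    chips_per_group = config$synth$chips_per_group %||% 4,
    fovs_per_chip = config$synth$fovs_per_chip %||% 5,
    seed = config$seed,
    params = do.call(morphometry_params, config$morph$params %||% list()))
  utils::write.csv(sim$chip_truth, file.path(out_dir, "chip_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$chip_metrics, file.path(out_dir, "chip_metrics.csv"),
                   row.names = FALSE)
  cmp <- compare_metrics(sim$chip_metrics)
  utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  c(sim, list(comparisons = cmp,
              outputs = c("chip_truth.csv", "chip_metrics.csv",
                          "comparisons.csv")))
}

#' Simulate a cohort and measure it, one stack at a time
#'
#' Streams the synthetic study design through the measurement pipeline:
#' each field of view is generated, measured and discarded, so memory stays
#' at one stack regardless of cohort size. Produces matched ground-truth
#' and measured chip-level tables.
#'
#' @inheritParams generate_cohort
#' @param params a [morphometry_params()].
#' @return list with `chip_metrics` (measured records), `chip_truth`
#'   (ground-truth records) and `fov_metrics`.
#' @export
simulate_and_measure_cohort <- function(spec, params_by_group,
                                        chips_per_group = 4,
                                        fovs_per_chip = 5, seed = 1,
                                        params = morphometry_params()) {
  groups <- names(params_by_group)
  n_fov <- length(groups) * chips_per_group * fovs_per_chip
  sub_seeds <- with_local_seed(seed, sample.int(2^31 - 2, n_fov))
  fov_rows <- list(); truth_recs <- list()
  chip_rows <- list()
  i <- 0L
  for (g in groups) for (ch in seq_len(chips_per_group)) {
    chip_id <- paste0(g, "_chip", ch)
    fovs <- vector("list", fovs_per_chip)
    truths <- vector("list", fovs_per_chip)
    for (fv in seq_len(fovs_per_chip)) {
      i <- i + 1L
      sim <- generate_monolayer(spec, params_by_group[[g]], sub_seeds[i])
      fovs[[fv]] <- analyze_fov(sim$stack, params)
      truths[[fv]] <- list(group = g, chip = chip_id, truth = sim$truth)
    }
    fov_df <- do.call(rbind, fovs)
    chip_rows[[chip_id]] <- chip_summary(fov_df, chip_id, g)
    truth_recs[[chip_id]] <- chip_truth_row(truths)
    fov_rows[[chip_id]] <- cbind(data.frame(chip = chip_id, group = g),
                                 fov_df)
  }
  out <- list(chip_metrics = do.call(rbind, chip_rows),
              chip_truth = do.call(rbind, truth_recs),
              fov_metrics = do.call(rbind, fov_rows))
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  out
}
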