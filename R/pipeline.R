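#' Run configuration for end-to-end pipelines
#'
#' A nested, JSON-serialisable configuration tying together protocol,
#' properties, camera and pore-population settings with explicit seeds.
#' `read_run_config()`/`write_run_config()` round-trip it losslessly
#' (JSON by default; YAML is read when the `yaml` package is available).
#'
#' @param scenario scenario name.
#' @param loading,nucleation_mode,Tn_target protocol headline settings
#'   (see [freezing_protocol()]); remaining protocol/property fields take
#'   their defaults unless overridden via `protocol`/`props`.
#' @param solution label carried into outputs (e.g. `"sucrose5"`).
#' @param n_vials batch size.
#' @param seed master seed; stage seeds are derived from it.
#' @param protocol,props,camera,pores optional lists of overrides for
#'   [freezing_protocol()], [physical_properties()], [camera_config()] and
#'   [pore_spec()].
#' @param sem_image_shape,sem_px_size_um,sem_images_per_level SEM
#'   generation geometry.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(scenario = "on_visf271", loading = "ON_SHELF",
                       nucleation_mode = "VISF", Tn_target = 271,
                       solution = "sucrose5", n_vials = 10, seed = 1,
                       protocol = list(), props = list(), camera = list(),
                       pores = list(), sem_image_shape = c(512, 512),
                       sem_px_size_um = 0.43, sem_images_per_level = 1) {
  structure(list(scenario = scenario, loading = loading,
                 nucleation_mode = nucleation_mode, Tn_target = Tn_target,
                 solution = solution, n_vials = n_vials, seed = seed,
                 protocol = protocol, props = props, camera = camera,
                 pores = pores, sem_image_shape = sem_image_shape,
                 sem_px_size_um = sem_px_size_um,
                 sem_images_per_level = sem_images_per_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path file path (`.json`, or `.yaml`/`.yml` with the yaml package).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$sem_image_shape <- as.numeric(cfg$sem_image_shape)
  do.call(run_config, cfg)
}

config_protocol <- function(config) {
  args <- c(list(loading = config$loading,
                 nucleation_mode = config$nucleation_mode,
                 Tn_target = config$Tn_target),
            config$protocol)
  if (config$nucleation_mode == "VISF" && is.null(args$T_shelf_pre)) {
    # shelf setpoints used to reach the two nucleation targets
    args$T_shelf_pre <- if (config$loading == "ON_SHELF") {
      if (config$Tn_target >= 268) 268 else 258
    } else {
      if (config$Tn_target >= 268) 262 else 248
    }
  }
  do.call(freezing_protocol, args)
}

config_props <- function(config) {
  do.call(physical_properties, c(list(loading = config$loading), config$props))
}

write_manifest <- function(dir, files, config, seeds, extra = list()) {
  man <- c(list(scenario = config$scenario,
                package_version = as.character(utils::packageVersion("icefront")),
                seeds = seeds,
                files = lapply(files, function(f) {
                  list(path = basename(f),
                       md5 = unname(tools::md5sum(f)))
                })),
           extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run the freezing pipeline: simulate, render, extract, analyse
#'
#' Executes the full thermal chain for one scenario: batch simulation,
#' stack rendering, profile extraction with emissivity correction,
#' line/vial/batch extrema traces, front tracking (ON-shelf), freezing
#' interval and gradient-inversion labels, writing plain-text artifacts
#' and a manifest (file hashes + seeds) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory results and the manifest
#'   path.
#' @export
run_freezing_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- list(simulate = sample.int(2^31 - 2, 1),
                render = sample.int(2^31 - 2, 1))
  protocol <- config_protocol(config)
  props <- config_props(config)
  camera <- do.call(camera_config, config$camera)

  histories <- simulate_batch(protocol, props, n_vials = config$n_vials,
                              seed = seeds$simulate)
  stack <- render_thermal_stack(histories, camera, seed = seeds$render,
                                neighbor_humps =
                                  protocol$nucleation_mode == "SPONTANEOUS")
  stack_files <- write_thermal_stack(stack, out_dir)
  res <- process_stack(stack)

  traces <- rbind(
    cbind(level = "VIAL", res$vial[c("time_s", "vial_id", "Tmin_K", "Hmin_mm",
                                     "Tmax_K", "Hmax_mm")]),
    cbind(level = "BATCH", vial_id = NA,
          res$batch[c("time_s", "Tmin_K", "Hmin_mm", "Tmax_K", "Hmax_mm")])
  )
  traces_file <- file.path(out_dir, "traces.csv")
  utils::write.csv(traces, traces_file, row.names = FALSE)

  # VISF: the batch nucleates together, analyse batch-mean profiles.
  # Spontaneous: nucleation is staggered, so detect per vial and average
  # the profiles after aligning each vial on its own nucleation event.
  visf <- protocol$nucleation_mode == "VISF"
  jump_K <- if (visf) 2 else 4.5
  if (visf) {
    bottom <- res$profiles[res$profiles$pixel == 1, ]
    bottom_mean <- stats::aggregate(T_K ~ time_s, bottom, mean)
    t_nuc <- detect_nucleation(bottom_mean$time_s, bottom_mean$T_K,
                               jump_K = jump_K)
    cls_profiles <- res$profiles
    t_nuc_cls <- t_nuc
    t_pulse_cls <- histories[[1]]$t_pulse_start_s
  } else {
    ids <- sort(unique(res$profiles$vial_id))
    t_nuc_vials <- vapply(ids, function(v) {
      b <- res$profiles[res$profiles$vial_id == v & res$profiles$pixel == 1, ]
      bm <- stats::aggregate(T_K ~ time_s, b, mean)
      detect_nucleation(bm$time_s, bm$T_K, jump_K = jump_K)
    }, numeric(1))
    t_nuc <- t_nuc_vials[1]
    cls_profiles <- align_profiles(res$profiles, t_nuc_vials)
    t_nuc_cls <- 0
    t_pulse_cls <- NA
  }
  t_pulse <- histories[[1]]$t_pulse_start_s

  front_file <- NULL
  front <- NULL
  if (protocol$loading == "ON_SHELF" && is.finite(t_nuc)) {
    front <- track_front(res$batch, t_nuc)
    front_file <- file.path(out_dir, "front_track.csv")
    utils::write.csv(as.data.frame(front), front_file, row.names = FALSE)
  }

  label <- if (is.finite(t_nuc_cls)) {
    classify_inversion(average_profiles(cls_profiles), t_nuc_cls, t_pulse_cls)
  } else {
    structure(list(before_nucleation = "UNCLEAR", after_nucleation = "UNCLEAR",
                   during_pulse = NA_character_, visf_inversion = "NA"),
              class = "gradient_label")
  }
  interval_s <- if (is.finite(t_nuc)) freezing_interval(res$batch, t_nuc) else NA
  labels_df <- data.frame(
    type = config$loading, solution = config$solution,
    nucleation = if (protocol$nucleation_mode == "VISF")
      sprintf("VISF %g K", protocol$Tn_target) else "Spontaneous",
    before = label$before_nucleation, after = label$after_nucleation,
    inversion = label$visf_inversion,
    t_nucleation_s = t_nuc, freezing_interval_s = interval_s)
  labels_file <- file.path(out_dir, "labels.csv")
  utils::write.csv(labels_df, labels_file, row.names = FALSE)

  files <- c(stack_files, traces = traces_file, labels = labels_file)
  if (!is.null(front_file)) files <- c(files, front = front_file)
  manifest <- write_manifest(out_dir, files, config, seeds)
  invisible(list(histories = histories, stack = stack, traces = res,
                 t_nucleation = t_nuc, front = front, label = label,
                 labels_df = labels_df, interval_s = interval_s,
                 manifest = manifest, files = files))
}

#' Run the pore pipeline: generate, segment, report
#'
#' Generates synthetic SEM images for the three cake levels, writes them
#' as ASCII PGM with ground-truth CSVs, runs the MIA segmentation on each,
#' and writes the pooled pore table, dispersion report and Q-Q data.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, list with `table`, `truth`, `report`, `qq`,
#'   manifest path.
#' @export
run_pore_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  levels <- c("TOP", "MIDDLE", "BOTTOM")
  n_img <- config$sem_images_per_level
  img_seeds <- matrix(sample.int(2^31 - 2, 3 * n_img), nrow = 3)
  spec <- do.call(pore_spec, config$pores)

  tables <- list(); truths <- list(); files <- character(0)
  for (li in seq_along(levels)) {
    for (k in seq_len(n_img)) {
      id <- sprintf("%s_%s_%d", config$scenario, tolower(levels[li]), k)
      gen <- generate_sem_image(spec, config$sem_image_shape,
                                config$sem_px_size_um,
                                seed = img_seeds[li, k],
                                cake_level = levels[li], sample_id = id)
      pgm <- file.path(out_dir, paste0(id, ".pgm"))
      write_pgm(gen$image, pgm)
      gt <- file.path(out_dir, paste0(id, "_truth.csv"))
      utils::write.csv(gen$truth, gt, row.names = FALSE)
      seg <- segment_pores(gen$image, image_id = id)
      tables[[id]] <- seg$table
      truths[[id]] <- cbind(image_id = id, cake_level = levels[li], gen$truth)
      files <- c(files, pgm, gt)
    }
  }
  table <- do.call(rbind, tables); rownames(table) <- NULL
  truth <- do.call(rbind, truths); rownames(truth) <- NULL
  table_file <- file.path(out_dir, "poretable.csv")
  utils::write.csv(table, table_file, row.names = FALSE)

  report <- dispersion_stats(table, by = "cake_level")
  report_file <- file.path(out_dir, "dispersion.csv")
  utils::write.csv(report, report_file, row.names = FALSE)

  qq <- beta_qq(table$eq_diameter_um, spec$beta_a, spec$beta_b)
  qq_file <- file.path(out_dir, "qq.csv")
  utils::write.csv(data.frame(empirical_q = qq$empirical_q,
                              theoretical_q = qq$theoretical_q),
                   qq_file, row.names = FALSE)

  files <- c(files, table_file, report_file, qq_file)
  manifest <- write_manifest(out_dir, as.list(files), config,
                             list(master = config$seed),
                             extra = list(qq_r_squared = qq$r_squared,
                                          scale_fitted = qq$scale_fitted))
  invisible(list(table = table, truth = truth, report = report, qq = qq,
                 manifest = manifest, files = files))
}

#' Scenario matrix mirroring the experimental design
#'
#' The six freezing scenarios of the study design for one solution:
#' loading in {ON, OFF} crossed with nucleation in
#' {spontaneous, VISF 271 K, VISF 263 K}.
#'
#' @param solution solution label.
#' @param seed master seed (per-scenario seeds derived).
#' @param n_vials vials per batch.
#' @return List of [run_config()] objects.
#' @export
scenario_matrix <- function(solution = "sucrose5", seed = 1, n_vials = 10) {
  grid <- expand.grid(loading = c("ON_SHELF", "OFF_SHELF"),
                      nuc = c("SPONTANEOUS", "VISF271", "VISF263"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    nuc <- grid$nuc[i]
    run_config(
      scenario = tolower(paste0(sub("_SHELF", "", grid$loading[i]), "_", nuc)),
      loading = grid$loading[i],
      nucleation_mode = if (nuc == "SPONTANEOUS") "SPONTANEOUS" else "VISF",
      Tn_target = if (nuc == "VISF271") 271 else 263,
      solution = solution, n_vials = n_vials, seed = seed + i)
  })
}
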