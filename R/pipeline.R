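#' Run configuration
#'
#' Assembles the reproducible configuration of an end-to-end synthetic run.
#' Every stochastic stage derives its seed from `seed`; the configuration
#' round-trips losslessly through YAML.
#'
#' @param seed master integer seed.
#' @param n_pairs glaucoma-control pairs.
#' @param stimulus_preset `"lcr-default"` or `"localizer"`.
#' @param n_pix stimulus raster size.
#' @param tr repetition time (s).
#' @param field_radius stimulated field radius (deg).
#' @param n_units units per subject.
#' @param noise_sd,ar1,drift_amp noise model (see [sim_spec()]).
#' @param damage_exponent kappa.
#' @param plasticity_mode,plasticity_magnitude optional plasticity injection.
#' @param ve_min,ecc_max model thresholds.
#' @param refine run the pRF refinement stage.
#' @param grid_step,grid_extent,grid_sigmas coarse search grid.
#' @param vf_spacing reconstruction grid spacing (deg).
#' @param boundaries normative deviation boundaries (percent).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_pairs = 19, stimulus_preset = "lcr-default",
                       n_pix = 101, tr = 1.5, field_radius = 7, n_units = 500,
                       noise_sd = 0.12, ar1 = 0.3, drift_amp = 0.5,
                       damage_exponent = 1, plasticity_mode = "none",
                       plasticity_magnitude = 0, ve_min = 0.15, ecc_max = 7,
                       refine = TRUE, grid_step = 0.5, grid_extent = 8,
                       grid_sigmas = c(0.25, 0.5, 1, 1.5, 2, 3, 4),
                       vf_spacing = 0.25,
                       boundaries = c(90, 95, 98, 99, 99.5)) {
  if (is.null(seed) || !is.finite(seed)) stop("config must carry an explicit seed")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param file YAML path.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(run_config, cfg)
}

config_movie <- function(config) {
  if (config$stimulus_preset == "localizer") {
    make_localizer_movie(tr = config$tr, n_pix = config$n_pix,
                         field_radius = config$field_radius)
  } else {
    make_lcr_movie(tr = config$tr, n_pix = config$n_pix,
                   field_radius = config$field_radius)
  }
}

config_sim_spec <- function(config) {
  sim_spec(n_units = config$n_units, noise_sd = config$noise_sd,
           ar1 = config$ar1, drift_amp = config$drift_amp,
           damage_exponent = config$damage_exponent, seed = config$seed)
}

subject_ids <- function(pair) {
  sprintf(c("pair%02d_glaucoma", "pair%02d_control_ss", "pair%02d_control_ns"),
          pair)
}

#' Simulate a cohort and write it as a directory bundle
#'
#' Writes per-subject time-series CSVs, per-pair perimetry CSVs, ground-truth
#' sheet JSONs and a manifest JSON with all per-stage seeds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  movie <- config_movie(config)
  plast <- NULL
  if (config$plasticity_mode != "none" && config$plasticity_magnitude > 0) {
    plast <- list(mode = config$plasticity_mode,
                  magnitude = config$plasticity_magnitude)
  }
  cohort <- make_cohort(n_pairs = config$n_pairs, spec = config_sim_spec(config),
                        movie = movie, plasticity = plast)
  for (p in cohort$pairs) {
    ids <- subject_ids(p$pair)
    write_perimetry(p$grid, file.path(out_dir, sprintf("pair%02d_perimetry.csv", p$pair)))
    ds <- list(p$glaucoma, p$control_ss, p$control_ns)
    for (k in 1:3) {
      utils::write.csv(ds[[k]]$ts$data,
                       file.path(out_dir, paste0(ids[k], "_ts.csv")),
                       row.names = FALSE)
      jsonlite::write_json(as.list(ds[[k]]$sheet),
                           file.path(out_dir, paste0(ids[k], "_sheet.json")),
                           digits = NA)
    }
  }
  manifest <- c(cohort$manifest,
                list(config = unclass(config), tr = movie$tr_seconds,
                     dummy_frames = movie$dummy_frames,
                     n_frames = dim(movie$frames)[1]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

read_manifest <- function(cohort_dir) {
  f <- file.path(cohort_dir, "manifest.json")
  if (!file.exists(f)) stop("no manifest.json in ", cohort_dir)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Fit pRF models for every subject of a cohort bundle
#'
#' Reads the per-subject time series written by [run_simulate()], preprocesses
#' them, fits the full-field pRF model and writes per-subject pRF tables plus
#' a fit log of variance-explained summaries.
#'
#' @param cohort_dir directory written by [run_simulate()].
#' @param config a [run_config()] (defaults to the one in the manifest).
#' @return The directory, invisibly.
#' @export
run_fit <- function(cohort_dir, config = NULL) {
  man <- read_manifest(cohort_dir)
  config <- config %||% do.call(run_config, man$config)
  movie <- config_movie(config)
  ap <- effective_aperture(movie, "FF")
  grid <- prf_grid_spec(x = seq(-config$grid_extent, config$grid_extent,
                                by = config$grid_step),
                        y = seq(-config$grid_extent, config$grid_extent,
                                by = config$grid_step),
                        sigmas = config$grid_sigmas)
  files <- list.files(cohort_dir, pattern = "_ts\\.csv$")
  if (!length(files)) stop("no time-series files found in ", cohort_dir)
  log <- list()
  for (f in files) {
    id <- sub("_ts\\.csv$", "", f)
    Y <- as.matrix(utils::read.csv(file.path(cohort_dir, f)))
    ts <- preprocess(ts_set(Y, config$tr, dummy_frames = movie$dummy_frames))
    fit <- prf_fit(ts, ap, grid = grid, refine = config$refine)
    write_prf_table(fit, file.path(cohort_dir, paste0(id, "_prf.csv")))
    log[[id]] <- list(n = nrow(fit$models),
                      median_ve = stats::median(fit$models$ve),
                      n_pass = nrow(threshold_models(fit$models,
                                                     ve_min = config$ve_min)))
  }
  jsonlite::write_json(log, file.path(cohort_dir, "fit_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort_dir)
}

read_prf_table <- function(cohort_dir, id) {
  f <- file.path(cohort_dir, paste0(id, "_prf.csv"))
  if (!file.exists(f)) stop("missing pRF table: ", f)
  d <- utils::read.csv(f)
  d$unit <- d$unit_id
  d$degenerate <- FALSE
  d
}

#' Reconstruct, classify and summarize a fitted cohort
#'
#' For every pair: reconstructs the visual field of the glaucoma subject and
#' of the matched control (SS), classifies both against the control-NS
#' normative group (excluding the matched control), computes the
#' deviation-rank statistics on eccentricity/size histograms, and writes tidy
#' CSV/JSON summaries plus per-pair figures.
#'
#' @param cohort_dir directory with fits from [run_fit()].
#' @param config optional [run_config()] override.
#' @return The directory, invisibly.
#' @export
run_report <- function(cohort_dir, config = NULL) {
  man <- read_manifest(cohort_dir)
  config <- config %||% do.call(run_config, man$config)
  n_pairs <- config$n_pairs
  grid <- vf_grid(spacing = config$vf_spacing, radius = config$field_radius)
  thr <- function(m) threshold_models(m, ve_min = config$ve_min,
                                      ecc_range = c(0, config$ecc_max))
  subj <- function(p, role) read_prf_table(cohort_dir, subject_ids(p)[role])
  ns_maps <- lapply(seq_len(n_pairs), function(p) {
    reconstruct_vf(thr(subj(p, 3)), grid, ve_min = config$ve_min)
  })
  ns_hists <- lapply(seq_len(n_pairs), function(p) {
    normalized_hist(thr(subj(p, 3)), "eccentricity")
  })
  if (n_pairs < 6) {
    warning("fewer than 6 pairs: deviation maps and ranks are skipped")
  }
  stats_rows <- list()
  for (p in seq_len(n_pairs)) {
    mg <- thr(subj(p, 1)); mss <- thr(subj(p, 2))
    row <- list(pair = p)
    if (n_pairs >= 6) {
      map_g <- reconstruct_vf(mg, grid, ve_min = config$ve_min)
      dev_g <- normative_deviation(map_g, ns_maps, exclude = p,
                                   boundaries = config$boundaries)
      hg <- normalized_hist(mg, "eccentricity")
      hss <- normalized_hist(mss, "eccentricity")
      base <- lapply(setdiff(seq_len(n_pairs), p), function(q) {
        pair_deviation(ns_hists[[p]], ns_hists[[q]])
      })
      rk_g <- deviation_rank(pair_deviation(hg, ns_hists[[p]]), base)
      rk_ss <- deviation_rank(pair_deviation(hss, ns_hists[[p]]), base)
      row$frac_flagged <- mean(dev_g$class != "within")
      row$rank_glaucoma <- rk_g$rank
      row$sig_glaucoma <- rk_g$significant
      row$rank_control_ss <- rk_ss$rank
      row$sig_control_ss <- rk_ss$significant
      fig <- file.path(cohort_dir, sprintf("pair%02d_deviation.png", p))
      grDevices::png(fig, width = 600, height = 600)
      plot(dev_g)
      grDevices::dev.off()
      write_vf_map(dev_g, file.path(cohort_dir,
                                    sprintf("pair%02d_deviation.csv", p)))
    }
    row$median_sigma_glaucoma <- stats::median(mg$sigma)
    row$median_sigma_control_ss <- stats::median(mss$sigma)
    stats_rows[[p]] <- row
  }
  out <- do.call(rbind, lapply(stats_rows, function(r) {
    as.data.frame(r[!vapply(r, is.null, logical(1))])
  }))
  utils::write.csv(out, file.path(cohort_dir, "pair_stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(n_pairs = n_pairs,
                            n_significant = sum(out$sig_glaucoma %||% 0),
                            stats = out),
                       file.path(cohort_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(cohort_dir)
}

#' Run the full synthetic pipeline
#'
#' `run_simulate()`, `run_fit()` and `run_report()` in sequence.
#'
#' @inheritParams run_simulate
#' @export
run_all <- function(config, out_dir) {
  run_simulate(config, out_dir)
  run_fit(out_dir, config)
  run_report(out_dir, config)
  invisible(out_dir)
}
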