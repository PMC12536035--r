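#' Define a reproducible experiment
#'
#' An experiment bundles a model choice, its parameters, durations and a
#' seed, so that a config plus seed determines every output. Configs are
#' plain lists and serialize to YAML/JSON; [load_experiment()] reads one
#' back.
#'
#' @param name Experiment name (used in file names).
#' @param model `"ring"`, `"twopop"` or `"force"`.
#' @param parameters Named list forwarded to [ring_config()],
#'   [twopop_config()], or (for `"force"`) to [force_network()] plus the
#'   fields `pre`, `learn`, `post`, `supervisor_rho` and `calibrate`.
#' @param duration Recorded duration (time units; ignored for `"force"`).
#' @param burn_in Discarded transient (default 100).
#' @param window Velocity measurement window (defaults to `duration`).
#' @param seed Integer seed.
#' @param precession Also run spike-phase / precession analysis
#'   (default `TRUE` for `ring`/`twopop`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(name, model = c("ring", "twopop", "force"),
                              parameters = list(), duration = 1000,
                              burn_in = 100, window = NULL, seed = 1,
                              precession = TRUE) {
  model <- match.arg(model)
  structure(list(name = name, model = model, parameters = parameters,
                 duration = duration, burn_in = burn_in,
                 window = window %||% duration, seed = seed,
                 precession = precession),
            class = "experiment_config")
}

#' Read an experiment config from a YAML file
#'
#' @param path Path to a YAML file with the fields of [experiment_config()].
#' @return An `experiment_config`.
#' @export
load_experiment <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(
    name = y$name, model = y$model, parameters = y$parameters %||% list(),
    duration = y$duration %||% 1000, burn_in = y$burn_in %||% 100,
    window = y$window, seed = y$seed %||% 1,
    precession = y$precession %||% TRUE)
}

#' Run an experiment end to end
#'
#' Executes the pipeline named by the config — simulate, observables,
#' velocity metrics, and (optionally) precession analysis for the oscillator
#' models; supervisor building, FORCE training, phase decoding and
#' precession analysis for `"force"` — and writes its artifacts (CSV tables
#' and a metrics JSON) plus a manifest with MD5 checksums into `out_dir`.
#'
#' @param config An [experiment_config()] or the path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The manifest: a tibble with columns `file`, `bytes`, `md5`, with
#'   the computed metrics attached as the `"metrics"` attribute.
#' @export
run_experiment <- function(config, out_dir = tempfile("experiment")) {
  if (is.character(config)) config <- load_experiment(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- config$parameters

  metrics <- list(name = config$name, model = config$model,
                  seed = config$seed)
  artifacts <- character(0)
  put_csv <- function(df, stem) {
    f <- file.path(out_dir, paste0(config$name, "-", stem, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    artifacts <<- c(artifacts, f)
  }

  if (config$model %in% c("ring", "twopop")) {
    cfg <- if (config$model == "ring") {
      do.call(ring_config, c(prm, list(seed = config$seed)))
    } else {
      do.call(twopop_config, c(prm, list(seed = config$seed)))
    }
    traj <- if (config$model == "ring")
      simulate_ring(cfg, duration = config$duration, burn_in = config$burn_in)
    else
      simulate_twopop(cfg, duration = config$duration, burn_in = config$burn_in)

    prof <- classify_sync_domain(
      mean_phase_velocity(traj, window = config$window))
    vr <- velocity_ratio(prof)
    raster <- phases_to_spikes(traj)
    put_csv(as.data.frame(prof), "velocity-profile")
    put_csv(as.data.frame(raster), "spikes")
    metrics$rho <- cfg$rho
    metrics$omega_min <- min(prof$omega)
    metrics$omega_max <- max(prof$omega)
    metrics$ratio <- vr$ratio
    metrics$spread <- vr$spread
    metrics$collapse <- vr$collapse

    if (isTRUE(config$precession) && !vr$collapse) {
      sync_units <- prof$unit[prof$domain == "sync"]
      ref <- reference_phase(traj, sync_units[1])
      sp <- assign_spike_phases(raster, ref)
      rep_tbl <- precession_report(sp)
      put_csv(as.data.frame(rep_tbl), "precession")
      metrics$n_precessing <-
        sum(rep_tbl$classification == "precessing", na.rm = TRUE)
      metrics$n_locked <- sum(rep_tbl$classification == "locked", na.rm = TRUE)
      unsync_units <- prof$unit[prof$domain == "unsync"]
      ts <- theta_sequence_score(sp[sp$unit %in% unsync_units, ])
      metrics$theta_sequence_score <- ts$score
    }
  } else {
    sup_rho <- prm$supervisor_rho
    sup_cfg <- twopop_config(rho = sup_rho %||% 1, seed = config$seed)
    if (is.null(sup_rho)) sup_cfg <- calibrate_rho(sup_cfg)$config
    total <- (prm$pre %||% 1000) + (prm$learn %||% 30000) +
      (prm$post %||% 5000)
    traj <- simulate_twopop(sup_cfg, duration = total + 10,
                            burn_in = config$burn_in, record_stride = 10)
    sup <- build_supervisor(traj)
    net <- force_network(
      N = prm$N %||% 1000, G = prm$G %||% 6000, Q = prm$Q %||% 1400,
      dale = prm$dale %||% TRUE, seed = config$seed)
    fit <- train_force(net, sup, pre = prm$pre %||% 1000,
                       learn = prm$learn %||% 30000,
                       post = prm$post %||% 5000, seed = config$seed + 1)
    put_csv(as.data.frame(fit$traces$post$spikes), "spikes")
    put_csv(as.data.frame(tidy(fit)), "channel-correlations")
    metrics$rho <- sup_cfg$rho
    metrics$min_channel_cor <- min(fit$channel_cor)
    metrics$success <- fit$success
    dec <- decode_phases(fit$traces$post)
    prof <- classify_sync_domain(mean_phase_velocity(
      dec, window = floor(max(dec$times) - min(dec$times))))
    metrics$decoded_ratio <- velocity_ratio(prof)$ratio
    sync_unit <- prof$unit[prof$domain == "sync"][1]
    ref <- reference_phase(dec, sync_unit)
    raster <- fit$traces$post$spikes
    raster <- raster[raster$time >= min(ref$time) &
                       raster$time <= max(ref$time), ]
    sp <- assign_spike_phases(raster, ref)
    rep_tbl <- precession_report(sp)
    put_csv(as.data.frame(rep_tbl), "precession")
    metrics$n_precessing <-
      sum(rep_tbl$classification == "precessing", na.rm = TRUE)
    metrics$n_locked <- sum(rep_tbl$classification == "locked", na.rm = TRUE)
  }

  mf <- file.path(out_dir, paste0(config$name, "-metrics.json"))
  jsonlite::write_json(metrics, mf, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, mf)
  manifest <- tibble(file = basename(artifacts),
                     bytes = file.size(artifacts),
                     md5 = unname(tools::md5sum(artifacts)))
  manifest_path <- file.path(out_dir, paste0(config$name, "-manifest.csv"))
  utils::write.csv(as.data.frame(manifest), manifest_path, row.names = FALSE)
  attr(manifest, "metrics") <- metrics
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Summarize experiment outputs
#'
#' Renders a table of the metrics JSONs found in one or more experiment
#' directories; missing or unreadable artifacts produce an explicit failure
#' row rather than an error.
#'
#' @param dirs Character vector of experiment output directories (or a
#'   manifest returned by [run_experiment()]).
#' @return A tibble with one row per metrics file; collapsed runs are
#'   flagged in the `note` column.
#' @export
report_experiment <- function(dirs) {
  if (is_tibble(dirs) && !is.null(attr(dirs, "dir"))) dirs <- attr(dirs, "dir")
  files <- unlist(lapply(dirs, function(d)
    list.files(d, pattern = "-metrics\\.json$", full.names = TRUE)))
  if (!length(files))
    return(tibble(name = character(0), status = character(0)))
  rows <- purrr::map(files, function(f) {
    m <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(m))
      return(tibble(name = basename(f), status = "unreadable", note = ""))
    tibble(name = m$name %||% basename(f), status = "ok",
           model = m$model %||% NA_character_,
           ratio = m$ratio %||% NA_real_,
           omega_min = m$omega_min %||% NA_real_,
           omega_max = m$omega_max %||% NA_real_,
           note = if (isTRUE(m$collapse)) "collapsed" else "")
  })
  dplyr::bind_rows(rows)
}
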