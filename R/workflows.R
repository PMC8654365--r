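#' Run configuration for the two workflows
#'
#' Reads (or builds) the resolved configuration driving [run_spt_workflow()]
#' and [run_ripley_workflow()]. Configurations are plain YAML with blocks
#' mirroring the stage parameters; unknown keys are rejected so typos fail
#' loudly. Every run writes a `resolved_config.yaml` copy next to its
#' outputs.
#'
#' @param path YAML file, or `NULL` to build from `...`.
#' @param ... Named settings overriding the file (see Details).
#'
#' @details Recognized top-level keys: `workflow` (`"spt"` or `"ripley"`),
#' `seed`, `outdir`, `input` (path to a trajectory or point-pattern CSV;
#' omit to simulate), `simulate` (a [sim_config()] / [pattern_config()]
#' block), `pairs` (`s_max`, `min_frames`, `gap_max`), `msd` (`max_lag`,
#' `n_points`), `hmm` (`n_boot`, `gap_cap`), `ripley` (`r_min`, `r_max`,
#' `r_step`, `n_sims`, `alpha`, `critical_distance`).
#'
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  known <- c(
    "workflow", "seed", "outdir", "input", "simulate",
    "pairs", "msd", "hmm", "ripley"
  )
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
      class = "sptk_config_error"
    )
  }
  cfg$workflow <- cfg$workflow %||% "spt"
  if (!cfg$workflow %in% c("spt", "ripley")) {
    abort("workflow must be 'spt' or 'ripley'", class = "sptk_config_error")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "sptk_out"
  defaults <- list(
    pairs = list(s_max = 500, min_frames = 3, gap_max = 3),
    msd = list(max_lag = 10, n_points = 5),
    hmm = list(
      n_boot = 200, gap_cap = 10, method = "dwell",
      min_duration_frames = 6
    ),
    ripley = list(
      r_min = 5, r_max = 200, r_step = 5, n_sims = 999,
      alpha = 0.01, critical_distance = 50
    )
  )
  for (blk in names(defaults)) {
    user <- cfg[[blk]] %||% list()
    bad <- setdiff(names(user), names(defaults[[blk]]))
    if (length(bad)) {
      abort(sprintf(
        "unknown keys in '%s' block: %s", blk, paste(bad, collapse = ", ")
      ), class = "sptk_config_error")
    }
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], user)
  }
  structure(cfg, class = "run_config")
}

log_stage <- function(stage, t0, ...) {
  inform(sprintf(
    "[%s] %s (%.1f s) %s", format(Sys.time(), "%H:%M:%S"), stage,
    as.numeric(Sys.time()) - t0, paste(..., collapse = " ")
  ))
}

# stage-named substream of the run seed: stable if stages are added/removed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1000L + utils::head(utf8ToInt(stage), 1)) %% .Machine$integer.max
}

#' Run the SPT kinetics workflow
#'
#' Executes simulate (optional) -> ensemble MSD + diffusion fit -> candidate
#' pairs -> HMM fit -> k_off, writing every stage's table as CSV plus a JSON
#' summary into `outdir`.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with the stage results (`tracks`, `msd`,
#'   `diffusion`, `pairs`, `hmm`, `koff`) and `outdir`.
#' @export
run_spt_workflow <- function(config) {
  if (is.character(config)) config <- run_config(config)
  t0 <- as.numeric(Sys.time())

  if (!is.null(config$input)) {
    tracks <- read_trajectories(config$input) # fails before any output exists
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  } else {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- do.call(sim_config, utils::modifyList(
      config$simulate %||% list(),
      list(seed = stage_seed(config$seed, "simulate"))
    ))
    tracks <- simulate_pair_tracks(sim)
    write_trajectories(tracks, file.path(config$outdir, "trajectories.csv"))
    log_stage("simulate", t0, sprintf("%d rows", nrow(tracks)))
  }

  msd <- ensemble_msd(tracks, max_lag = config$msd$max_lag)
  dfit <- fit_diffusion(msd, n_points = config$msd$n_points)
  write_csv_exact(as.data.frame(msd), file.path(config$outdir, "msd.csv"))
  write_csv_exact(glance(dfit), file.path(config$outdir, "diffusion.csv"))
  log_stage("msd", t0, sprintf("D = %.4g um^2/s", dfit$D))

  pairs <- find_candidate_pairs(
    dplyr::filter(tracks, .data$channel == 1),
    dplyr::filter(tracks, .data$channel == 2),
    s_max = config$pairs$s_max, min_frames = config$pairs$min_frames,
    gap_max = config$pairs$gap_max
  )
  attr(pairs, "frame_rate") <- frame_rate_of(tracks)
  write_pair_series(pairs, file.path(config$outdir, "pair_series.csv"))
  log_stage("pairs", t0, sprintf("%d series", length(unique(pairs$pair_id))))

  fit <- fit_hmm(pairs, gap_cap = config$hmm$gap_cap)
  events <- viterbi_segment(pairs, fit$params)
  write_csv_exact(as.data.frame(events), file.path(config$outdir, "events.csv"))
  koff <- estimate_koff(pairs, fit,
    method = config$hmm$method,
    min_duration_frames = config$hmm$min_duration_frames,
    n_boot = config$hmm$n_boot,
    seed = stage_seed(config$seed, "hmm"), gap_cap = config$hmm$gap_cap
  )
  log_stage("hmm", t0, sprintf("k_off = %.4g 1/s", koff$k_off))

  summary <- list(
    workflow = "spt", seed = config$seed,
    D_um2_s = dfit$D, D_ci95 = c(dfit$ci95_lo, dfit$ci95_hi),
    msd_intercept_um2 = dfit$intercept,
    n_pair_series = fit$n_series,
    hmm = unclass(fit$params),
    k_off_per_s = koff$k_off, k_off_se = koff$se,
    mean_lifetime_s = koff$mean_lifetime_s
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  yaml::write_yaml(unclass(config), file.path(config$outdir, "resolved_config.yaml"))
  invisible(list(
    tracks = tracks, msd = msd, diffusion = dfit, pairs = pairs,
    hmm = fit, koff = koff, outdir = config$outdir
  ))
}

#' Run the co-clustering (Ripley) workflow
#'
#' Executes simulate (optional) -> bivariate K -> CSR envelope ->
#' co-clustering call, writing the curve, envelope and call into `outdir`.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with `pattern`, `ripley`, `call`, `outdir`.
#' @export
run_ripley_workflow <- function(config) {
  if (is.character(config)) config <- run_config(config)
  t0 <- as.numeric(Sys.time())
  rp <- config$ripley
  k_min <- floor((rp$n_sims + 1) * rp$alpha / 2)
  if (k_min < 1) {
    abort(sprintf(
      "n_sims = %d too small for alpha = %g (need >= %d)",
      rp$n_sims, rp$alpha, ceiling(2 / rp$alpha - 1)
    ), class = "sptk_config_error")
  }
  if (!is.null(config$input)) {
    pattern <- read_point_pattern(config$input) # fails before any output exists
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  } else {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- do.call(pattern_config, utils::modifyList(
      config$simulate %||% list(),
      list(seed = stage_seed(config$seed, "pattern"))
    ))
    pattern <- simulate_point_pattern(sim)
    write_point_pattern(pattern, file.path(config$outdir, "pattern.csv"))
    log_stage("simulate", t0, sprintf("%d points", nrow(pattern)))
  }

  r_grid <- seq(rp$r_min, rp$r_max, by = rp$r_step)
  res <- ripley_analysis(pattern, r_grid,
    n_sims = rp$n_sims, alpha = rp$alpha,
    seed = stage_seed(config$seed, "ripley")
  )
  call <- coclustering_test(res, critical_distance = rp$critical_distance)
  write_csv_exact(as.data.frame(res), file.path(config$outdir, "ripley.csv"))
  jsonlite::write_json(
    list(
      workflow = "ripley", seed = config$seed,
      significant_coclustering = call$significant_coclustering,
      r_exceed_nm = call$r_exceed_nm,
      critical_distance_nm = call$critical_distance_nm
    ),
    file.path(config$outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  yaml::write_yaml(unclass(config), file.path(config$outdir, "resolved_config.yaml"))
  log_stage("ripley", t0, sprintf("co-clustering: %s", call$significant_coclustering))
  invisible(list(pattern = pattern, ripley = res, call = call, outdir = config$outdir))
}
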