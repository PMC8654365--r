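#' Time-lag-averaged mean squared displacement of one track
#'
#' Computes MSD(n*dt) as the mean of `|r(i+n) - r(i)|^2` over every pair of
#' observed frames `(i, i+n)` of the track (overlapping windows, the
#' time-averaged estimator). Frames may be missing; only pairs where both
#' frames were observed contribute, and lags with no contributing pair are
#' omitted.
#'
#' @param track Data frame with columns `frame`, `x_nm`, `y_nm` for a single
#'   particle (one row per observed frame).
#' @param max_lag Largest lag, in frames.
#' @param frame_rate Frames per second used to express lags in seconds;
#'   defaults to the `frame_rate` attribute of `track`.
#'
#' @return A tibble of class `"msd_curve"` with columns `lag_frames`,
#'   `lag_s`, `msd_um2` and `n_jumps`.
#' @export
#' @examples
#' tr <- tibble::tibble(frame = 0:2, x_nm = c(0, 1000, 2000), y_nm = 0)
#' compute_msd(tr, max_lag = 2, frame_rate = 20)
compute_msd <- function(track, max_lag = 10, frame_rate = NULL) {
  frame_rate <- frame_rate %||% attr(track, "frame_rate")
  if (is.null(frame_rate)) {
    abort("supply frame_rate or a track with a frame_rate attribute",
      class = "sptk_config_error"
    )
  }
  if (nrow(track) < 2) {
    abort("track has fewer than 2 localizations; MSD undefined",
      class = "sptk_empty_track_error"
    )
  }
  ord <- order(track$frame)
  fr <- as.integer(track$frame[ord])
  if (anyDuplicated(fr)) {
    abort("duplicated frames within one track", class = "sptk_input_error")
  }
  x <- track$x_nm[ord] / 1000 # work in um
  y <- track$y_nm[ord] / 1000
  idx <- rep(NA_integer_, max(fr) - min(fr) + 1L)
  idx[fr - min(fr) + 1L] <- seq_along(fr)

  res <- purrr::map(seq_len(max_lag), function(n) {
    if (n > length(idx) - 1L) {
      return(NULL)
    }
    i <- idx[seq_len(length(idx) - n)]
    j <- idx[seq_len(length(idx) - n) + n]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) {
      return(NULL)
    }
    sq <- (x[j[ok]] - x[i[ok]])^2 + (y[j[ok]] - y[i[ok]])^2
    tibble(lag_frames = n, msd_um2 = mean(sq), n_jumps = sum(ok))
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out, lag_s = .data$lag_frames / frame_rate, .after = "lag_frames")
  structure(out, class = c("msd_curve", class(out)), frame_rate = frame_rate)
}

#' Ensemble (jump-weighted) MSD over many tracks
#'
#' Pools the squared displacements of all tracks per lag: each contributing
#' frame pair counts once, so tracks enter in proportion to the number of
#' jumps they provide, matching how ensemble MSD curves report pooled jump
#' counts.
#'
#' @param tracks Trajectory table (columns `frame`, `particle_id`, `x_nm`,
#'   `y_nm`; a `cell` column, if present, is ignored here).
#' @param max_lag Largest lag in frames.
#' @param frame_rate Frames per second; defaults to the table's attribute.
#'
#' @return A tibble of class `"msd_curve"`.
#' @export
ensemble_msd <- function(tracks, max_lag = 10, frame_rate = NULL) {
  frame_rate <- frame_rate %||% attr(tracks, "frame_rate")
  if (is.null(frame_rate)) {
    abort("supply frame_rate or tracks with a frame_rate attribute",
      class = "sptk_config_error"
    )
  }
  usable <- dplyr::count(tracks, .data$particle_id)
  usable <- usable$particle_id[usable$n >= 2]
  if (length(usable) == 0) {
    abort("no track has >= 2 localizations", class = "sptk_empty_track_error")
  }
  per_track <- tracks |>
    dplyr::filter(.data$particle_id %in% usable) |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_map(~ compute_msd(.x, max_lag = max_lag, frame_rate = frame_rate))
  pooled <- dplyr::bind_rows(per_track) |>
    dplyr::group_by(.data$lag_frames, .data$lag_s) |>
    dplyr::summarise(
      msd_um2 = sum(.data$msd_um2 * .data$n_jumps) / sum(.data$n_jumps),
      n_jumps = sum(.data$n_jumps),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag_frames) |>
    dplyr::relocate("lag_frames", "lag_s", "msd_um2", "n_jumps")
  structure(pooled, class = c("msd_curve", class(pooled)), frame_rate = frame_rate)
}

#' Fit a Brownian diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of MSD on time lag over the first `n_points` lags,
#' with an intercept. For 2-D Brownian motion MSD = 4 D t + 4 sigma^2, so
#' `D = slope / 4` and the intercept absorbs the localization-noise offset.
#' The 95% confidence interval comes from the slope's standard error with
#' `n_points - 2` degrees of freedom. A non-positive D is reported, not
#' censored, and flagged.
#'
#' @param curve An [compute_msd()]/[ensemble_msd()] result (or any data
#'   frame with `lag_s`, `msd_um2`, `n_jumps`).
#' @param n_points Number of leading lags to fit (default 5).
#'
#' @return An object of class `"diffusion_fit"`: a list with elements `D`
#'   (um^2/s), `intercept` (um^2), `ci95_lo`, `ci95_hi`, `se`,
#'   `n_points_fit`, `n_jumps_total`, `nonpositive_D` and the underlying
#'   `lm` fit. Has [tidy()] and [glance()] methods.
#' @export
fit_diffusion <- function(curve, n_points = 5) {
  if (nrow(curve) < n_points) {
    abort(sprintf(
      "MSD curve has %d lags; %d required for the fit",
      nrow(curve), n_points
    ), class = "sptk_insufficient_data_error")
  }
  dat <- dplyr::arrange(curve, .data$lag_s)[seq_len(n_points), ]
  fit <- lm(msd_um2 ~ lag_s, data = dat)
  slope <- unname(coef(fit)[2])
  # summary() warns on exact fits; a zero-width CI is a legitimate outcome
  se_slope <- suppressWarnings(summary(fit))$coefficients[2, 2]
  tcrit <- qt(0.975, df = n_points - 2)
  D <- slope / 4
  se_D <- se_slope / 4
  # a slope at numerical zero (e.g. a flat noise-floor curve) counts as no
  # measurable diffusion
  zero_scale <- .Machine$double.eps^0.5 * max(abs(dat$msd_um2)) / max(dat$lag_s)
  out <- list(
    D = D,
    intercept = unname(coef(fit)[1]),
    se = se_D,
    ci95_lo = D - tcrit * se_D,
    ci95_hi = D + tcrit * se_D,
    n_points_fit = n_points,
    n_jumps_total = sum(dat$n_jumps),
    nonpositive_D = D <= zero_scale,
    fit = fit
  )
  if (out$nonpositive_D) {
    warn(sprintf("fitted D = %.3g um^2/s is not positive", D))
  }
  structure(out, class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Brownian diffusion fit (first %d MSD points)\n  D = %.4g um^2/s  [95%% CI %.4g, %.4g]\n  intercept = %.4g um^2   n_jumps = %d\n",
    x$n_points_fit, x$D, x$ci95_lo, x$ci95_hi, x$intercept, x$n_jumps_total
  ))
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(
    term = c("D", "intercept"),
    estimate = c(x$D, x$intercept),
    std.error = c(x$se, summary(x$fit)$coefficients[1, 2]),
    conf.low = c(x$ci95_lo, NA_real_),
    conf.high = c(x$ci95_hi, NA_real_)
  )
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(
    D = x$D, intercept = x$intercept,
    ci95_lo = x$ci95_lo, ci95_hi = x$ci95_hi,
    n_points_fit = x$n_points_fit, n_jumps_total = x$n_jumps_total,
    r.squared = summary(x$fit)$r.squared
  )
}

#' Per-cell diffusion coefficients
#'
#' Runs one ensemble-MSD fit per cell, reproducing "distribution of D across
#' cells" analyses. Cells whose tracks cannot support the fit are skipped
#' with a warning.
#'
#' @param tracks Trajectory table with a grouping column (default `cell`).
#' @param cell_col Name of the grouping column.
#' @param n_points,max_lag Fit settings passed on.
#' @param frame_rate Frames per second; defaults to the table's attribute.
#'
#' @return A tibble with one row per cell: `cell`, `D`, `intercept`,
#'   `ci95_lo`, `ci95_hi`, `n_jumps_total`.
#' @export
per_cell_D <- function(tracks, cell_col = "cell", n_points = 5, max_lag = 10,
                       frame_rate = NULL) {
  if (!cell_col %in% names(tracks)) {
    abort(sprintf("grouping column '%s' not found", cell_col),
      class = "sptk_input_error"
    )
  }
  frame_rate <- frame_rate %||% attr(tracks, "frame_rate")
  cells <- split(as_tibble(tracks), tracks[[cell_col]])
  rows <- purrr::imap(cells, function(df, key) {
    est <- tryCatch(
      fit_diffusion(ensemble_msd(df, max_lag = max_lag, frame_rate = frame_rate),
        n_points = n_points
      ),
      error = function(e) {
        warn(sprintf("cell '%s' skipped: %s", key, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(est)) {
      return(NULL)
    }
    tibble(
      cell = key, D = est$D, intercept = est$intercept,
      ci95_lo = est$ci95_lo, ci95_hi = est$ci95_hi,
      n_jumps_total = est$n_jumps_total
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare per-cell mobility between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on per-cell diffusion coefficients; the
#' rank test is robust to the right skew typical of per-cell D
#' distributions.
#'
#' @param D_groupA,D_groupB Numeric vectors of per-cell D values.
#'
#' @return A tibble with `statistic`, `p.value`, `n_A`, `n_B`, `method`.
#' @export
compare_mobility <- function(D_groupA, D_groupB) {
  if (length(D_groupA) < 3 || length(D_groupB) < 3) {
    abort("need >= 3 cells per group", class = "sptk_insufficient_data_error")
  }
  if (length(unique(c(D_groupA, D_groupB))) == 1) {
    warn("all D values tied across both groups; p = 1")
    return(tibble(
      statistic = NA_real_, p.value = 1,
      n_A = length(D_groupA), n_B = length(D_groupB),
      method = "Wilcoxon rank-sum (degenerate: all tied)"
    ))
  }
  wt <- suppressWarnings(wilcox.test(D_groupA, D_groupB, exact = FALSE))
  tibble(
    statistic = unname(wt$statistic), p.value = wt$p.value,
    n_A = length(D_groupA), n_B = length(D_groupB),
    method = wt$method
  )
}
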