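#' Find candidate two-color particle pairs
#'
#' Scans all cross-channel particle pairs and extracts the stretches during
#' which the two particles are co-observed closer than `s_max`. A stretch
#' tolerates internal gaps of up to `gap_max` missing frames (no jump is
#' recorded across a gap); longer interruptions split it. Stretches with at
#' least `min_frames` co-observed frames become one pair series each; a
#' particle may belong to several pairs.
#'
#' @param tracks_ch1,tracks_ch2 Trajectory tables (or data frames with
#'   `frame`, `particle_id`, `x_nm`, `y_nm`) for the two channels.
#' @param s_max Separation gate, nm (default 500).
#' @param min_frames Minimum co-observed frames per series (default 3).
#' @param gap_max Longest internal gap retained as missing (default 3).
#'
#' @return A tibble of class `"pair_series"` with columns `pair_id`, `id1`,
#'   `id2`, `frame`, `x1_nm`, `y1_nm`, `x2_nm`, `y2_nm`, `s_nm`, ordered by
#'   pair then frame. Attribute `frame_rate` is propagated when available.
#' @export
find_candidate_pairs <- function(tracks_ch1, tracks_ch2, s_max = 500,
                                 min_frames = 3, gap_max = 3) {
  if (nrow(tracks_ch1) == 0 || nrow(tracks_ch2) == 0) {
    abort("both channels must contain localizations", class = "sptk_input_error")
  }
  t1 <- dplyr::select(as_tibble(tracks_ch1), "particle_id", "frame", "x_nm", "y_nm")
  t2 <- dplyr::select(as_tibble(tracks_ch2), "particle_id", "frame", "x_nm", "y_nm")

  # frames-by-particles position matrices (NA where unobserved): lets the
  # all-pairs separation scan run as vectorized column arithmetic instead of
  # a many-to-many join, which matters at hundreds of tracks x 10^3 frames
  all_frames <- seq(min(t1$frame, t2$frame), max(t1$frame, t2$frame))
  to_mats <- function(t) {
    ids <- sort(unique(t$particle_id))
    X <- Y <- matrix(NA_real_, nrow = length(all_frames), ncol = length(ids))
    ri <- match(t$frame, all_frames)
    ci <- match(t$particle_id, ids)
    X[cbind(ri, ci)] <- t$x_nm
    Y[cbind(ri, ci)] <- t$y_nm
    list(ids = ids, X = X, Y = Y)
  }
  m1 <- to_mats(t1)
  m2 <- to_mats(t2)

  rows <- list()
  for (i in seq_along(m1$ids)) {
    d2 <- (m2$X - m1$X[, i])^2 + (m2$Y - m1$Y[, i])^2
    hit <- which(colSums(d2 < s_max^2, na.rm = TRUE) > 0)
    for (j in hit) {
      ok <- which(!is.na(d2[, j]) & d2[, j] < s_max^2)
      rows[[length(rows) + 1L]] <- tibble(
        particle_id1 = m1$ids[i], particle_id2 = m2$ids[j],
        frame = all_frames[ok],
        x_nm1 = m1$X[ok, i], y_nm1 = m1$Y[ok, i],
        x_nm2 = m2$X[ok, j], y_nm2 = m2$Y[ok, j],
        s_nm = sqrt(d2[ok, j])
      )
    }
  }
  if (length(rows) == 0) {
    return(empty_pair_series(attr(tracks_ch1, "frame_rate")))
  }
  joined <- dplyr::arrange(
    dplyr::bind_rows(rows),
    .data$particle_id1, .data$particle_id2, .data$frame
  )

  # split runs: new series at a particle-pair change or a gap > gap_max
  new_pair <- c(TRUE, diff(joined$particle_id1) != 0 | diff(joined$particle_id2) != 0)
  gap <- c(0L, diff(joined$frame))
  new_run <- new_pair | (gap > gap_max + 1L)
  run_id <- cumsum(new_run)

  out <- joined |>
    dplyr::mutate(run = run_id) |>
    dplyr::group_by(.data$run) |>
    dplyr::filter(dplyr::n() >= min_frames) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    return(empty_pair_series(attr(tracks_ch1, "frame_rate")))
  }
  out <- out |>
    dplyr::mutate(pair_id = match(.data$run, unique(.data$run))) |>
    dplyr::transmute(
      pair_id = .data$pair_id,
      id1 = .data$particle_id1, id2 = .data$particle_id2,
      frame = .data$frame,
      x1_nm = .data$x_nm1, y1_nm = .data$y_nm1,
      x2_nm = .data$x_nm2, y2_nm = .data$y_nm2,
      s_nm = .data$s_nm
    )
  structure(out,
    class = c("pair_series", class(out)),
    frame_rate = attr(tracks_ch1, "frame_rate") %||% attr(tracks_ch2, "frame_rate"),
    s_max = s_max
  )
}

#' Pair series of the simulator's true pairs
#'
#' For a simulated trajectory table (where pair `i` is particles `2i - 1`
#' and `2i`), joins the two partners frame by frame without any separation
#' gate. Useful for closed-form checks and estimator studies where the
#' candidate-pair search would truncate the separation distribution.
#'
#' @param tracks A [simulate_pair_tracks()] result.
#' @return A pair-series tibble (same shape as [find_candidate_pairs()]).
#' @export
pair_series_from_tracks <- function(tracks) {
  t1 <- dplyr::filter(as_tibble(tracks), .data$channel == 1)
  t2 <- dplyr::filter(as_tibble(tracks), .data$channel == 2)
  t1$pair_id <- (t1$particle_id + 1L) %/% 2L
  t2$pair_id <- t2$particle_id %/% 2L
  out <- dplyr::inner_join(t1, t2,
    by = c("pair_id", "frame"), suffix = c("1", "2")
  ) |>
    dplyr::transmute(
      pair_id = .data$pair_id,
      id1 = .data$particle_id1, id2 = .data$particle_id2,
      frame = .data$frame,
      x1_nm = .data$x_nm1, y1_nm = .data$y_nm1,
      x2_nm = .data$x_nm2, y2_nm = .data$y_nm2,
      s_nm = sqrt((.data$x_nm1 - .data$x_nm2)^2 + (.data$y_nm1 - .data$y_nm2)^2)
    ) |>
    dplyr::arrange(.data$pair_id, .data$frame)
  structure(out,
    class = c("pair_series", class(out)),
    frame_rate = attr(tracks, "frame_rate")
  )
}

empty_pair_series <- function(frame_rate = NULL) {
  out <- tibble(
    pair_id = integer(0), id1 = integer(0), id2 = integer(0),
    frame = integer(0), x1_nm = numeric(0), y1_nm = numeric(0),
    x2_nm = numeric(0), y2_nm = numeric(0), s_nm = numeric(0)
  )
  structure(out, class = c("pair_series", class(out)), frame_rate = frame_rate)
}

# per-interval jumps of both particles: one row per pair of consecutive
# observed frames (frame and frame + 1 both present)
pair_jumps <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      consecutive = dplyr::lead(.data$frame) == .data$frame + 1L,
      dx1 = dplyr::lead(.data$x1_nm) - .data$x1_nm,
      dy1 = dplyr::lead(.data$y1_nm) - .data$y1_nm,
      dx2 = dplyr::lead(.data$x2_nm) - .data$x2_nm,
      dy2 = dplyr::lead(.data$y2_nm) - .data$y2_nm
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$consecutive) & .data$consecutive) |>
    dplyr::transmute(
      pair_id = .data$pair_id,
      frame = .data$frame,
      s_start_nm = .data$s_nm,
      jump1_nm = sqrt(.data$dx1^2 + .data$dy1^2),
      jump2_nm = sqrt(.data$dx2^2 + .data$dy2^2),
      uncorr_jump_nm = sqrt((.data$dx1 - .data$dx2)^2 + (.data$dy1 - .data$dy2)^2)
    )
}

#' Correlated-motion statistics versus pair separation
#'
#' Bins every frame-to-frame interval of every pair series by the pair
#' separation at the interval start and reports, per bin, the mean jump
#' magnitude `(|dr1| + |dr2|) / 2` and the mean uncorrelated jump distance
#' `|dr1 - dr2|` (magnitude of the relative displacement). For two particles
#' moving as one complex the relative displacement collapses toward the
#' localization-noise floor, which is the correlated-motion signature.
#'
#' @param pairs A [find_candidate_pairs()] result.
#' @param bin_edges Separation bin edges in nm (default 0-500 by 50).
#'
#' @return A tibble of class `"correlated_motion"`: `sep_bin_nm` (bin
#'   center), `mean_jump_nm`, `mean_uncorr_jump_nm`, `mean_sq_uncorr_jump_nm2`
#'   and `n_jumps`. Empty bins keep `n_jumps = 0` and `NA` means.
#' @export
correlated_jump_stats <- function(pairs, bin_edges = seq(0, 500, by = 50)) {
  jumps <- pair_jumps(pairs)
  if (nrow(jumps) == 0) {
    abort("no pair contributes a jump", class = "sptk_insufficient_data_error")
  }
  centers <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  jumps$bin <- cut(jumps$s_start_nm, breaks = bin_edges, include.lowest = TRUE)
  stats <- jumps |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      mean_jump_nm = mean((.data$jump1_nm + .data$jump2_nm) / 2),
      mean_uncorr_jump_nm = mean(.data$uncorr_jump_nm),
      mean_sq_uncorr_jump_nm2 = mean(.data$uncorr_jump_nm^2),
      n_jumps = dplyr::n(),
      .groups = "drop"
    )
  out <- tibble(
    sep_bin_nm = centers,
    mean_jump_nm = stats$mean_jump_nm,
    mean_uncorr_jump_nm = stats$mean_uncorr_jump_nm,
    mean_sq_uncorr_jump_nm2 = stats$mean_sq_uncorr_jump_nm2,
    n_jumps = stats$n_jumps
  )
  structure(out, class = c("correlated_motion", class(out)), bin_edges = bin_edges)
}
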