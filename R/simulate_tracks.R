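#' Simulation settings for two-color pair trajectories
#'
#' Bundles every parameter of the two-color quantum-dot tracking simulator
#' into a validated list. Defaults mirror the acquisition settings of the
#' live-cell experiments the simulator emulates: 20 frames/s camera rate and
#' movies up to 1000 frames.
#'
#' @param n_pairs Number of two-particle (one per channel) pairs to simulate.
#' @param n_frames Movie length in frames (>= 2).
#' @param frame_rate Camera rate, frames per second.
#' @param D_free_ch1,D_free_ch2 Free-state diffusion coefficients, um^2/s.
#' @param D_dimer Diffusion coefficient of the dimer center, um^2/s.
#' @param k_on Association rate while the pair is within `capture_radius`,
#'    1/s. A nuisance parameter: it controls how often dimers form, not any
#'   quantity estimated downstream.
#' @param k_off Dissociation rate of the dimer, 1/s.
#' @param capture_radius Separation below which association can occur, nm.
#' @param dimer_separation Fixed physical distance between the two labels in
#'   a dimer, nm (label offset; orientation is redrawn every frame).
#' @param sigma_loc_ch1,sigma_loc_ch2 Per-axis localization precision, nm.
#' @param p_miss Per-frame probability that an observation is dropped,
#'   in `[0, 1)`.
#' @param p_dimer_init Probability that a pair starts in the dimer state.
#' @param roi_size Side of the square field of view, nm. Boundaries reflect.
#' @param seed Integer seed; the same config reproduces identical tables.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_pair_tracks()]
#' @export
sim_config <- function(n_pairs = 100,
                       n_frames = 1000,
                       frame_rate = 20,
                       D_free_ch1 = 0.1,
                       D_free_ch2 = 0.1,
                       D_dimer = 0.05,
                       k_on = 2,
                       k_off = 0.18,
                       capture_radius = 150,
                       dimer_separation = 20,
                       sigma_loc_ch1 = 20,
                       sigma_loc_ch2 = 20,
                       p_miss = 0,
                       p_dimer_init = 0.5,
                       roi_size = 20000,
                       seed = 1L) {
  cfg <- list(
    n_pairs = n_pairs, n_frames = n_frames, frame_rate = frame_rate,
    D_free_ch1 = D_free_ch1, D_free_ch2 = D_free_ch2, D_dimer = D_dimer,
    k_on = k_on, k_off = k_off, capture_radius = capture_radius,
    dimer_separation = dimer_separation,
    sigma_loc_ch1 = sigma_loc_ch1, sigma_loc_ch2 = sigma_loc_ch2,
    p_miss = p_miss, p_dimer_init = p_dimer_init,
    roi_size = roi_size, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) {
    abort("all sim_config fields must be numeric", class = "sptk_config_error")
  }
  if (!all(vapply(cfg, function(x) length(x) == 1 && is.finite(x), logical(1)))) {
    abort("all sim_config fields must be finite scalars", class = "sptk_config_error")
  }
  nonneg <- c(
    "D_free_ch1", "D_free_ch2", "D_dimer", "k_on", "k_off",
    "capture_radius", "dimer_separation", "sigma_loc_ch1", "sigma_loc_ch2"
  )
  bad <- nonneg[vapply(nonneg, function(f) cfg[[f]] < 0, logical(1))]
  if (length(bad)) {
    abort(paste0("sim_config fields must be >= 0: ", paste(bad, collapse = ", ")),
      class = "sptk_config_error"
    )
  }
  if (cfg$p_miss < 0 || cfg$p_miss >= 1) {
    abort("p_miss must lie in [0, 1)", class = "sptk_config_error")
  }
  if (cfg$p_dimer_init < 0 || cfg$p_dimer_init > 1) {
    abort("p_dimer_init must lie in [0, 1]", class = "sptk_config_error")
  }
  if (cfg$frame_rate <= 0) abort("frame_rate must be > 0", class = "sptk_config_error")
  if (cfg$n_frames < 2) abort("n_frames must be >= 2", class = "sptk_config_error")
  if (cfg$n_pairs < 1) abort("n_pairs must be >= 1", class = "sptk_config_error")
  if (cfg$roi_size <= 0) abort("roi_size must be > 0", class = "sptk_config_error")
  invisible(cfg)
}

# reflect coordinates into [0, L] (single bounce suffices for step << L)
reflect_into <- function(x, L) {
  x <- abs(x)
  over <- x > L
  x[over] <- 2 * L - x[over]
  pmin(pmax(x, 0), L)
}

#' Simulate two-color trajectories of dimerizing particle pairs
#'
#' Discrete-time, continuous-space simulation of `n_pairs` two-particle
#' pairs (channel 1 + channel 2) at the camera interval `dt = 1/frame_rate`.
#' In the free state the two particles diffuse independently (per-axis step
#' variance `2 * D_free * dt`); a free pair closer than `capture_radius`
#' dimerizes at a frame step with probability `1 - exp(-k_on * dt)`. In the
#' dimer state a common center diffuses with variance `2 * D_dimer * dt` and
#' the two labels sit `dimer_separation` nm apart with orientation redrawn
#' every frame (fast rotational diffusion limit); the dimer dissociates with
#' probability `1 - exp(-k_off * dt)`. Observed positions add per-axis
#' Gaussian localization noise and are dropped independently with
#' probability `p_miss`. Boundaries of the square ROI reflect.
#'
#' @param config A [sim_config()].
#'
#' @return A tibble of class `"trajectory_table"` with columns `frame`
#'   (0-based), `particle_id`, `channel` (1 or 2), `x_nm`, `y_nm`, and
#'   attributes `frame_rate`, `roi_size` and `ground_truth` (a tibble
#'   `pair_id, frame, state` of the true per-frame state). Pair `i` is made
#'   of particles `2i - 1` (channel 1) and `2i` (channel 2).
#' @export
#' @examples
#' trks <- simulate_pair_tracks(sim_config(n_pairs = 5, n_frames = 50))
#' dplyr::count(trks, channel)
simulate_pair_tracks <- function(config) {
  validate_sim_config(config)
  withr::local_seed(config$seed)

  np <- as.integer(config$n_pairs)
  nf <- as.integer(config$n_frames)
  dt <- 1 / config$frame_rate
  L <- config$roi_size
  # nm-scale step standard deviations (D in um^2/s -> nm^2/s via 1e6)
  sd1 <- sqrt(2 * config$D_free_ch1 * 1e6 * dt)
  sd2 <- sqrt(2 * config$D_free_ch2 * 1e6 * dt)
  sdd <- sqrt(2 * config$D_dimer * 1e6 * dt)
  p_on <- 1 - exp(-config$k_on * dt)
  p_off <- 1 - exp(-config$k_off * dt)
  half_sep <- config$dimer_separation / 2

  rms_disp <- sqrt(4 * max(config$D_free_ch1, config$D_free_ch2, config$D_dimer) *
    1e6 * dt * nf)
  if (L < 10 * rms_disp) {
    inform(sprintf(
      "roi_size (%g nm) is within 10x of the expected root-mean-square excursion (%g nm); reflecting-boundary effects may be visible",
      L, rms_disp
    ))
  }

  # state 1 = free, 2 = dimer
  state <- ifelse(runif(np) < config$p_dimer_init, 2L, 1L)

  # initial positions: pair centers uniform in the ROI, partner within the
  # capture disk so encounters are possible within a finite movie
  cx <- runif(np, 0, L)
  cy <- runif(np, 0, L)
  th0 <- runif(np, 0, 2 * pi)
  r0 <- config$capture_radius * sqrt(runif(np))
  x1 <- reflect_into(cx - r0 / 2 * cos(th0), L)
  y1 <- reflect_into(cy - r0 / 2 * sin(th0), L)
  x2 <- reflect_into(cx + r0 / 2 * cos(th0), L)
  y2 <- reflect_into(cy + r0 / 2 * sin(th0), L)
  dimer <- state == 2L
  if (any(dimer)) { # dimer pairs start on a common center
    th <- runif(sum(dimer), 0, 2 * pi)
    x1[dimer] <- reflect_into(cx[dimer] - half_sep * cos(th), L)
    y1[dimer] <- reflect_into(cy[dimer] - half_sep * sin(th), L)
    x2[dimer] <- reflect_into(cx[dimer] + half_sep * cos(th), L)
    y2[dimer] <- reflect_into(cy[dimer] + half_sep * sin(th), L)
  }

  X1 <- Y1 <- X2 <- Y2 <- matrix(NA_real_, nrow = nf, ncol = np)
  S <- matrix(NA_integer_, nrow = nf, ncol = np)
  X1[1, ] <- x1; Y1[1, ] <- y1; X2[1, ] <- x2; Y2[1, ] <- y2
  S[1, ] <- state

  for (f in 2:nf) {
    free <- state == 1L
    dimer <- !free
    # transitions decided on the state at the previous frame
    if (any(free)) {
      sep <- sqrt((x1[free] - x2[free])^2 + (y1[free] - y2[free])^2)
      go <- runif(sum(free)) < p_on & sep < config$capture_radius
      state[free][go] <- 2L
    }
    if (any(dimer)) {
      go <- runif(sum(dimer)) < p_off
      state[dimer][go] <- 1L
    }
    fr <- state == 1L

    if (any(fr)) {
      n <- sum(fr)
      x1[fr] <- reflect_into(x1[fr] + rnorm(n, 0, sd1), L)
      y1[fr] <- reflect_into(y1[fr] + rnorm(n, 0, sd1), L)
      x2[fr] <- reflect_into(x2[fr] + rnorm(n, 0, sd2), L)
      y2[fr] <- reflect_into(y2[fr] + rnorm(n, 0, sd2), L)
    }
    dm <- state == 2L
    if (any(dm)) {
      n <- sum(dm)
      cx <- (x1[dm] + x2[dm]) / 2
      cy <- (y1[dm] + y2[dm]) / 2
      cx <- reflect_into(cx + rnorm(n, 0, sdd), L)
      cy <- reflect_into(cy + rnorm(n, 0, sdd), L)
      th <- runif(n, 0, 2 * pi)
      x1[dm] <- reflect_into(cx - half_sep * cos(th), L)
      y1[dm] <- reflect_into(cy - half_sep * sin(th), L)
      x2[dm] <- reflect_into(cx + half_sep * cos(th), L)
      y2[dm] <- reflect_into(cy + half_sep * sin(th), L)
    }
    X1[f, ] <- x1; Y1[f, ] <- y1; X2[f, ] <- x2; Y2[f, ] <- y2
    S[f, ] <- state
  }

  frames <- rep(0:(nf - 1L), times = np)
  pair_of <- rep(seq_len(np), each = nf)
  obs1 <- tibble(
    frame = frames,
    particle_id = 2L * pair_of - 1L,
    channel = 1L,
    x_nm = as.vector(X1) + rnorm(nf * np, 0, config$sigma_loc_ch1),
    y_nm = as.vector(Y1) + rnorm(nf * np, 0, config$sigma_loc_ch1)
  )
  obs2 <- tibble(
    frame = frames,
    particle_id = 2L * pair_of,
    channel = 2L,
    x_nm = as.vector(X2) + rnorm(nf * np, 0, config$sigma_loc_ch2),
    y_nm = as.vector(Y2) + rnorm(nf * np, 0, config$sigma_loc_ch2)
  )
  out <- dplyr::bind_rows(obs1, obs2)
  if (config$p_miss > 0) {
    out <- out[runif(nrow(out)) >= config$p_miss, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$particle_id, .data$frame)

  gt <- tibble(
    pair_id = pair_of,
    frame = frames,
    state = c("free", "dimer")[as.vector(S)]
  )
  new_trajectory_table(out,
    frame_rate = config$frame_rate, roi_size = L,
    ground_truth = gt
  )
}

new_trajectory_table <- function(df, frame_rate, roi_size = NA_real_,
                                 ground_truth = NULL) {
  out <- as_tibble(df)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "roi_size") <- roi_size
  attr(out, "ground_truth") <- ground_truth
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Frame rate stored with a trajectory table
#' @param tracks A trajectory table.
#' @return Frames per second (scalar).
#' @export
frame_rate_of <- function(tracks) {
  fr <- attr(tracks, "frame_rate")
  if (is.null(fr)) abort("tracks carry no frame_rate attribute", class = "sptk_config_error")
  fr
}

#' Ground-truth state sequence of a simulated trajectory table
#' @param tracks A trajectory table produced by [simulate_pair_tracks()].
#' @return Tibble `pair_id, frame, state` or `NULL` for real data.
#' @export
ground_truth_of <- function(tracks) attr(tracks, "ground_truth")
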