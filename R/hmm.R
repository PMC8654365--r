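#' Two-state hidden Markov model parameters
#'
#' Parameters of the free/dimer HMM over pair-separation series. Per-frame
#' transition probabilities `p_on` (free to dimer) and `p_off` (dimer to
#' free) encode the association/dissociation kinetics at the camera
#' interval; the emission densities encode what separations each state
#' produces: a Rayleigh density with scale `sigma_d` for the dimer state
#' (isotropic Gaussian scatter of the measured label-label vector, which
#' absorbs both localization error and the physical label offset) and a
#' triangular-in-radius density `2 s / s_max^2` on `(0, s_max]` for the free
#' state (a partner positioned uniformly within the candidate disk).
#'
#' @param p_on,p_off Per-frame transition probabilities in `[0, 1]`.
#' @param sigma_d Dimer emission scale, nm (> 0).
#' @param s_max Free-state support bound, nm; fix it to the candidate-pair
#'   gate used upstream.
#' @param pi_dimer Initial dimer probability in `[0, 1]`.
#'
#' @return A list of class `"hmm_params"`.
#' @export
hmm_params <- function(p_on = 0.05, p_off = 0.02, sigma_d = 40,
                       s_max = 500, pi_dimer = 0.3) {
  p <- list(
    p_on = p_on, p_off = p_off, sigma_d = sigma_d,
    s_max = s_max, pi_dimer = pi_dimer
  )
  validate_hmm_params(p)
  structure(p, class = "hmm_params")
}

validate_hmm_params <- function(p) {
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1)))) {
    abort("all hmm_params fields must be finite scalars", class = "sptk_config_error")
  }
  probs <- c("p_on", "p_off", "pi_dimer")
  if (any(vapply(probs, function(f) p[[f]] < 0 || p[[f]] > 1, logical(1)))) {
    abort("p_on, p_off, pi_dimer must lie in [0, 1]", class = "sptk_config_error")
  }
  if (p$sigma_d <= 0) abort("sigma_d must be > 0", class = "sptk_config_error")
  if (p$s_max <= 0) abort("s_max must be > 0", class = "sptk_config_error")
  invisible(p)
}

#' State-conditional emission density of the pair separation
#'
#' @param s Separations, nm (>= 0); vectorized.
#' @param state `"free"` or `"dimer"`.
#' @param params An [hmm_params()].
#'
#' @return Density values; each density integrates to 1 on its support.
#' @export
emission_density <- function(s, state, params) {
  validate_hmm_params(params)
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("separations must be finite and >= 0", class = "sptk_input_error")
  }
  switch(state,
    dimer = ifelse(s > 0, (s / params$sigma_d^2) * exp(-s^2 / (2 * params$sigma_d^2)), 0),
    free = ifelse(s > 0 & s <= params$s_max, 2 * s / params$s_max^2, 0),
    abort("state must be 'free' or 'dimer'", class = "sptk_input_error")
  )
}

# split each pair series at frame gaps > gap_cap and return concatenated
# arrays for the C++ recursions
prepare_series <- function(pairs, gap_cap = 10) {
  if (nrow(pairs) == 0) abort("no pair series", class = "sptk_insufficient_data_error")
  if (any(!is.finite(pairs$s_nm))) {
    abort("non-finite separations", class = "sptk_input_error")
  }
  pairs <- dplyr::arrange(pairs, .data$pair_id, .data$frame)
  gap <- c(1L, diff(pairs$frame))
  new_series <- c(TRUE, diff(pairs$pair_id) != 0) | gap > gap_cap
  gap[new_series] <- 1L
  sid <- cumsum(new_series)
  len <- as.integer(table(sid))
  list(
    s = pairs$s_nm,
    gap = as.integer(gap),
    start = c(0L, cumsum(len)[-length(len)]),
    len = len,
    series_id = sid,
    pair_id = pairs$pair_id,
    frame = pairs$frame
  )
}

#' Forward log-likelihood of pair-separation series under the two-state HMM
#'
#' Scaled forward recursion over the free/dimer chain, summed over all
#' series. Gaps of `g` missing frames contribute the `g`-step transition
#' matrix (closed-form power of the 2x2 chain) and no emission term; gaps
#' longer than `gap_cap` frames split the series.
#'
#' @param pairs A pair-series tibble (see [find_candidate_pairs()]) or any
#'   data frame with `pair_id`, `frame`, `s_nm`.
#' @param params An [hmm_params()].
#' @param gap_cap Longest bridged gap, frames.
#'
#' @return Total log-likelihood (scalar).
#' @export
forward_loglik <- function(pairs, params, gap_cap = 10) {
  validate_hmm_params(params)
  d <- prepare_series(pairs, gap_cap)
  hmm_forward_batch_cpp(
    d$s, d$gap, d$start, d$len,
    params$p_on, params$p_off, params$sigma_d, params$s_max, params$pi_dimer
  )
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit the two-state dimer HMM by maximum likelihood
#'
#' Maximizes the summed forward log-likelihood over all series by bounded
#' quasi-Newton (L-BFGS-B) on logit/log-transformed parameters, from five
#' deterministic starting points spread over the parameter space (the best
#' final likelihood wins), so the fit is reproducible given the data. The
#' free-state support `s_max` stays fixed at the candidate gate.
#'
#' @param pairs Pair-series tibble with `pair_id`, `frame`, `s_nm`.
#' @param init An [hmm_params()] giving initial values and `s_max`; default
#'   uses the `s_max` attribute of `pairs`.
#' @param fixed Character vector naming parameters to hold at their `init`
#'   value (subset of `p_on`, `p_off`, `sigma_d`, `pi_dimer`).
#' @param gap_cap Longest bridged frame gap.
#' @param multi_start Use the five spread starting points (`TRUE`) or only
#'   `init` (`FALSE`, faster; used by the bootstrap).
#'
#' @return An object of class `"dimer_hmm"`: `params` ([hmm_params()]),
#'   `log_likelihood`, `n_series`, `n_obs`, `convergence`, `fixed`.
#'   Has [tidy()] and [glance()] methods.
#' @export
fit_hmm <- function(pairs, init = NULL, fixed = character(), gap_cap = 10,
                    multi_start = TRUE) {
  if (is.null(init)) {
    s_max <- attr(pairs, "s_max") %||% max(pairs$s_nm) * 1.001
    init <- hmm_params(s_max = s_max)
  }
  validate_hmm_params(init)
  d <- prepare_series(pairs, gap_cap)

  free_names <- setdiff(c("p_on", "p_off", "sigma_d", "pi_dimer"), fixed)
  if (length(free_names) == 0) {
    abort("at least one parameter must be free", class = "sptk_config_error")
  }
  to_theta <- function(p) {
    th <- c(
      p_on = logit(min(max(p$p_on, 1e-6), 1 - 1e-6)),
      p_off = logit(min(max(p$p_off, 1e-6), 1 - 1e-6)),
      sigma_d = log(p$sigma_d),
      pi_dimer = logit(min(max(p$pi_dimer, 1e-6), 1 - 1e-6))
    )
    th[free_names]
  }
  from_theta <- function(th) {
    p <- init
    for (nm in free_names) {
      p[[nm]] <- if (nm == "sigma_d") exp(th[[nm]]) else inv_logit(th[[nm]])
    }
    p
  }
  negll <- function(th) {
    p <- from_theta(th)
    ll <- hmm_forward_batch_cpp(
      d$s, d$gap, d$start, d$len,
      p$p_on, p$p_off, p$sigma_d, p$s_max, p$pi_dimer
    )
    if (!is.finite(ll)) {
      return(1e12)
    }
    -ll
  }

  lower <- setNames(rep(-12, length(free_names)), free_names)
  upper <- setNames(rep(12, length(free_names)), free_names)
  if ("sigma_d" %in% free_names) {
    lower["sigma_d"] <- log(1) # 1 nm
    upper["sigma_d"] <- log(init$s_max)
  }

  starts <- list(to_theta(init))
  if (multi_start) {
    grid <- list(
      list(p_on = 0.02, p_off = 0.005, sigma_d = 25, pi_dimer = 0.5),
      list(p_on = 0.10, p_off = 0.05, sigma_d = 60, pi_dimer = 0.2),
      list(p_on = 0.30, p_off = 0.20, sigma_d = 120, pi_dimer = 0.8),
      list(p_on = 0.01, p_off = 0.10, sigma_d = 40, pi_dimer = 0.05)
    )
    starts <- c(starts, lapply(grid, function(g) {
      p <- init
      for (nm in intersect(names(g), free_names)) p[[nm]] <- g[[nm]]
      to_theta(p)
    }))
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, negll,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    abort("HMM optimization failed from every start", class = "sptk_optim_error")
  }

  params <- from_theta(setNames(best$par, free_names))
  ll <- -best$value
  ll_init <- -negll(to_theta(init))
  if (is.finite(ll_init) && ll < ll_init) { # never return worse than init
    params <- init
    ll <- ll_init
  }
  structure(
    list(
      params = params, log_likelihood = ll,
      n_series = length(d$len), n_obs = length(d$s),
      convergence = best$convergence, fixed = fixed
    ),
    class = "dimer_hmm"
  )
}

#' @export
print.dimer_hmm <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Two-state (free/dimer) HMM fit\n  p_on = %.4g  p_off = %.4g  sigma_d = %.4g nm  pi_dimer = %.4g\n  s_max = %.4g nm (fixed)  loglik = %.2f  (%d series, %d obs)\n",
    p$p_on, p$p_off, p$sigma_d, p$pi_dimer, p$s_max, x$log_likelihood,
    x$n_series, x$n_obs
  ))
  invisible(x)
}

#' @export
tidy.dimer_hmm <- function(x, ...) {
  p <- x$params
  terms <- c("p_on", "p_off", "sigma_d", "pi_dimer", "s_max")
  tibble(
    term = terms,
    estimate = c(p$p_on, p$p_off, p$sigma_d, p$pi_dimer, p$s_max),
    fixed = terms %in% c(x$fixed, "s_max")
  )
}

#' @export
glance.dimer_hmm <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood, n_series = x$n_series,
    n_obs = x$n_obs, convergence = x$convergence
  )
}

#' Segment pair series into free/dimer events (Viterbi)
#'
#' Computes the maximum-a-posteriori state path of every series and merges
#' consecutive same-state frames into events. Missing frames carry no state:
#' an event never spans a frame gap, so durations count contiguously
#' observed frames only.
#'
#' @param pairs Pair-series tibble.
#' @param params Fitted or supplied [hmm_params()].
#' @param frame_rate Frames per second for durations in seconds; defaults to
#'   the `frame_rate` attribute of `pairs`.
#' @param gap_cap Longest bridged frame gap in the state inference.
#'
#' @return A tibble of class `"dimer_events"`: `pair_id`, `start_frame`,
#'   `end_frame`, `state`, `duration_frames`, `duration_s`.
#' @export
viterbi_segment <- function(pairs, params, frame_rate = NULL, gap_cap = 10) {
  validate_hmm_params(params)
  frame_rate <- frame_rate %||% attr(pairs, "frame_rate")
  d <- prepare_series(pairs, gap_cap)
  states <- integer(length(d$s))
  for (k in seq_along(d$len)) {
    ix <- (d$start[k] + 1):(d$start[k] + d$len[k])
    states[ix] <- hmm_viterbi_cpp(
      d$s[ix], d$gap[ix],
      params$p_on, params$p_off, params$sigma_d, params$s_max, params$pi_dimer
    )
  }
  # event boundaries: new series, state change, or any unobserved frame
  gap1 <- d$gap > 1L
  new_series <- c(TRUE, diff(d$series_id) != 0)
  new_event <- new_series | gap1 | c(TRUE, diff(states) != 0)
  ev <- cumsum(new_event)
  out <- tibble(
    pair_id = d$pair_id, frame = d$frame,
    state = c("free", "dimer")[states], event = ev
  ) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      pair_id = .data$pair_id[1],
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      state = .data$state[1],
      duration_frames = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"event") |>
    dplyr::arrange(.data$pair_id, .data$start_frame)
  if (!is.null(frame_rate)) {
    out$duration_s <- out$duration_frames / frame_rate
  }
  structure(out, class = c("dimer_events", class(out)))
}

# truncated-geometric MLE of the per-frame dissociation probability from
# Viterbi dimer dwells: events shorter than min_frames are discarded (they
# are dominated by transient crossings of independent particles), and the
# remaining lengths L satisfy L - min_frames ~ geometric(p_off) thanks to
# memorylessness. Events abutting a series end or an unobserved frame are
# right-censored.
dwell_p_off <- function(events, pairs, min_frames) {
  dimer <- events[events$state == "dimer" & events$duration_frames >= min_frames, ]
  if (nrow(dimer) == 0) {
    return(list(p_off = NA_real_, n_events = 0L, n_complete = 0L))
  }
  observed_next <- logical(nrow(dimer))
  frames_by_pair <- split(pairs$frame, pairs$pair_id)
  for (i in seq_len(nrow(dimer))) {
    observed_next[i] <- (dimer$end_frame[i] + 1L) %in%
      frames_by_pair[[as.character(dimer$pair_id[i])]]
  }
  d <- observed_next # complete iff the dissociation frame itself was seen
  l <- dimer$duration_frames
  list(
    p_off = sum(d) / (sum(d) + sum(l - min_frames) + sum(1 - d)),
    n_events = nrow(dimer), n_complete = sum(d)
  )
}

#' Dissociation rate of the dimer state
#'
#' Estimates `k_off` from segmented pair series. The default `"dwell"`
#' method works on the Viterbi dimer events: series showing no dimer event
#' of at least `min_duration_frames` are dropped and the model refit on the
#' remainder (candidate pairs that merely cross paths contribute spurious
#' short events), then the per-frame dissociation probability is the
#' maximum-likelihood estimate of a left-truncated, right-censored geometric
#' dwell distribution. The `"transition"` method converts the fitted HMM
#' `p_off` directly. Either per-frame probability becomes a continuous-time
#' rate through `k_off = -log(1 - p_off) * frame_rate`, exact for a
#' two-state Markov chain observed at the camera interval. The standard
#' error is a nonparametric bootstrap over pairs.
#'
#' @param pairs Pair-series tibble used for the fit.
#' @param fit A [fit_hmm()] result (or an [hmm_params()]).
#' @param frame_rate Frames per second; defaults to the attribute of
#'   `pairs`.
#' @param method `"dwell"` (default) or `"transition"`.
#' @param min_duration_frames Shortest dimer event trusted by the dwell
#'   method, frames. The default 6 (0.3 s at 20 frames/s) sits well above
#'   the ~1-frame time in which two independent membrane receptors diffuse
#'   across the dimer emission scale.
#' @param n_boot Bootstrap resamples (default 200; 0 skips the bootstrap).
#' @param seed Integer seed for the resampling.
#' @param gap_cap Longest bridged frame gap.
#'
#' @return An object of class `"koff_estimate"`: `k_off` (1/s), `se`,
#'   `mean_lifetime_s`, `p_off`, `n_pairs`, `n_dimer_frames`, `n_events`,
#'   `method`, `log_likelihood`, `frame_rate`. [tidy()]/[glance()] methods
#'   available.
#' @export
estimate_koff <- function(pairs, fit, frame_rate = NULL,
                          method = c("dwell", "transition"),
                          min_duration_frames = 6, n_boot = 200,
                          seed = 1L, gap_cap = 10) {
  method <- match.arg(method)
  params <- if (inherits(fit, "dimer_hmm")) fit$params else fit
  validate_hmm_params(params)
  frame_rate <- frame_rate %||% attr(pairs, "frame_rate")
  if (is.null(frame_rate) || frame_rate <= 0) {
    abort("frame_rate must be supplied and > 0", class = "sptk_config_error")
  }
  if (params$p_off >= 1) {
    abort("p_off = 1 implies an infinite rate at this frame interval",
      class = "sptk_input_error"
    )
  }
  p_to_k <- function(p) -log(1 - p) * frame_rate

  ev <- viterbi_segment(pairs, params, frame_rate = frame_rate, gap_cap = gap_cap)
  n_dimer_frames <- sum(ev$duration_frames[ev$state == "dimer"])

  if (method == "dwell") {
    keep <- unique(ev$pair_id[ev$state == "dimer" &
      ev$duration_frames >= min_duration_frames])
    if (length(keep) == 0) {
      warn("no dimer event reaches min_duration_frames; falling back to the transition method")
      method <- "transition"
    } else {
      sub <- pairs[pairs$pair_id %in% keep, , drop = FALSE]
      attr(sub, "s_max") <- params$s_max
      refit <- tryCatch(
        fit_hmm(sub, init = params, gap_cap = gap_cap, multi_start = FALSE),
        error = function(e) NULL
      )
      params_used <- if (is.null(refit)) params else refit$params
      ev_sub <- viterbi_segment(sub, params_used,
        frame_rate = frame_rate, gap_cap = gap_cap
      )
      mle <- dwell_p_off(ev_sub, sub, min_duration_frames)
      p_off_hat <- mle$p_off
      n_events <- mle$n_events
      kept_pairs <- keep
      # bootstrap over the retained pairs: resample event tables per pair
      se <- NA_real_
      if (n_boot > 0) {
        ev_by_pair <- split(ev_sub, ev_sub$pair_id)
        fr_by_pair <- split(as_tibble(sub), sub$pair_id)
        boots <- withr::with_seed(seed, {
          vapply(seq_len(n_boot), function(b) {
            take <- sample(kept_pairs, length(kept_pairs), replace = TRUE)
            evb <- dplyr::bind_rows(ev_by_pair[as.character(take)], .id = "draw")
            prb <- dplyr::bind_rows(fr_by_pair[as.character(take)], .id = "draw")
            evb$pair_id <- as.integer(evb$draw)
            prb$pair_id <- as.integer(prb$draw)
            p <- dwell_p_off(evb, prb, min_duration_frames)$p_off
            if (is.na(p)) NA_real_ else p_to_k(p)
          }, numeric(1))
        })
        se <- sd(boots, na.rm = TRUE)
      }
      k_off <- p_to_k(p_off_hat)
      return(structure(
        list(
          k_off = k_off, se = se,
          mean_lifetime_s = if (k_off > 0) 1 / k_off else Inf,
          lifetime_infinite = k_off == 0,
          p_off = p_off_hat,
          n_pairs = length(kept_pairs), n_dimer_frames = n_dimer_frames,
          n_events = n_events, method = "dwell",
          min_duration_frames = min_duration_frames,
          log_likelihood = if (inherits(fit, "dimer_hmm")) fit$log_likelihood else NA_real_,
          frame_rate = frame_rate, n_boot = n_boot
        ),
        class = "koff_estimate"
      ))
    }
  }

  # transition method: direct conversion of the fitted per-frame p_off
  k_off <- p_to_k(params$p_off)
  se <- NA_real_
  if (n_boot > 0) {
    ids <- unique(pairs$pair_id)
    split_pairs <- split(as_tibble(pairs), pairs$pair_id)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        res <- dplyr::bind_rows(split_pairs[as.character(take)], .id = "draw")
        res$pair_id <- as.integer(res$draw) # resampled copies are distinct pairs
        refit <- tryCatch(
          fit_hmm(res,
            init = params, fixed = "sigma_d", gap_cap = gap_cap,
            multi_start = FALSE
          ),
          error = function(e) NULL
        )
        if (is.null(refit)) NA_real_ else p_to_k(refit$params$p_off)
      }, numeric(1))
    })
    se <- sd(boots, na.rm = TRUE)
  }

  structure(
    list(
      k_off = k_off, se = se,
      mean_lifetime_s = if (k_off > 0) 1 / k_off else Inf,
      lifetime_infinite = k_off == 0,
      p_off = params$p_off,
      n_pairs = length(unique(pairs$pair_id)),
      n_dimer_frames = n_dimer_frames,
      n_events = sum(ev$state == "dimer"), method = "transition",
      min_duration_frames = NA_integer_,
      log_likelihood = if (inherits(fit, "dimer_hmm")) fit$log_likelihood else NA_real_,
      frame_rate = frame_rate, n_boot = n_boot
    ),
    class = "koff_estimate"
  )
}

#' @export
print.koff_estimate <- function(x, ...) {
  cat(sprintf(
    "Dissociation rate estimate (%s method)\n  k_off = %.4g +/- %.2g 1/s  (mean lifetime %.3g s)\n  %d pairs, %d dimer frames, %d events, %d bootstrap resamples\n",
    x$method, x$k_off, x$se, x$mean_lifetime_s, x$n_pairs, x$n_dimer_frames,
    x$n_events, x$n_boot
  ))
  invisible(x)
}

#' @export
tidy.koff_estimate <- function(x, ...) {
  tibble(
    term = "k_off", estimate = x$k_off, std.error = x$se,
    mean_lifetime_s = x$mean_lifetime_s
  )
}

#' @export
glance.koff_estimate <- function(x, ...) {
  tibble(
    k_off = x$k_off, se = x$se, mean_lifetime_s = x$mean_lifetime_s,
    method = x$method, n_pairs = x$n_pairs,
    n_dimer_frames = x$n_dimer_frames, n_events = x$n_events,
    log_likelihood = x$log_likelihood
  )
}
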