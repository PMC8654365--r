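test_that("emission densities match plug-in values and normalize", {
  p <- hmm_params(sigma_d = 25, s_max = 500)
  # Rayleigh density at its scale: (1/sigma) exp(-1/2)
  expect_equal(
    emission_density(25, "dimer", p), exp(-0.5) / 25,
    tolerance = 1e-12
  )
  # mode of the dimer density sits at sigma_d
  s <- seq(1, 200, by = 0.1)
  expect_equal(s[which.max(emission_density(s, "dimer", p))], 25, tolerance = 1e-2)
  # both densities integrate to 1 on their support
  expect_equal(
    stats::integrate(function(x) emission_density(x, "free", p), 0, 500,
      rel.tol = 1e-12
    )$value, 1,
    tolerance = 1e-9
  )
  expect_equal(
    stats::integrate(function(x) emission_density(x, "dimer", p), 0, Inf)$value, 1,
    tolerance = 1e-7
  )
  expect_equal(emission_density(600, "free", p), 0)
  expect_error(emission_density(10, "bound", p), class = "sptk_input_error")
})

series_tbl <- function(s, frames = seq_along(s) - 1L, pair_id = 1L) {
  tibble::tibble(pair_id = pair_id, frame = as.integer(frames), s_nm = s)
}

test_that("length-1 and frozen-chain likelihoods have closed forms", {
  p <- hmm_params(p_on = 0.1, p_off = 0.05, sigma_d = 30, s_max = 500, pi_dimer = 0.4)
  s1 <- 80
  expect_equal(
    forward_loglik(series_tbl(s1), p),
    log(0.4 * emission_density(s1, "dimer", p) +
      0.6 * emission_density(s1, "free", p))
  )
  frozen <- hmm_params(p_on = 0, p_off = 0, sigma_d = 30, s_max = 500, pi_dimer = 1)
  s <- c(20, 35, 50, 28)
  expect_equal(
    forward_loglik(series_tbl(s), frozen),
    sum(log(emission_density(s, "dimer", frozen)))
  )
})

test_that("forward log-likelihood equals the exhaustive path sum (T <= 8)", {
  for (i in 1:100) {
    p <- random_hmm_params(i)
    withr::with_seed(1000 + i, {
      T_len <- sample(1:8, 1)
      s <- runif(T_len, 5, 490)
      gap <- c(1L, sample(1:4, max(T_len - 1, 0), replace = TRUE))
      frames <- cumsum(gap) - 1L
    })
    got <- forward_loglik(series_tbl(s, frames), p)
    want <- brute_forward(s, gap, p)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Viterbi path equals the exhaustive argmax (T <= 8)", {
  for (i in 1:100) {
    p <- random_hmm_params(200 + i)
    withr::with_seed(3000 + i, {
      T_len <- sample(2:8, 1)
      s <- runif(T_len, 5, 490)
      gap <- c(1L, sample(1:4, T_len - 1, replace = TRUE))
    })
    got <- sptkinetics:::hmm_viterbi_cpp(
      s, gap, p$p_on, p$p_off, p$sigma_d, p$s_max, p$pi_dimer
    )
    expect_equal(got, brute_viterbi(s, gap, p))
  }
})

test_that("likelihood is invariant to reordering independent series", {
  p <- hmm_params()
  a <- series_tbl(c(20, 30, 400, 380), pair_id = 1L)
  b <- series_tbl(c(100, 90, 25, 30, 28), pair_id = 2L)
  expect_equal(
    forward_loglik(dplyr::bind_rows(a, b), p),
    forward_loglik(dplyr::bind_rows(b, dplyr::mutate(a, pair_id = 3L)), p)
  )
})

test_that("emission dominance calls every close frame a dimer", {
  p <- hmm_params(p_on = 0.05, p_off = 0.05, sigma_d = 25, s_max = 500)
  ev <- viterbi_segment(series_tbl(rep(10, 30)), p, frame_rate = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, "dimer")
  expect_equal(ev$duration_frames, 30)
  expect_equal(ev$duration_s, 1.5)
})

test_that("event boundaries land within 2 frames of true block edges", {
  withr::with_seed(11, {
    blocks <- rep(c("free", "dimer"), 4)
    s <- unlist(lapply(blocks, function(b) {
      if (b == "dimer") {
        25 * sqrt(-2 * log(runif(50))) # Rayleigh(25)
      } else {
        sqrt(runif(50)) * 500 # triangular radial on (0, 500]
      }
    }))
  })
  p <- hmm_params(p_on = 0.02, p_off = 0.02, sigma_d = 25, s_max = 500, pi_dimer = 0.5)
  ev <- viterbi_segment(series_tbl(s), p, frame_rate = 20)
  dimer_starts <- ev$start_frame[ev$state == "dimer"]
  true_starts <- c(50, 150, 250, 350)
  for (ts in true_starts) {
    expect_true(any(abs(dimer_starts - ts) <= 2))
  }
})

test_that("gaps use the g-step transition matrix and split events", {
  p <- hmm_params(p_on = 0.1, p_off = 0.08, sigma_d = 25, s_max = 500, pi_dimer = 0.5)
  s <- c(20, 22, 18, 25, 21)
  gapped <- series_tbl(s, frames = c(0L, 1L, 2L, 6L, 7L))
  want <- brute_forward(s, c(1L, 1L, 1L, 4L, 1L), p)
  expect_equal(forward_loglik(gapped, p), want, tolerance = 1e-10)
  ev <- viterbi_segment(gapped, p, frame_rate = 20)
  expect_equal(nrow(ev), 2) # the 3-frame gap splits the dimer event
  expect_equal(sum(ev$duration_frames), 5)
})

test_that("fitting recovers generating parameters and is stationary at its optimum", {
  cfg <- sim_config(n_pairs = 150, n_frames = 600, k_off = 0.3, k_on = 3, seed = 77)
  trks <- suppressMessages(simulate_pair_tracks(cfg))
  pairs <- find_candidate_pairs(
    dplyr::filter(trks, channel == 1), dplyr::filter(trks, channel == 2)
  )
  fit <- fit_hmm(pairs)
  p_off_true <- 1 - exp(-0.3 / 20)
  expect_equal(fit$params$p_off, p_off_true, tolerance = 0.15)
  # observed dimer separations: label offset 20 nm + two 20 nm localizations
  expect_equal(fit$params$sigma_d, sqrt(20^2 + 20^2), tolerance = 0.35)

  refit <- fit_hmm(pairs, init = fit$params, multi_start = FALSE)
  expect_gte(refit$log_likelihood, fit$log_likelihood - 1e-6)
  for (nm in c("p_on", "p_off", "sigma_d", "pi_dimer")) {
    expect_equal(refit$params[[nm]], fit$params[[nm]], tolerance = 0.01)
  }
})

test_that("data with no close approaches drive p_on and pi_dimer to their floors", {
  withr::with_seed(4, {
    s <- runif(400, 420, 499)
  })
  far <- series_tbl(s, pair_id = rep(1:8, each = 50))
  far$frame <- rep(0:49, 8)
  fit <- fit_hmm(far, init = hmm_params(s_max = 500))
  expect_lt(fit$params$p_on, 0.01)
  expect_lt(fit$params$pi_dimer, 0.01)
})

test_that("rate conversion and lifetime follow the closed form", {
  p <- hmm_params(p_off = 0.0089598, s_max = 500)
  pairs <- series_tbl(c(20, 25, 30, 28))
  ko <- estimate_koff(pairs, p, frame_rate = 20, method = "transition", n_boot = 0)
  expect_equal(ko$k_off, 0.18, tolerance = 1e-4)
  expect_equal(ko$mean_lifetime_s, 5.56, tolerance = 1e-3)

  p0 <- hmm_params(p_off = 0, s_max = 500)
  ko0 <- estimate_koff(pairs, p0, frame_rate = 20, method = "transition", n_boot = 0)
  expect_equal(ko0$k_off, 0)
  expect_true(is.infinite(ko0$mean_lifetime_s))
  expect_true(ko0$lifetime_infinite)

  expect_error(
    estimate_koff(pairs, hmm_params(p_off = 1, s_max = 500), frame_rate = 20),
    class = "sptk_input_error"
  )
})

test_that("tidy and glance methods expose the fit as tables", {
  p <- hmm_params()
  pairs <- series_tbl(c(20, 30, 40, 400, 380, 25), pair_id = rep(1:2, each = 3))
  pairs$frame <- rep(0:2, 2)
  fit <- fit_hmm(pairs, init = p, multi_start = FALSE)
  td <- tidy(fit)
  expect_equal(td$term, c("p_on", "p_off", "sigma_d", "pi_dimer", "s_max"))
  expect_true(td$fixed[td$term == "s_max"])
  gl <- glance(fit)
  expect_equal(gl$n_series, 2)
  expect_equal(gl$n_obs, 6)
})
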