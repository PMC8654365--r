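test_that("MSD matches hand-computed values on a collinear walk", {
  tr <- tibble::tibble(frame = 0:2, x_nm = c(0, 1000, 2000), y_nm = 0)
  m <- compute_msd(tr, max_lag = 2, frame_rate = 20)
  expect_equal(m$msd_um2, c(1, 4))
  expect_equal(m$n_jumps, c(2L, 1L))
  expect_equal(m$lag_s, c(0.05, 0.10))

  still <- tibble::tibble(frame = 0:9, x_nm = 500, y_nm = 300)
  expect_true(all(compute_msd(still, max_lag = 5, frame_rate = 20)$msd_um2 == 0))
})

test_that("MSD equals the brute-force double loop, including gapped tracks", {
  for (seed in 1:5) {
    tr <- random_track(10, seed)
    tr <- tr[-sample(2:9, 2), ] # knock out two interior frames
    m <- compute_msd(tr, max_lag = 6, frame_rate = 20)
    o <- brute_msd(tr$frame, tr$x_nm, tr$y_nm, max_lag = 6, frame_rate = 20)
    expect_equal(m$msd_um2, o$msd_um2)
    expect_equal(m$n_jumps, o$n_jumps)
    expect_equal(m$lag_s, o$lag_s)
  }
})

test_that("MSD is invariant under translation and rotation", {
  tr <- random_track(20, seed = 2)
  m0 <- compute_msd(tr, max_lag = 5, frame_rate = 20)
  th <- 0.7
  rot <- tr
  rot$x_nm <- cos(th) * tr$x_nm - sin(th) * tr$y_nm + 5000
  rot$y_nm <- sin(th) * tr$x_nm + cos(th) * tr$y_nm - 2000
  m1 <- compute_msd(rot, max_lag = 5, frame_rate = 20)
  expect_equal(m0$msd_um2, m1$msd_um2)
})

test_that("ensemble MSD pools jumps, not tracks", {
  tr <- random_track(15, seed = 3)
  both <- dplyr::bind_rows(
    dplyr::mutate(tr, particle_id = 1L),
    dplyr::mutate(tr, particle_id = 2L)
  )
  single <- compute_msd(tr, max_lag = 4, frame_rate = 20)
  ens <- ensemble_msd(both, max_lag = 4, frame_rate = 20)
  expect_equal(ens$msd_um2, single$msd_um2)
  expect_equal(ens$n_jumps, 2L * single$n_jumps)

  # jump-weighted pooling equals the mean over the concatenated jump list
  t2 <- random_track(7, seed = 4)
  uneven <- dplyr::bind_rows(
    dplyr::mutate(tr, particle_id = 1L),
    dplyr::mutate(t2, particle_id = 2L)
  )
  ens2 <- ensemble_msd(uneven, max_lag = 3, frame_rate = 20)
  o1 <- brute_msd(tr$frame, tr$x_nm, tr$y_nm, 3, 20)
  o2 <- brute_msd(t2$frame, t2$x_nm, t2$y_nm, 3, 20)
  pooled <- (o1$msd_um2 * o1$n_jumps + o2$msd_um2 * o2$n_jumps) /
    (o1$n_jumps + o2$n_jumps)
  expect_equal(ens2$msd_um2, pooled)
})

test_that("diffusion fit recovers exact lines and flags degenerate slopes", {
  lags <- (1:5) / 20
  exact <- tibble::tibble(lag_s = lags, msd_um2 = 4 * 0.1 * lags, n_jumps = 100L)
  fit <- fit_diffusion(exact)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$ci95_hi - fit$ci95_lo, 0, tolerance = 1e-9)

  noisefloor <- tibble::tibble(lag_s = lags, msd_um2 = 4 * 0.02^2, n_jumps = 100L)
  expect_warning(fit0 <- fit_diffusion(noisefloor), "not positive")
  expect_equal(fit0$D, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 4 * 0.02^2)
  expect_true(fit0$nonpositive_D)

  expect_error(fit_diffusion(exact[1:3, ]), class = "sptk_insufficient_data_error")
  expect_error(compute_msd(exact[1, ], 5, 20), class = "sptk_empty_track_error")
})

test_that("noise-free Brownian simulation yields an unbiased D estimate", {
  errs <- vapply(1:25, function(s) {
    cfg <- sim_config(
      n_pairs = 15, n_frames = 150, k_on = 0, p_dimer_init = 0,
      D_free_ch1 = 0.1, D_free_ch2 = 0.1, sigma_loc_ch1 = 0, sigma_loc_ch2 = 0,
      roi_size = 2e5, seed = s
    )
    trks <- simulate_pair_tracks(cfg)
    fit_diffusion(ensemble_msd(trks, max_lag = 6))$D / 0.1 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("localization noise moves the intercept, not the slope", {
  cfg <- sim_config(
    n_pairs = 60, n_frames = 300, k_on = 0, p_dimer_init = 0,
    D_free_ch1 = 0.08, D_free_ch2 = 0.08, sigma_loc_ch1 = 0, sigma_loc_ch2 = 0,
    roi_size = 4e5, seed = 31
  )
  trks <- simulate_pair_tracks(cfg)
  clean <- fit_diffusion(ensemble_msd(trks, max_lag = 6))
  noisy_tr <- trks
  sigma <- 30
  noise <- withr::with_seed(5, rnorm(2 * nrow(trks), 0, sigma))
  noisy_tr$x_nm <- trks$x_nm + noise[seq_len(nrow(trks))]
  noisy_tr$y_nm <- trks$y_nm + noise[nrow(trks) + seq_len(nrow(trks))]
  noisy <- fit_diffusion(ensemble_msd(noisy_tr, max_lag = 6))
  expect_equal(noisy$D, clean$D, tolerance = 0.02)
  expect_equal(noisy$intercept - clean$intercept, 4 * (sigma / 1000)^2,
    tolerance = 0.2
  )
})

test_that("per-cell estimates separate distinct mobilities", {
  make_cells <- function(D, n_cells, seed0) {
    purrr::map(seq_len(n_cells), function(i) {
      cfg <- sim_config(
        n_pairs = 6, n_frames = 120, k_on = 0, p_dimer_init = 0,
        D_free_ch1 = D, D_free_ch2 = D, sigma_loc_ch1 = 10, sigma_loc_ch2 = 10,
        roi_size = 2e5, seed = seed0 + i
      )
      dplyr::mutate(as.data.frame(simulate_pair_tracks(cfg)),
        cell = paste0("c", D, "_", i),
        particle_id = .data$particle_id + 1000L * i
      )
    }) |> dplyr::bind_rows()
  }
  slow <- make_cells(0.05, 12, 100)
  fast <- make_cells(0.10, 12, 200)
  d_slow <- per_cell_D(slow, frame_rate = 20, max_lag = 6)
  d_fast <- per_cell_D(fast, frame_rate = 20, max_lag = 6)
  expect_equal(nrow(d_slow), 12)

  # identical data per cell give identical estimates
  same <- per_cell_D(
    dplyr::bind_rows(
      dplyr::mutate(slow[slow$cell == "c0.05_1", ], cell = "a"),
      dplyr::mutate(slow[slow$cell == "c0.05_1", ], cell = "b")
    ),
    frame_rate = 20, max_lag = 6
  )
  expect_equal(same$D[1], same$D[2])

  cmp <- compare_mobility(d_slow$D, d_fast$D)
  expect_lt(cmp$p.value, 0.001)
})

test_that("mobility comparison handles ties and matches a permutation oracle", {
  expect_warning(tied <- compare_mobility(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(tied$p.value, 1)

  withr::with_seed(3, {
    a <- round(rlnorm(10, log(0.05), 0.4), 4)
    b <- round(rlnorm(10, log(0.08), 0.4), 4)
  })
  got <- compare_mobility(a, b)$p.value
  # permutation distribution of the rank-sum statistic
  pooled <- c(a, b)
  obs <- sum(rank(pooled)[seq_along(a)])
  perm <- withr::with_seed(1, vapply(1:20000, function(i) {
    sum(rank(pooled)[sample(20, 10)])
  }, numeric(1)))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_equal(got, p_perm, tolerance = 0.15)
})
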