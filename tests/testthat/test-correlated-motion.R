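test_that("pair search returns nothing for distant particles and one series for coincident ones", {
  t1 <- dplyr::mutate(random_track(20, 1), particle_id = 1L)
  t2 <- dplyr::mutate(t1, particle_id = 2L, x_nm = x_nm + 5000)
  expect_equal(nrow(find_candidate_pairs(t1, t2, s_max = 500)), 0)

  t3 <- dplyr::mutate(t1, particle_id = 2L, x_nm = x_nm + 10)
  pr <- find_candidate_pairs(t1, t3, s_max = 500)
  expect_equal(length(unique(pr$pair_id)), 1)
  expect_equal(pr$frame, t1$frame)
})

test_that("pair search equals the brute-force all-pairs scan", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      t1 <- purrr::map(1:10, function(i) {
        n <- sample(10:25, 1)
        dplyr::mutate(random_track(n, seed * 100 + i, frame0 = sample(0:5, 1), box = 1500),
          particle_id = i
        )
      }) |> dplyr::bind_rows()
      t2 <- purrr::map(1:10, function(i) {
        n <- sample(10:25, 1)
        dplyr::mutate(random_track(n, seed * 200 + i, frame0 = sample(0:5, 1), box = 1500),
          particle_id = 100L + i
        )
      }) |> dplyr::bind_rows()
    })
    got <- find_candidate_pairs(t1, t2, s_max = 400, min_frames = 3)
    want <- brute_pairs(t1, t2, s_max = 400, min_frames = 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got_o <- dplyr::arrange(got, id1, id2, frame)
      want_o <- dplyr::arrange(want, id1, id2, frame)
      expect_equal(got_o$id1, want_o$id1)
      expect_equal(got_o$id2, want_o$id2)
      expect_equal(got_o$frame, want_o$frame)
      expect_equal(got_o$s_nm, want_o$s_nm)
    }
  }
})

test_that("rigid pairs have exactly zero uncorrelated jump", {
  base <- random_track(30, 9)
  t1 <- dplyr::mutate(base, particle_id = 1L)
  t2 <- dplyr::mutate(base, particle_id = 2L, x_nm = x_nm + 40) # rigid offset
  pr <- find_candidate_pairs(t1, t2, s_max = 500)
  st <- correlated_jump_stats(pr, bin_edges = c(0, 250, 500))
  expect_equal(st$mean_uncorr_jump_nm[st$n_jumps > 0], 0)
  expect_true(all(st$n_jumps[is.na(st$mean_jump_nm)] == 0))
})

test_that("independent particles match the closed-form uncorrelated jump", {
  cfg <- sim_config(
    n_pairs = 210, n_frames = 500, k_on = 0, p_dimer_init = 0,
    D_free_ch1 = 0.1, D_free_ch2 = 0.1, sigma_loc_ch1 = 0, sigma_loc_ch2 = 0,
    roi_size = 1e6, seed = 14
  )
  trks <- simulate_pair_tracks(cfg)
  pr <- pair_series_from_tracks(trks)
  st <- correlated_jump_stats(pr, bin_edges = c(0, Inf))
  expect_gt(st$n_jumps, 1e5)
  # E|dr1 - dr2|^2 = 4 (D1 + D2) dt, in nm^2
  expect_equal(st$mean_sq_uncorr_jump_nm2, 4 * 0.2 * 1e6 * 0.05, tolerance = 0.03)

  # independence: E|dr1 - dr2|^2 = E|dr1|^2 + E|dr2|^2
  jumps <- sptkinetics:::pair_jumps(pr)
  expect_equal(
    mean(jumps$uncorr_jump_nm^2),
    mean(jumps$jump1_nm^2) + mean(jumps$jump2_nm^2),
    tolerance = 0.02
  )
})

test_that("equal localization noise on both channels adds 4 (s1^2 + s2^2)", {
  cfg <- sim_config(
    n_pairs = 210, n_frames = 300, k_on = 0, p_dimer_init = 0,
    D_free_ch1 = 0.05, D_free_ch2 = 0.05, sigma_loc_ch1 = 0, sigma_loc_ch2 = 0,
    roi_size = 1e6, seed = 15
  )
  trks <- simulate_pair_tracks(cfg)
  st0 <- correlated_jump_stats(pair_series_from_tracks(trks), bin_edges = c(0, Inf))
  sigma <- 25
  noisy <- trks
  noise <- withr::with_seed(6, rnorm(2 * nrow(trks), 0, sigma))
  noisy$x_nm <- trks$x_nm + noise[seq_len(nrow(trks))]
  noisy$y_nm <- trks$y_nm + noise[nrow(trks) + seq_len(nrow(trks))]
  st1 <- correlated_jump_stats(pair_series_from_tracks(noisy), bin_edges = c(0, Inf))
  expect_equal(
    st1$mean_sq_uncorr_jump_nm2 - st0$mean_sq_uncorr_jump_nm2,
    4 * (sigma^2 + sigma^2),
    tolerance = 0.05
  )
})

test_that("statistics are invariant to swapping channel labels", {
  cfg <- sim_config(n_pairs = 20, n_frames = 200, seed = 40)
  trks <- simulate_pair_tracks(cfg)
  ch1 <- dplyr::filter(trks, channel == 1)
  ch2 <- dplyr::filter(trks, channel == 2)
  a <- correlated_jump_stats(find_candidate_pairs(ch1, ch2))
  b <- correlated_jump_stats(find_candidate_pairs(ch2, ch1))
  expect_equal(a$mean_uncorr_jump_nm, b$mean_uncorr_jump_nm)
  expect_equal(a$mean_jump_nm, b$mean_jump_nm)
  expect_equal(a$n_jumps, b$n_jumps)
})

test_that("dimerizing pairs show reduced uncorrelated jumps at small separation", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_pairs = 40, n_frames = 400, k_off = 0.18, seed = s)
    trks <- suppressMessages(simulate_pair_tracks(cfg))
    pr <- find_candidate_pairs(
      dplyr::filter(trks, channel == 1), dplyr::filter(trks, channel == 2)
    )
    st <- correlated_jump_stats(pr)
    filled <- st[st$n_jumps > 0, ]
    filled$mean_uncorr_jump_nm[1] < filled$mean_uncorr_jump_nm[nrow(filled)]
  }, logical(1))
  expect_true(all(hits))
})
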