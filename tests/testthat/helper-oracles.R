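# Independent brute-force oracles used to cross-check the implementation.
# These stay deliberately naive: double loops and exhaustive enumeration.

# time-averaged MSD by a double loop over all index pairs
brute_msd <- function(frames, x_nm, y_nm, max_lag, frame_rate) {
  res <- list()
  for (n in seq_len(max_lag)) {
    sq <- c()
    for (i in seq_along(frames)) {
      for (j in seq_along(frames)) {
        if (frames[j] - frames[i] == n) {
          sq <- c(sq, ((x_nm[j] - x_nm[i])^2 + (y_nm[j] - y_nm[i])^2) / 1e6)
        }
      }
    }
    if (length(sq)) {
      res[[length(res) + 1]] <- data.frame(
        lag_frames = n, lag_s = n / frame_rate,
        msd_um2 = mean(sq), n_jumps = length(sq)
      )
    }
  }
  do.call(rbind, res)
}

brute_trans_power <- function(p_on, p_off, g) {
  T1 <- matrix(c(1 - p_on, p_on, p_off, 1 - p_off), 2, 2, byrow = TRUE)
  out <- diag(2)
  for (i in seq_len(g)) out <- out %*% T1
  out
}

# exhaustive sum over all 2^T hidden paths
brute_forward <- function(s, gap, params) {
  T_len <- length(s)
  states <- expand.grid(rep(list(1:2), T_len)) # 1 free, 2 dimer
  init <- c(1 - params$pi_dimer, params$pi_dimer)
  emit <- function(si, st) {
    emission_density(si, c("free", "dimer")[st], params)
  }
  total <- 0
  for (r in seq_len(nrow(states))) {
    path <- as.integer(states[r, ])
    p <- init[path[1]] * emit(s[1], path[1])
    for (t in seq_len(T_len)[-1]) {
      Tg <- brute_trans_power(params$p_on, params$p_off, gap[t])
      p <- p * Tg[path[t - 1], path[t]] * emit(s[t], path[t])
    }
    total <- total + p
  }
  log(total)
}

# exhaustive most-probable path
brute_viterbi <- function(s, gap, params) {
  T_len <- length(s)
  states <- expand.grid(rep(list(1:2), T_len))
  init <- c(1 - params$pi_dimer, params$pi_dimer)
  emit <- function(si, st) emission_density(si, c("free", "dimer")[st], params)
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(states))) {
    path <- as.integer(states[r, ])
    lp <- log(init[path[1]]) + log(emit(s[1], path[1]))
    for (t in seq_len(T_len)[-1]) {
      Tg <- brute_trans_power(params$p_on, params$p_off, gap[t])
      lp <- lp + log(Tg[path[t - 1], path[t]]) + log(emit(s[t], path[t]))
    }
    if (lp > best) {
      best <- lp
      best_path <- path
    }
  }
  best_path
}

# all-pairs candidate scan mirroring the definition, one pair at a time
brute_pairs <- function(tracks_ch1, tracks_ch2, s_max, min_frames, gap_max = 3) {
  out <- list()
  for (i in unique(tracks_ch1$particle_id)) {
    a <- tracks_ch1[tracks_ch1$particle_id == i, ]
    for (j in unique(tracks_ch2$particle_id)) {
      b <- tracks_ch2[tracks_ch2$particle_id == j, ]
      common <- intersect(a$frame, b$frame)
      if (!length(common)) next
      common <- sort(common)
      ax <- a[match(common, a$frame), ]
      bx <- b[match(common, b$frame), ]
      s <- sqrt((ax$x_nm - bx$x_nm)^2 + (ax$y_nm - bx$y_nm)^2)
      keep <- s < s_max
      if (!any(keep)) next
      kf <- common[keep]
      ks <- s[keep]
      run <- cumsum(c(TRUE, diff(kf) > gap_max + 1))
      for (rr in unique(run)) {
        sel <- run == rr
        if (sum(sel) >= min_frames) {
          out[[length(out) + 1]] <- data.frame(
            id1 = i, id2 = j, frame = kf[sel], s_nm = ks[sel]
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

# O(n1 n2) weighted cross-pair count in plain R
brute_crosscount <- function(p1, p2, w, r_grid, correct = TRUE) {
  out <- numeric(length(r_grid))
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(nrow(p2))) {
      dx <- p1$x_nm[i] - p2$x_nm[j]
      dy <- p1$y_nm[i] - p2$y_nm[j]
      d <- sqrt(dx^2 + dy^2)
      e <- if (correct) (w[1] * w[2]) / ((w[1] - abs(dx)) * (w[2] - abs(dy))) else 1
      out <- out + e * (d <= r_grid)
    }
  }
  out
}

# small random walk track for oracle comparisons
random_track <- function(n, seed, frame0 = 0L, box = 2000, step = 60) {
  withr::with_seed(seed, {
    data.frame(
      frame = frame0 + 0:(n - 1),
      x_nm = cumsum(rnorm(n, 0, step)) + runif(1, 0, box),
      y_nm = cumsum(rnorm(n, 0, step)) + runif(1, 0, box)
    )
  })
}

random_hmm_params <- function(seed) {
  withr::with_seed(seed, hmm_params(
    p_on = runif(1, 0.01, 0.4), p_off = runif(1, 0.01, 0.4),
    sigma_d = runif(1, 15, 60), s_max = 500,
    pi_dimer = runif(1, 0.05, 0.95)
  ))
}
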