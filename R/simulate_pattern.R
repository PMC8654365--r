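#' Settings for two-species point-pattern simulation
#'
#' Describes the synthetic immunogold membrane-sheet patterns: complete
#' spatial randomness (`"csr"`), independent single-species clustering
#' (`"clustered"`, one Thomas process per species), or co-clustering
#' (`"coclustered"`, both species' offspring scattered around one shared
#' parent set).
#'
#' @param kind One of `"csr"`, `"clustered"`, `"coclustered"`.
#' @param window_nm Length-2 numeric, rectangle width and height in nm.
#' @param n1,n2 Target point counts per species (exact for `"csr"`; expected
#'   counts are matched by thinning/replication for the cluster processes).
#' @param parent_intensity Cluster parents per um^2.
#' @param offspring_mean Mean offspring per parent per species (Poisson).
#' @param cluster_sigma Isotropic Gaussian scatter of offspring about their
#'   parent, nm.
#' @param seed Integer seed.
#'
#' @return A list of class `"pattern_config"`.
#' @export
pattern_config <- function(kind = c("csr", "clustered", "coclustered"),
                           window_nm = c(1000, 1000),
                           n1 = 300, n2 = 300,
                           parent_intensity = 20,
                           offspring_mean = 5,
                           cluster_sigma = 20,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (length(window_nm) != 2 || any(!is.finite(window_nm)) || any(window_nm <= 0)) {
    abort("window_nm must be two positive finite numbers", class = "sptk_config_error")
  }
  if (n1 < 0 || n2 < 0) abort("n1, n2 must be >= 0", class = "sptk_config_error")
  if (kind != "csr" && cluster_sigma <= 0) {
    abort("cluster_sigma must be > 0 for clustered kinds", class = "sptk_config_error")
  }
  structure(
    list(
      kind = kind, window_nm = window_nm, n1 = n1, n2 = n2,
      parent_intensity = parent_intensity, offspring_mean = offspring_mean,
      cluster_sigma = cluster_sigma, seed = as.integer(seed)
    ),
    class = "pattern_config"
  )
}

# parents of a homogeneous Poisson process at `intensity` per um^2
draw_parents <- function(window_nm, intensity) {
  area_um2 <- prod(window_nm) / 1e6
  n <- rpois(1, intensity * area_um2)
  tibble(x_nm = runif(n, 0, window_nm[1]), y_nm = runif(n, 0, window_nm[2]))
}

# Thomas offspring around given parents, clipped to the window
draw_offspring <- function(parents, offspring_mean, cluster_sigma, window_nm) {
  if (nrow(parents) == 0) {
    return(tibble(x_nm = numeric(0), y_nm = numeric(0)))
  }
  counts <- rpois(nrow(parents), offspring_mean)
  x <- rep(parents$x_nm, counts) + rnorm(sum(counts), 0, cluster_sigma)
  y <- rep(parents$y_nm, counts) + rnorm(sum(counts), 0, cluster_sigma)
  keep <- x >= 0 & x <= window_nm[1] & y >= 0 & y <= window_nm[2]
  tibble(x_nm = x[keep], y_nm = y[keep])
}

#' Simulate a two-species spatial point pattern
#'
#' Generates species-1 and species-2 point coordinates in a rectangular
#' window under one of three spatial structures (see [pattern_config()]).
#' Realized counts appear in the output; for the cluster processes the
#' targets `n1`/`n2` are matched exactly by random thinning (or by adding
#' parents when the first draw falls short).
#'
#' @param config A [pattern_config()].
#'
#' @return A tibble of class `"point_pattern"` with columns `species`
#'   (1 or 2), `x_nm`, `y_nm`; attribute `window_nm` carries the window.
#' @export
#' @examples
#' pp <- simulate_point_pattern(pattern_config("coclustered", seed = 7))
#' dplyr::count(pp, species)
simulate_point_pattern <- function(config) {
  if (!inherits(config, "pattern_config")) {
    abort("config must be a pattern_config()", class = "sptk_config_error")
  }
  withr::local_seed(config$seed)
  w <- config$window_nm

  thin_to <- function(pts, n_target) {
    if (nrow(pts) > n_target) pts[sample.int(nrow(pts), n_target), ] else pts
  }

  if (config$kind == "csr") {
    s1 <- tibble(x_nm = runif(config$n1, 0, w[1]), y_nm = runif(config$n1, 0, w[2]))
    s2 <- tibble(x_nm = runif(config$n2, 0, w[1]), y_nm = runif(config$n2, 0, w[2]))
  } else if (config$kind == "coclustered") {
    # one parent set drives both species; top-up parents stay shared so that
    # exact-count matching does not dilute the co-clustering
    parents <- draw_parents(w, config$parent_intensity)
    s1 <- draw_offspring(parents, config$offspring_mean, config$cluster_sigma, w)
    s2 <- draw_offspring(parents, config$offspring_mean, config$cluster_sigma, w)
    while (nrow(s1) < config$n1 || nrow(s2) < config$n2) {
      extra <- draw_parents(w, config$parent_intensity)
      s1 <- dplyr::bind_rows(s1, draw_offspring(extra, config$offspring_mean, config$cluster_sigma, w))
      s2 <- dplyr::bind_rows(s2, draw_offspring(extra, config$offspring_mean, config$cluster_sigma, w))
    }
    s1 <- thin_to(s1, config$n1)
    s2 <- thin_to(s2, config$n2)
  } else {
    draw_one <- function(n_target) {
      pts <- draw_offspring(
        draw_parents(w, config$parent_intensity),
        config$offspring_mean, config$cluster_sigma, w
      )
      while (nrow(pts) < n_target) {
        pts <- dplyr::bind_rows(pts, draw_offspring(
          draw_parents(w, config$parent_intensity),
          config$offspring_mean, config$cluster_sigma, w
        ))
      }
      thin_to(pts, n_target)
    }
    s1 <- draw_one(config$n1)
    s2 <- draw_one(config$n2)
  }

  out <- dplyr::bind_rows(
    dplyr::mutate(s1, species = 1L, .before = 1),
    dplyr::mutate(s2, species = 2L, .before = 1)
  )
  new_point_pattern(out, window_nm = w)
}

new_point_pattern <- function(df, window_nm) {
  out <- as_tibble(df)
  attr(out, "window_nm") <- as.numeric(window_nm)
  class(out) <- c("point_pattern", class(out))
  out
}

#' Observation window of a point pattern
#' @param pattern A point pattern tibble.
#' @return Length-2 numeric (width, height) in nm.
#' @export
window_of <- function(pattern) {
  w <- attr(pattern, "window_nm")
  if (is.null(w)) abort("pattern carries no window_nm attribute", class = "sptk_config_error")
  w
}
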