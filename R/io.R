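#' Read and write the pipeline's CSV schemas
#'
#' Plain CSV is the interchange format of the pipeline. Headers are fixed:
#' trajectories `frame,particle_id,channel,x_nm,y_nm`; pair series
#' `pair_id,frame,s_nm`; point patterns `species,x_nm,y_nm`. Metadata
#' (frame rate, window) travels in a YAML sidecar written next to each file
#' (same path with extension `.meta.yaml`). Writing then reading a table is
#' the identity on values; malformed input is rejected with the offending
#' line number.
#'
#' @param tracks,pairs,pattern Table to write.
#' @param path File path.
#' @name sptk_io
NULL

meta_path <- function(path) sub("\\.csv$", ".meta.yaml", path)

# CSV writer that preserves doubles exactly (17 significant digits survive
# an as.numeric round trip bit-for-bit)
write_csv_exact <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_meta <- function(path, meta) {
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta)) yaml::write_yaml(meta, meta_path(path))
  invisible(path)
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (file.exists(mp)) yaml::read_yaml(mp) else list()
}

check_header <- function(path, expected) {
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(hdr, expected)) {
    abort(sprintf(
      "'%s': expected header '%s', found '%s'",
      path, paste(expected, collapse = ","), paste(hdr, collapse = ",")
    ), class = "sptk_io_error")
  }
}

check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      abort(sprintf(
        "'%s': non-numeric value in column '%s' at line %d",
        path, cl, bad[1] + 1L # header is line 1
      ), class = "sptk_io_error")
    }
    if (anyNA(v)) {
      abort(sprintf(
        "'%s': missing value in column '%s' at line %d",
        path, cl, which(is.na(v))[1] + 1L
      ), class = "sptk_io_error")
    }
    df[[cl]] <- v
  }
  df
}

#' @rdname sptk_io
#' @export
write_trajectories <- function(tracks, path) {
  write_csv_exact(
    as.data.frame(tracks)[, c("frame", "particle_id", "channel", "x_nm", "y_nm")],
    path
  )
  write_meta(path, list(
    frame_rate = attr(tracks, "frame_rate"),
    roi_size = attr(tracks, "roi_size")
  ))
  gt <- attr(tracks, "ground_truth")
  if (!is.null(gt)) {
    write_csv_exact(gt, sub("\\.csv$", ".truth.csv", path))
  }
  invisible(path)
}

#' @rdname sptk_io
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file '%s' does not exist", path), class = "sptk_io_error")
  }
  check_header(path, c("frame", "particle_id", "channel", "x_nm", "y_nm"))
  df <- utils::read.csv(path, colClasses = "character")
  df <- check_numeric(df, c("frame", "particle_id", "channel", "x_nm", "y_nm"), path)
  df$frame <- as.integer(df$frame)
  df$particle_id <- as.integer(df$particle_id)
  df$channel <- as.integer(df$channel)
  dup <- which(duplicated(df[, c("particle_id", "frame")]))
  if (length(dup)) {
    abort(sprintf(
      "'%s': duplicated (particle_id, frame) at line %d", path, dup[1] + 1L
    ), class = "sptk_io_error")
  }
  if (nrow(df)) {
    chan <- unique(df[, c("particle_id", "channel")])
    if (anyDuplicated(chan$particle_id)) {
      abort(sprintf("'%s': a particle_id maps to more than one channel", path),
        class = "sptk_io_error"
      )
    }
  }
  meta <- read_meta(path)
  new_trajectory_table(df,
    frame_rate = meta$frame_rate,
    roi_size = meta$roi_size %||% NA_real_
  )
}

#' @rdname sptk_io
#' @export
write_pair_series <- function(pairs, path) {
  write_csv_exact(as.data.frame(pairs)[, c("pair_id", "frame", "s_nm")], path)
  write_meta(path, list(
    frame_rate = attr(pairs, "frame_rate"),
    s_max = attr(pairs, "s_max")
  ))
  invisible(path)
}

#' @rdname sptk_io
#' @export
read_pair_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file '%s' does not exist", path), class = "sptk_io_error")
  }
  check_header(path, c("pair_id", "frame", "s_nm"))
  df <- utils::read.csv(path, colClasses = "character")
  df <- check_numeric(df, c("pair_id", "frame", "s_nm"), path)
  df$pair_id <- as.integer(df$pair_id)
  df$frame <- as.integer(df$frame)
  meta <- read_meta(path)
  out <- as_tibble(df)
  structure(out,
    class = c("pair_series", class(out)),
    frame_rate = meta$frame_rate, s_max = meta$s_max
  )
}

#' @rdname sptk_io
#' @export
write_point_pattern <- function(pattern, path) {
  write_csv_exact(as.data.frame(pattern)[, c("species", "x_nm", "y_nm")], path)
  write_meta(path, list(window_nm = as.numeric(window_of(pattern))))
  invisible(path)
}

#' @rdname sptk_io
#' @export
read_point_pattern <- function(path, window_nm = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("input file '%s' does not exist", path), class = "sptk_io_error")
  }
  check_header(path, c("species", "x_nm", "y_nm"))
  df <- utils::read.csv(path, colClasses = "character")
  df <- check_numeric(df, c("species", "x_nm", "y_nm"), path)
  df$species <- as.integer(df$species)
  meta <- read_meta(path)
  w <- window_nm %||% meta$window_nm
  if (is.null(w)) {
    w <- c(max(df$x_nm, 0), max(df$y_nm, 0))
    warn("no window recorded; using the bounding box of the data")
  }
  new_point_pattern(df, window_nm = w)
}
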