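#' Takens delay embedding of a time series
#'
#' Maps a scalar series x(t) to the point cloud of delayed coordinate
#' vectors (x(t), x(t - tau), ..., x(t - (p-1) tau)), one point per
#' admissible t in increasing order.  The geometry of this cloud encodes
#' the dynamics of the series; its Vietoris-Rips persistence is the
#' second feature channel of the pipeline.  The pipeline default
#' (p, tau) = (120, 1) makes each point a 30-second snapshot of a 4 Hz
#' series.
#'
#' @param x numeric vector.
#' @param p embedding dimension (>= 1).
#' @param tau lag in samples (>= 1).
#' @return A numeric matrix with `length(x) - (p - 1) * tau` rows and
#'   `p` columns; row t is the window ending at sample t.
#' @examples
#' takens_embedding(1:5, p = 3, tau = 1)
#' @export
takens_embedding <- function(x, p = 120L, tau = 1L) {
  x <- as.numeric(x)
  p <- as.integer(p); tau <- as.integer(tau)
  if (p < 1L || tau < 1L) abort("`p` and `tau` must be positive integers")
  need <- (p - 1L) * tau + 1L
  if (length(x) < need) {
    abort(sprintf(
      "series of length %d too short for takens_embedding(p = %d, tau = %d); at least %d samples needed",
      length(x), p, tau, need
    ))
  }
  ts <- seq.int(need, length(x))
  out <- vapply(0:(p - 1L), function(k) x[ts - k * tau], numeric(length(ts)))
  matrix(out, nrow = length(ts), ncol = p)
}

#' Write a point cloud as CSV
#'
#' One row per point, columns `x1..xp`; an inspection/debug format for
#' embedded clouds.
#'
#' @param cloud numeric matrix (points in rows).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(cloud, path) {
  cloud <- as.matrix(cloud)
  df <- as_tibble(cloud, .name_repair = ~ paste0("x", seq_along(.x)))
  readr::write_csv(df, path)
  invisible(path)
}
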