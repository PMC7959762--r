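feature_names <- function() {
  as.vector(vapply(c("sl0", "vr0", "vr1"),
                   function(b) paste(b, ps_stat_names(), sep = "_"),
                   character(16)))
}

#' Topological feature vector of one heart-rate window
#'
#' The full feature-extraction scheme for a single median-centered IHR
#' window: the window's sub-level set persistence (dim 0), and the
#' Vietoris-Rips persistence (dims 0 and 1) of its Takens embedding with
#' dimension `p` and lag `tau`, each diagram summarized by its 16
#' persistence statistics.  The result is the 48-vector
#' (sub-level P0, Rips P0, Rips P1), blocks prefixed `sl0_`, `vr0_`,
#' `vr1_`.
#'
#' @param window numeric vector, one IHR window (default pipeline:
#'   length 360 = 90 s at 4 Hz).
#' @param p,tau Takens embedding dimension and lag; (120, 1) makes each
#'   embedded point a 30-s snapshot at 4 Hz.
#' @param max_scale optional Rips scale cap (passed to [vr_diagrams()]).
#' @return Named numeric vector of length 48.
#' @examples
#' w <- sin(seq(0, 8 * pi, length.out = 360)) * 5
#' head(epoch_features(w), 8)
#' @export
epoch_features <- function(window, p = 120L, tau = 1L, max_scale = Inf) {
  window <- as.numeric(window)
  need <- (p - 1L) * tau + 1L
  if (length(window) < need) {
    abort(sprintf(
      "window of length %d is shorter than the %d samples needed for the (p = %d, tau = %d) embedding",
      length(window), need, p, tau
    ))
  }
  sl <- sublevel_diagram(window)
  cloud <- takens_embedding(window, p = p, tau = tau)
  vr <- vr_diagrams(cloud, max_dim = 1L, max_scale = max_scale)
  out <- c(
    persistence_statistics(sl),
    persistence_statistics(vr[vr$dimension == 0L, ]),
    persistence_statistics(vr[vr$dimension == 1L, ])
  )
  stats::setNames(out, feature_names())
}

#' Feature table for a set of labeled windows
#'
#' Maps [epoch_features()] over a window table (as produced by
#' [extract_windows()]), returning one row per epoch with the window
#' metadata and the 48 feature columns — the input the classifier
#' trains on.
#'
#' @param windows tibble with columns `subject_id`, `epoch`, `label` and
#'   a `values` list-column of numeric windows.
#' @param p,tau,max_scale passed to [epoch_features()].
#' @return Tibble: `subject_id`, `epoch`, `label`, then the 48 features.
#' @export
compute_features <- function(windows, p = 120L, tau = 1L, max_scale = Inf) {
  stopifnot(all(c("subject_id", "epoch", "label", "values") %in% names(windows)))
  feats <- purrr::map(windows$values, epoch_features,
                      p = p, tau = tau, max_scale = max_scale)
  dplyr::bind_cols(
    windows[c("subject_id", "epoch", "label")],
    as_tibble(do.call(rbind, feats))
  )
}

#' Read / write a feature table as CSV
#'
#' One row per epoch: `subject_id`, `epoch`, `label`, 48 named feature
#' columns.  Full double precision is kept so files round-trip exactly.
#'
#' @param features tibble from [compute_features()].
#' @param path file path.
#' @return `read_features()` returns the tibble; `write_features()`
#'   returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  out <- features
  dbl <- vapply(out, is.double, logical(1))
  # 17 significant digits: lossless for IEEE doubles
  out[dbl] <- lapply(out[dbl], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  # doubles come in as text and through base R's correctly rounded
  # parser, so written files reload bit-identically
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df$epoch <- as.integer(df$epoch)
  num <- setdiff(names(df), c("subject_id", "epoch", "label"))
  df[num] <- lapply(df[num], as.numeric)
  df
}
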