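#' Clean an R-peak train with a 5-beat median filter
#'
#' Compares every RR interval with the running median of the five
#' surrounding intervals.  An interval shorter than
#' `low_ratio x median` marks an artifactual extra beat (too close to
#' its predecessor), which is removed; an interval longer than
#' `high_ratio x median` marks missed beats (a gap), which is filled
#' with evenly spaced interpolated beats.  Passes are repeated until the
#' train is stable, so the operation is idempotent.
#'
#' @param times strictly increasing numeric vector of R-peak times in
#'   seconds, or a tibble with a `time_s` column.
#' @param low_ratio,high_ratio acceptance band for an interval relative
#'   to the running median; defaults 0.7 and 1.4, the conventional HRV
#'   artifact bounds.
#' @param max_pass safety cap on the number of passes.
#' @return Tibble with column `time_s`: the cleaned, strictly
#'   increasing beat times.
#' @examples
#' beats <- c(0:5, 5.1, 6:10) # one spurious beat at 5.1 s
#' clean_rpeaks(beats)
#' @export
clean_rpeaks <- function(times, low_ratio = 0.7, high_ratio = 1.4,
                         max_pass = 10L) {
  t <- rpeak_times(times)
  if (any(diff(t) <= 0)) abort("R-peak times must be strictly increasing")
  if (length(t) < 6L) {
    warn("fewer than 6 beats: median filter skipped")
    return(tibble(time_s = t))
  }
  for (pass in seq_len(max_pass)) {
    t2 <- clean_pass(t, low_ratio, high_ratio)
    if (length(t2) == length(t) && all(t2 == t)) break
    t <- t2
  }
  tibble(time_s = t)
}

rpeak_times <- function(times) {
  if (is.data.frame(times)) {
    if (!"time_s" %in% names(times)) abort("expected a `time_s` column")
    times <- times$time_s
  }
  as.numeric(times)
}

# one filter pass: scan intervals against the running 5-interval median
clean_pass <- function(t, low_ratio, high_ratio) {
  rr <- diff(t)
  n <- length(rr)
  med <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - 2L):min(n, i + 2L)
    median(rr[w])
  }, numeric(1))
  out <- t[1]
  for (i in seq_len(n)) {
    beat <- t[i + 1L]
    if (rr[i] < low_ratio * med[i]) next          # drop the early beat
    if (rr[i] > high_ratio * med[i]) {            # fill the gap
      k <- round(rr[i] / med[i])                  # presumed true beat count
      if (k >= 2) {
        fill <- t[i] + rr[i] * seq_len(k - 1L) / k
        out <- c(out, fill)
      }
    }
    out <- c(out, beat)
  }
  out
}

#' Instantaneous heart rate from R-peak times
#'
#' The IHR at beat i is 60/(r_i - r_(i-1)) beats per minute.  These
#' beat-anchored values are interpolated onto a uniform 4 Hz grid with
#' shape-preserving piecewise-cubic (monotone Hermite) interpolation,
#' which never overshoots the surrounding knot values.  The grid is
#' aligned to multiples of the sample period from time zero, so epochs
#' defined on recording time line up with samples exactly.
#'
#' @param times R-peak times (vector or tibble with `time_s`), already
#'   cleaned.
#' @param fs sampling rate in Hz (default 4).
#' @return An `ihr_series`: tibble with columns `time` (s) and `bpm`.
#' @examples
#' compute_ihr(seq(0, 60, by = 1)) # steady 60 bpm
#' @export
compute_ihr <- function(times, fs = 4) {
  t <- rpeak_times(times)
  if (length(t) < 2L) abort("at least 2 beats are needed to define an IHR")
  if (any(diff(t) <= 0)) abort("R-peak times must be strictly increasing")
  knots_t <- t[-1]
  knots_v <- 60 / diff(t)
  # left-extend with the first interval's rate so the grid can span the
  # first beat
  knots_t <- c(t[1], knots_t)
  knots_v <- c(knots_v[1], knots_v)
  grid <- seq(ceiling(t[1] * fs) / fs, floor(t[length(t)] * fs) / fs, by = 1 / fs)
  bpm <- signal::pchip(knots_t, knots_v, grid)
  structure(tibble(time = grid, bpm = bpm),
            fs = fs, class = c("ihr_series", class(tibble())))
}

#' Labeled 90-second IHR windows
#'
#' Cuts the IHR series into one window per scored 30-s epoch: the epoch
#' together with its two preceding epochs, 360 samples at 4 Hz ending at
#' the epoch's end time, centered by subtracting the window median.
#' Epochs are dropped when they have no full 90-s history (the first two
#' of a recording, or any window reaching before the first IHR sample)
#' and when their own 30-s span contains fewer than `min_beats` cleaned
#' R peaks (too little evidence for the heart rate there).
#'
#' @param ihr an `ihr_series` from [compute_ihr()].
#' @param labels tibble with columns `epoch` (1-based consecutive index)
#'   and `label` (`"W"`, `"R"` or `"N"`); epoch j spans
#'   ((j-1) x 30, j x 30] seconds of recording time.
#' @param times cleaned R-peak times (vector or tibble with `time_s`),
#'   used for the beat-count rule.
#' @param epoch_s epoch length in seconds (default 30).
#' @param window_epochs epochs per window (default 3).
#' @param min_beats minimum R peaks per labeled epoch (default 5).
#' @return Tibble: `subject_id` (NA here, filled by callers), `epoch`,
#'   `label`, `end_time`, `values` (list-column, each
#'   `window_epochs * epoch_s * fs` samples with median 0).
#' @export
extract_windows <- function(ihr, labels, times, epoch_s = 30,
                            window_epochs = 3L, min_beats = 5L) {
  stopifnot(inherits(ihr, "ihr_series"))
  if (!all(c("epoch", "label") %in% names(labels))) {
    abort("`labels` needs columns `epoch` and `label`")
  }
  bad <- labels$epoch[!labels$label %in% c("W", "R", "N")]
  if (length(bad)) {
    abort(sprintf("unknown stage label at epoch(s) %s",
                  paste(bad, collapse = ", ")))
  }
  if (!identical(as.integer(labels$epoch), seq_len(nrow(labels)))) {
    abort("`labels$epoch` must be the consecutive sequence 1, 2, ...")
  }
  fs <- attr(ihr, "fs")
  t <- rpeak_times(times)
  nwin <- as.integer(window_epochs * epoch_s * fs)
  t0 <- ihr$time[1]
  tend <- ihr$time[nrow(ihr)]

  rows <- purrr::map(seq_len(nrow(labels)), function(j) {
    if (j < window_epochs) return(NULL) # no full history yet
    end_time <- j * epoch_s
    start_time <- end_time - (nwin - 1L) / fs
    if (start_time < t0 || end_time > tend) return(NULL)
    nbeats <- sum(t > (j - 1) * epoch_s & t <= j * epoch_s)
    if (nbeats < min_beats) return(NULL)
    idx <- round((start_time - t0) * fs) + seq_len(nwin)
    v <- ihr$bpm[idx]
    tibble(epoch = j, label = labels$label[j], end_time = end_time,
           values = list(v - median(v)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(subject_id = character(0), epoch = integer(0),
                  label = character(0), end_time = numeric(0),
                  values = list()))
  }
  dplyr::bind_cols(tibble(subject_id = rep(NA_character_, nrow(out))), out)
}

#' Read R-peak and stage-label files
#'
#' `read_rpeaks()` reads a single-column CSV of beat times in seconds
#' (header `time_s`); an RR-interval file (header `rr_s`) is accepted
#' and converted by cumulative summation from time zero.
#' `read_stage_labels()` reads a CSV with columns `epoch` and `label`.
#'
#' @param path file path.
#' @return A tibble (`time_s`, or `epoch` + `label`).
#' @export
read_rpeaks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("time_s" %in% names(df)) {
    tibble(time_s = as.numeric(df$time_s))
  } else if ("rr_s" %in% names(df)) {
    tibble(time_s = cumsum(c(0, as.numeric(df$rr_s))))
  } else {
    abort("expected a `time_s` (beat times) or `rr_s` (intervals) column")
  }
}

#' @rdname read_rpeaks
#' @export
read_stage_labels <- function(path) {
  df <- readr::read_csv(path, col_types = "ic")
  stopifnot(all(c("epoch", "label") %in% names(df)))
  df
}
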