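#' The worked five-step filtration
#'
#' A fixed filtration on four vertices used throughout the persistence
#' literature as a worked example: vertices v1, v2 and their edge enter
#' at index 1; v3 attaches by an edge at index 2; the edge closing the
#' triangle cycle appears at index 3; index 4 adds v4 with two edges and
#' the filled triangle (v1, v2, v4); index 5 fills the (v1, v2, v3)
#' triangle.  Its persistence is one essential component born at 1 and
#' one loop born at 3 that dies at 5.
#'
#' @return A [filtration()].
#' @examples
#' compute_persistence(worked_filtration(), max_dim = 1)
#' @export
worked_filtration <- function() {
  filtration(
    simplices = list(
      1, 2, c(1, 2),                      # index 1
      3, c(2, 3),                         # index 2
      c(1, 3),                            # index 3: cycle closes
      4, c(1, 4), c(2, 4), c(1, 2, 4),    # index 4
      c(1, 2, 3)                          # index 5: cycle filled
    ),
    values = c(1, 1, 1, 2, 2, 3, 4, 4, 4, 4, 5)
  )
}

#' Points on a noisy circle
#'
#' Samples n angles uniformly on the unit circle and perturbs each
#' point with isotropic Gaussian noise.  The Rips dim-1 diagram of such
#' a cloud shows one long-lived loop (the circle) over short-lived
#' noise — the canonical illustration that persistence separates
#' structure from noise.
#'
#' @param n number of points (>= 4).
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed; the draw is fully reproducible.
#' @return An n x 2 numeric matrix.
#' @examples
#' cloud <- noisy_circle(100, sigma = 0.05, seed = 1)
#' vr_diagrams(cloud)
#' @export
noisy_circle <- function(n, sigma = 0.05, seed = 1L) {
  if (n < 4) abort("`n` must be at least 4")
  if (sigma < 0) abort("`sigma` must be non-negative")
  withr::with_seed(seed, {
    theta <- runif(n, 0, 2 * pi)
    cbind(cos(theta), sin(theta)) + matrix(rnorm(2 * n, 0, sigma), n, 2)
  })
}

#' Default per-stage physiology of the synthetic recording generator
#'
#' Mean RR interval, RR jitter, respiratory sinus-arrhythmia amplitude
#' and frequency per sleep stage, chosen to mimic textbook sleep
#' cardiology: wake is fast and irregular (sympathetic tone, external
#' stimuli), NREM slow and steady with pronounced respiratory
#' modulation (parasympathetic dominance), REM in between with a less
#' stable rhythm.  These are generator settings, not estimates of any
#' clinical dataset.
#'
#' @return Tibble with columns `stage`, `mean_rr`, `sd_rr`,
#'   `resp_amp`, `resp_freq`.
#' @export
stage_physiology <- function() {
  tibble(
    stage = c("W", "R", "N"),
    mean_rr = c(0.80, 0.90, 1.00),   # s
    sd_rr = c(0.060, 0.045, 0.020),  # s, beat-to-beat jitter
    resp_amp = c(0.010, 0.020, 0.040), # s, RSA modulation depth
    resp_freq = c(0.30, 0.25, 0.25)  # Hz, breathing rate
  )
}

#' Simulate a stage-labeled R-peak recording
#'
#' Generates a beat train by integrate-and-fire: the next beat follows
#' the previous one after an interval equal to the current stage's mean
#' RR, plus a respiratory sinusoidal modulation, plus Gaussian jitter.
#' During wake epochs, random transient accelerations (bursts in which
#' RR is multiplied by a factor below one for a run of beats) emulate
#' movement/arousal effects, making wake both faster and less stable.
#' Everything is driven by `seed`.
#'
#' @param stages character vector of per-epoch labels (`"W"`, `"R"`,
#'   `"N"`), one per 30-s epoch.
#' @param seed integer seed.
#' @param physiology per-stage parameters, see [stage_physiology()].
#' @param epoch_s epoch length in seconds (default 30).
#' @param wake_transient_rate per-beat probability of starting a
#'   transient acceleration during wake (default 0.05).
#' @param subject_id label stored with the recording.
#' @return A list with `rpeaks` (tibble `time_s`) and `labels` (tibble
#'   `epoch`, `label`).
#' @examples
#' rec <- synthetic_recording(rep(c("N", "W"), c(4, 2)), seed = 1)
#' nrow(rec$rpeaks)
#' @export
synthetic_recording <- function(stages, seed = 1L,
                                physiology = stage_physiology(),
                                epoch_s = 30,
                                wake_transient_rate = 0.05,
                                subject_id = "synthetic") {
  stages <- as.character(stages)
  if (length(stages) == 0) abort("`stages` must name at least one epoch")
  if (!all(stages %in% physiology$stage)) {
    abort(sprintf("stages must be one of: %s",
                  paste(physiology$stage, collapse = ", ")))
  }
  if (epoch_s <= 0) abort("`epoch_s` must be positive")
  phys <- as.data.frame(physiology)
  rownames(phys) <- phys$stage
  duration <- length(stages) * epoch_s

  withr::with_seed(seed, {
    t <- 0
    times <- 0 # a beat at recording start, so the IHR spans every epoch
    burst_left <- 0L
    burst_factor <- 1
    repeat {
      st <- stages[min(length(stages), floor(t / epoch_s) + 1L)]
      p <- phys[st, ]
      rr <- p$mean_rr +
        p$resp_amp * sin(2 * pi * p$resp_freq * t) +
        rnorm(1, 0, p$sd_rr)
      if (st == "W") {
        if (burst_left == 0L && runif(1) < wake_transient_rate) {
          burst_left <- sample(3:8, 1) # beats of transient tachycardia
          burst_factor <- runif(1, 0.70, 0.90)
        }
      } else {
        burst_left <- 0L
      }
      if (burst_left > 0L) {
        rr <- rr * burst_factor
        burst_left <- burst_left - 1L
      }
      rr <- max(rr, 0.3) # refractory floor
      t <- t + rr
      times <- c(times, t)
      if (t > duration) break # one overshoot beat closes the last epoch
    }
  })
  list(
    rpeaks = tibble(time_s = times),
    labels = tibble(epoch = seq_along(stages), label = stages),
    subject_id = subject_id
  )
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws one stage sequence per subject from a simple two-state dwell
#' process (runs of sleep broken by wake bouts; within sleep, runs of
#' NREM with occasional REM periods) and generates each recording with
#' [synthetic_recording()], using per-subject seeds derived from
#' `seed`.
#'
#' @param n_subjects number of subjects.
#' @param n_epochs epochs per subject.
#' @param seed integer seed.
#' @param ... passed to [synthetic_recording()].
#' @return List of recordings (see [synthetic_recording()]), with
#'   subject ids `"s01"`, `"s02"`, ...
#' @export
synthetic_cohort <- function(n_subjects, n_epochs, seed = 1L, ...) {
  purrr::map(seq_len(n_subjects), function(k) {
    sub_seed <- seed * 1000L + k
    stages <- withr::with_seed(sub_seed, draw_stage_sequence(n_epochs))
    synthetic_recording(stages, seed = sub_seed + 1L,
                        subject_id = sprintf("s%02d", k), ...)
  })
}

# runs of W / R / N with geometric dwell times; roughly 1/4 wake,
# REM interleaved in sleep
draw_stage_sequence <- function(n_epochs) {
  out <- character(0)
  state <- "W"
  while (length(out) < n_epochs) {
    dwell <- switch(state,
      W = 2L + stats::rgeom(1, 0.4),
      N = 4L + stats::rgeom(1, 0.25),
      R = 2L + stats::rgeom(1, 0.5)
    )
    out <- c(out, rep(state, dwell))
    state <- switch(state,
      W = "N",
      N = sample(c("R", "W"), 1, prob = c(0.6, 0.4)),
      R = sample(c("N", "W"), 1, prob = c(0.7, 0.3))
    )
  }
  out[seq_len(n_epochs)]
}
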