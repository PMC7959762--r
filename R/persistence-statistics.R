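#' Midpoint and lifespan multisets of a diagram
#'
#' Each finite-death point (b, d) of a persistence diagram contributes a
#' midpoint (b + d)/2 to M and a lifespan d - b to L.  For a Rips
#' filtration the midpoint captures the size of a hole and the lifespan
#' its robustness; for a sub-level filtration the midpoint locates an
#' oscillation and the lifespan measures peak-to-trough amplitude.
#' Infinite-death (essential) points are discarded — every diagram of a
#' connected filtration carries one, and it holds no comparative
#' information.  Zero lifespans are kept: short-lived classes are not
#' treated as noise.
#'
#' @param diagram a [persistence_diagram()] (restrict to one dimension
#'   before calling if it mixes several).
#' @return A list with numeric components `M` (midpoints) and `L`
#'   (lifespans, all >= 0), of equal length.
#' @examples
#' d <- persistence_diagram(1, 3, 5)
#' diagram_to_multisets(d) # M = 4, L = 2
#' @export
diagram_to_multisets <- function(diagram) {
  fin <- diagram[is.finite(diagram$death), ]
  list(M = (fin$birth + fin$death) / 2, L = fin$death - fin$birth)
}

#' Persistent entropy of a multiset
#'
#' Shannon entropy (natural log) of the values normalized by their sum:
#' E = sum over v of -(v/S) log(v/S) with S the total.  It measures how
#' evenly the mass of the multiset is spread: 0 when a single value
#' carries everything, log(n) when all n values are equal.  Zero values
#' contribute nothing (the x log x limit); an empty multiset, or one
#' summing to zero, has entropy 0.
#'
#' @param values numeric vector of non-negative values.
#' @return A non-negative number.
#' @examples
#' persistent_entropy(c(1, 3)) # about 0.5623
#' @export
persistent_entropy <- function(values) {
  if (any(values < 0)) abort("persistent entropy needs non-negative values")
  s <- sum(values)
  if (length(values) == 0 || s == 0) return(0)
  p <- values[values > 0] / s
  -sum(p * log(p))
}

ps_stat_names <- function() {
  stats <- c("mean", "sd", "skew", "kurt", "q25", "q50", "q75", "entropy")
  c(paste0("M_", stats), paste0("L_", stats))
}

#' The 16 persistence statistics of a diagram
#'
#' Summarizes a persistence diagram as a fixed-length vector: the mean,
#' standard deviation, skewness, kurtosis, 25th/50th/75th percentiles
#' and persistent entropy of the midpoint multiset M (statistics 1-8)
#' and of the lifespan multiset L (statistics 9-16).  Conventions:
#' population (biased) moments, non-excess kurtosis (normal about 3),
#' linearly interpolated percentiles; statistics of an empty multiset
#' are 0 and the skewness/kurtosis of a zero-spread multiset are 0, so
#' the vector is always finite.  The entropy of M is computed on
#' absolute midpoints (midpoints of a median-centered series can be
#' negative; entropy needs non-negative mass).
#'
#' @param diagram a [persistence_diagram()].
#' @return Named numeric vector of length 16 (`M_mean` ... `L_entropy`).
#' @examples
#' d <- persistence_diagram(c(0, 0, 0), c(0, 1, 2), c(4, 3, 6))
#' persistence_statistics(d)
#' @export
persistence_statistics <- function(diagram) {
  ml <- diagram_to_multisets(diagram)
  out <- c(multiset_stats_(ml$M, entropy_on_abs = TRUE),
           multiset_stats_(ml$L, entropy_on_abs = FALSE))
  stats::setNames(out, ps_stat_names())
}

multiset_stats_ <- function(v, entropy_on_abs) {
  if (length(v) == 0) return(rep(0, 8))
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- sqrt(m2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  e <- persistent_entropy(if (entropy_on_abs) abs(v) else v)
  c(m, s, skew, kurt, q, e)
}
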