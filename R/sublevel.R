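#' Sub-level set persistence of a time series
#'
#' The sub-level set filtration of a function f grows the domain
#' \{t : f(t) <= h\} as the threshold h rises; its 0-dimensional
#' persistence pairs each local minimum (a component birth) with the
#' local maximum at which its component merges into an older one.  The
#' component of the global minimum never dies and is reported with
#' `death = Inf`.  For a sampled series the min-max pairs are identical
#' whether the samples are read as a step function or as a piecewise
#' linear interpolant, so the computation works directly on the samples.
#'
#' Implemented by a single sweep over the sample values in increasing
#' order with union-find over adjacent indices: equal consecutive values
#' form one flat critical region, merges follow the elder rule (the
#' component with the smaller minimum survives; value ties broken by the
#' earlier index).  [compute_persistence()] on the explicit lower-star
#' filtration is the independent cross-check for this routine.
#'
#' @param x numeric vector, the sampled series.
#' @return A [persistence_diagram()] with `dimension = 0` points:
#'   finite (local-min value, merging-max value) pairs plus one
#'   essential point (global minimum, `Inf`).
#' @examples
#' sublevel_diagram(c(0, 2, 1, 3)) # (0, Inf) and (1, 2)
#' @export
sublevel_diagram <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) abort("empty series")
  if (any(!is.finite(x))) abort("series must be finite")
  n <- length(x)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  active <- logical(n)
  comp_min_value <- rep(NA_real_, n) # root -> value of the component minimum
  comp_min_index <- rep(NA_integer_, n)

  births <- numeric(0)
  deaths <- numeric(0)

  ord <- order(x, seq_len(n))
  for (i in ord) {
    active[i] <- TRUE
    comp_min_value[i] <- x[i]
    comp_min_index[i] <- i
    for (nb in c(i - 1L, i + 1L)) {
      if (nb < 1L || nb > n || !active[nb]) next
      ra <- find(i); rb <- find(nb)
      if (ra == rb) next
      # elder rule: the component with the later-entered minimum dies
      older_a <- comp_min_value[ra] < comp_min_value[rb] ||
        (comp_min_value[ra] == comp_min_value[rb] &&
           comp_min_index[ra] < comp_min_index[rb])
      older <- if (older_a) ra else rb
      younger <- if (older_a) rb else ra
      if (comp_min_value[younger] < x[i]) { # flat regions merge silently
        births <- c(births, comp_min_value[younger])
        deaths <- c(deaths, x[i])
      }
      parent[younger] <- older
    }
  }

  persistence_diagram(
    dimension = rep(0L, length(births) + 1L),
    birth = c(births, min(x)),
    death = c(deaths, Inf)
  )
}
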