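#' Persistence diagram container
#'
#' A persistence diagram is the multiset of (birth, death) value pairs of
#' the homology classes of a filtration, one row per class, tagged with
#' the homology dimension (0 = connected components, 1 = loops).  A death
#' of `Inf` marks an essential class that survives the whole filtration.
#'
#' @param dimension integer vector of homology dimensions.
#' @param birth,death numeric vectors of birth and death values
#'   (`death` may be `Inf`).
#' @return A `persistence_diagram`: tibble with columns `dimension`,
#'   `birth`, `death`, sorted by (dimension, birth, death).
#' @export
persistence_diagram <- function(dimension = integer(), birth = numeric(),
                                death = numeric()) {
  d <- tibble(
    dimension = as.integer(dimension),
    birth = as.numeric(birth),
    death = as.numeric(death)
  )
  if (any(d$death < d$birth)) abort("death < birth in persistence diagram")
  d <- d[order(d$dimension, d$birth, d$death), ]
  structure(d, class = c("persistence_diagram", class(tibble())))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  ess <- sum(is.infinite(x$death))
  cat(sprintf("# Persistence diagram: %d points (%d essential), dims %s\n",
              nrow(x), ess,
              paste(sort(unique(x$dimension)), collapse = ", ")))
  NextMethod()
}

#' Drop zero-persistence points
#'
#' Remove points whose birth and death coincide.  Such points pair a
#' simplex with an immediate coface entering at the same filtration
#' value; they correspond to no homology class of any complex in the
#' filtration and are conventionally omitted from the diagram of a
#' point-cloud filtration.
#'
#' @param diagram a [persistence_diagram()].
#' @return The filtered [persistence_diagram()].
#' @export
drop_zero_persistence <- function(diagram) {
  persistence_diagram_from_df(diagram[diagram$death > diagram$birth |
                                        is.infinite(diagram$death), ])
}

persistence_diagram_from_df <- function(df) {
  persistence_diagram(df$dimension, df$birth, df$death)
}

#' Read / write a persistence diagram as CSV
#'
#' Columns `dim`, `birth`, `death`; infinite deaths are written as the
#' literal `"inf"`.  Full double precision is kept so files round-trip
#' exactly.
#'
#' @param diagram a [persistence_diagram()].
#' @param path file path.
#' @return `read_diagram()` returns a [persistence_diagram()];
#'   `write_diagram()` returns `path` invisibly.
#' @export
write_diagram <- function(diagram, path) {
  out <- tibble(
    dim = diagram$dimension,
    birth = format(diagram$birth, digits = 17, trim = TRUE, scientific = FALSE),
    death = ifelse(is.infinite(diagram$death), "inf",
                   format(diagram$death, digits = 17, trim = TRUE,
                          scientific = FALSE))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- readr::read_csv(path, col_types = "icc")
  death <- ifelse(tolower(df$death) == "inf", Inf, as.numeric(df$death))
  persistence_diagram(df$dim, as.numeric(df$birth), death)
}

#' Plot a persistence diagram
#'
#' Births against deaths, one panel convention: points above the
#' diagonal, essential classes drawn at the top margin as triangles.
#'
#' @param object a [persistence_diagram()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  finite <- object[is.finite(object$death), ]
  ess <- object[is.infinite(object$death), ]
  top <- max(c(finite$death, finite$birth, ess$birth, 1)) * 1.05
  p <- ggplot2::ggplot(finite, ggplot2::aes(x = .data$birth, y = .data$death,
                                            colour = factor(.data$dimension))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "birth", y = "death", colour = "dim") +
    ggplot2::theme_minimal()
  if (nrow(ess)) {
    p <- p + ggplot2::geom_point(
      data = transform(ess, death = top),
      shape = 17, size = 2.5
    )
  }
  p
}
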