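#' Vietoris-Rips persistence of a point cloud
#'
#' The Vietoris-Rips complex at scale epsilon contains every simplex
#' whose vertex set has diameter at most 2 epsilon; growing epsilon
#' yields a filtration whose persistence summarizes the cloud's shape.
#' All births and deaths are reported on the epsilon (radius) scale,
#' i.e. half the simplex diameter.
#'
#' Dimension 0 comes from union-find over the edge filtration (finite
#' deaths are half the Euclidean minimum-spanning-tree edge lengths, and
#' the essential class (0, Inf) of the last surviving component is
#' retained in the diagram).  Dimension 1 is computed by reduction of
#' the edge coboundary matrix in reverse filtration order (persistent
#' cohomology) with clearing and lazy heap columns, in compiled code;
#' the barcode is identical to boundary-matrix reduction, which serves
#' as its cross-check at small sizes via [compute_persistence()].
#' Dim-1 pairs with equal birth and death (an edge filled by a coface of
#' the same diameter) correspond to no homology class of the
#' scale-indexed filtration and are omitted; dim-0 keeps all n - 1
#' merge deaths, zero-length ones included, so the MST identity holds
#' even with duplicated points.
#'
#' @param cloud numeric matrix, one point per row (Euclidean metric),
#'   or a `dist` object.
#' @param max_dim highest homology dimension, 0 or 1 (dimension >= 2 is
#'   deliberately unsupported: its cost grows too quickly with cloud
#'   size to be useful here).
#' @param max_scale only simplexes entering at epsilon <= `max_scale`
#'   are built; classes alive at the cap are reported with
#'   `death = Inf`.  Default `Inf` (exact diagram).
#' @return A [persistence_diagram()].
#' @examples
#' square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' vr_diagrams(square) # one loop: born 1/2, filled at sqrt(2)/2
#' @export
vr_diagrams <- function(cloud, max_dim = 1L, max_scale = Inf) {
  if (inherits(cloud, "dist")) {
    dmat <- as.matrix(cloud)
  } else {
    cloud <- as.matrix(cloud)
    if (nrow(cloud) == 0) abort("empty point cloud")
    if (any(!is.finite(cloud))) abort("point cloud must be finite")
    dmat <- as.matrix(dist(cloud))
  }
  if (nrow(dmat) == 0) abort("empty point cloud")
  max_dim <- as.integer(max_dim)
  if (!max_dim %in% c(0L, 1L)) {
    abort("`max_dim` must be 0 or 1 for Vietoris-Rips persistence")
  }
  if (!(max_scale > 0)) abort("`max_scale` must be positive")

  res <- .rips_persistence_cpp(dmat, 2 * max_scale, max_dim >= 1L)

  # dim 0 keeps all n - 1 merge deaths (including 0 for duplicate points,
  # matching the MST identity); dim 1 pairs with birth == death are the
  # artifacts of equal-diameter cofaces and are omitted in compiled code
  d0 <- res$deaths0 / 2
  dimension <- c(rep(0L, length(d0) + res$n_components),
                 rep(1L, length(res$births1)))
  birth <- c(rep(0, length(d0) + res$n_components), res$births1 / 2)
  death <- c(d0, rep(Inf, res$n_components), res$deaths1 / 2)
  persistence_diagram(dimension, birth, death)
}
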