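#' Persistent homology of a filtered simplicial complex
#'
#' Computes the persistence diagram of an arbitrary filtration over the
#' field with two elements, by the standard column reduction of the
#' filtration-ordered boundary matrix: columns are processed in
#' filtration order, each is added to earlier columns sharing its lowest
#' non-zero row until its pivot is free, and every settled pivot pairs a
#' birth simplex with a death simplex.  Ties (simplexes entering at the
#' same value) are ordered by dimension then lexicographic vertex tuple,
#' so the pairing is deterministic.  Components merge by the elder rule:
#' the component whose minimum entered later dies.
#'
#' Pairs whose birth and death values coincide (simplex and killing
#' coface entering at the same value) are retained in the output; use
#' [drop_zero_persistence()] to obtain the diagram of the value-indexed
#' filtration, in which such pairs correspond to no homology class.
#'
#' @param flt a [filtration()].
#' @param max_dim highest homology dimension to report (classes of all
#'   dimensions present in the filtration are computed; the boundary of
#'   a (q+1)-simplex is what kills a q-class, so the filtration must
#'   contain the (q+1)-simplexes for deaths in dimension q to be found).
#' @return A [persistence_diagram()] with all classes of dimension
#'   `0..max_dim`, essential classes having `death = Inf`.
#' @examples
#' flt <- worked_filtration()
#' compute_persistence(flt, max_dim = 1)
#' @export
compute_persistence <- function(flt, max_dim = 1L) {
  stopifnot(max_dim >= 0)
  validate_filtration(flt)
  n <- nrow(flt)
  ids <- simplex_id(flt$simplex)
  pos <- stats::setNames(seq_len(n), ids)
  dims <- flt$dim
  values <- flt$value

  # boundary columns as sorted position vectors
  boundary <- vector("list", n)
  for (j in seq_len(n)) {
    v <- flt$simplex[[j]]
    if (length(v) == 1L) {
      boundary[[j]] <- integer(0)
    } else {
      faces <- vapply(seq_along(v),
                      function(drop) paste(v[-drop], collapse = ","),
                      character(1))
      boundary[[j]] <- sort(unname(pos[faces]))
    }
  }

  low_owner <- integer(n) # pivot row -> column that owns it (0 = free)
  reduced <- boundary
  pair_birth <- integer(0)
  pair_death <- integer(0)
  for (j in seq_len(n)) {
    col <- reduced[[j]]
    while (length(col)) {
      piv <- col[length(col)]
      o <- low_owner[piv]
      if (o == 0L) {
        low_owner[piv] <- j
        pair_birth <- c(pair_birth, piv)
        pair_death <- c(pair_death, j)
        break
      }
      other <- reduced[[o]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    reduced[[j]] <- col
  }

  # positive simplexes (zero reduced column) never paired are essential
  zero_col <- vapply(reduced, length, integer(1)) == 0L
  essential <- which(zero_col & low_owner == 0L)

  keep <- dims[pair_birth] <= max_dim
  d <- persistence_diagram(
    dimension = c(dims[pair_birth[keep]], dims[essential[dims[essential] <= max_dim]]),
    birth = c(values[pair_birth[keep]], values[essential[dims[essential] <= max_dim]]),
    death = c(values[pair_death[keep]], rep(Inf, sum(dims[essential] <= max_dim)))
  )
  d
}

#' Betti numbers of a filtration at a value
#'
#' The q-th Betti number counts q-dimensional holes: components for
#' q = 0, loops for q = 1, and so on.  Computed directly from the
#' definition on the sub-complex of simplexes with entry value at most
#' `at_value`: the rank-nullity identity over the two-element field,
#' beta_q = dim ker(boundary_q) - rank(boundary_{q+1}), with ranks
#' obtained by Gaussian elimination.  This route is independent of the
#' reduction pairing in [compute_persistence()] and serves as its
#' cross-check.
#'
#' @param flt a [filtration()].
#' @param at_value filtration value at which to take the sub-complex.
#' @return Integer vector `c(beta_0, beta_1, ..., beta_qmax)` where
#'   `qmax` is the largest simplex dimension present in the sub-complex.
#' @examples
#' betti_numbers(worked_filtration(), at_value = 3) # one component, one loop
#' @export
betti_numbers <- function(flt, at_value) {
  validate_filtration(flt)
  if (at_value < min(flt$value)) {
    abort("`at_value` precedes the first filtration value")
  }
  sub <- flt[flt$value <= at_value, ]
  qmax <- max(sub$dim)
  ids <- simplex_id(sub$simplex)
  pos_by_dim <- lapply(0:qmax, function(q) which(sub$dim == q))
  betti <- integer(qmax + 1L)
  rank_bnd <- function(q) {
    # rank over Z2 of the boundary map C_q -> C_{q-1} of the sub-complex
    cols_idx <- pos_by_dim[[q + 1L]]
    rows_idx <- pos_by_dim[[q]]
    if (length(cols_idx) == 0 || length(rows_idx) == 0) return(0L)
    row_of <- stats::setNames(seq_along(rows_idx), ids[rows_idx])
    mat <- matrix(0L, length(rows_idx), length(cols_idx))
    for (jj in seq_along(cols_idx)) {
      v <- sub$simplex[[cols_idx[jj]]]
      faces <- vapply(seq_along(v),
                      function(drop) paste(v[-drop], collapse = ","),
                      character(1))
      mat[row_of[faces], jj] <- 1L
    }
    z2_rank(mat)
  }
  for (q in 0:qmax) {
    ncols <- length(pos_by_dim[[q + 1L]])
    rank_q <- if (q == 0) 0L else rank_bnd(q)
    rank_q1 <- if (q < qmax) rank_bnd(q + 1L) else 0L
    betti[q + 1L] <- ncols - rank_q - rank_q1 # dim ker - rank of next boundary
  }
  betti
}

# rank of a 0/1 matrix over Z2 by Gaussian elimination
z2_rank <- function(mat) {
  r <- 0L
  nr <- nrow(mat); nc <- ncol(mat)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(mat[row:nr, col] == 1L)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) mat[c(piv, row), ] <- mat[c(row, piv), ]
    hit <- which(mat[, col] == 1L)
    hit <- hit[hit != row]
    if (length(hit)) {
      mat[hit, ] <- (mat[hit, , drop = FALSE] +
                       matrix(mat[row, ], length(hit), nc, byrow = TRUE)) %% 2L
    }
    r <- r + 1L
    row <- row + 1L
    if (row > nr) break
  }
  r
}
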