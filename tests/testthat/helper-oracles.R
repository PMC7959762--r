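# Independent oracles used across the suite.  Each reimplements the
# quantity it checks from first principles, sharing no code path with
# the package internals it validates.

# ---- Z2 linear algebra ------------------------------------------------

# rank of a 0/1 matrix over Z2, by row reduction written independently
# of hrvtda:::z2_rank (column-major sweep instead of row-major)
oracle_z2_rank <- function(m) {
  if (length(m) == 0) return(0L)
  m <- m %% 2L
  rank <- 0L
  for (j in seq_len(ncol(m))) {
    rows <- which(m[, j] == 1L)
    rows <- rows[rows > rank]
    if (!length(rows)) next
    rank <- rank + 1L
    if (rows[1] != rank) m[c(rank, rows[1]), ] <- m[c(rows[1], rank), ]
    others <- which(m[, j] == 1L)
    others <- others[others != rank]
    for (r in others) m[r, ] <- (m[r, ] + m[rank, ]) %% 2L
  }
  rank
}

# Betti numbers of the sub-complex of `flt` at a value, straight from
# the definition: beta_q = (#q-simplexes) - rank d_q - rank d_{q+1}
oracle_betti <- function(flt, at_value) {
  sub <- flt[flt$value <= at_value, ]
  ids <- vapply(sub$simplex, paste, character(1), collapse = ",")
  qmax <- max(sub$dim)
  bnd_matrix <- function(q) {
    cols <- which(sub$dim == q)
    rows <- which(sub$dim == q - 1L)
    if (!length(cols) || !length(rows)) return(matrix(0L, 0, 0))
    m <- matrix(0L, length(rows), length(cols))
    rid <- stats::setNames(seq_along(rows), ids[rows])
    for (cc in seq_along(cols)) {
      v <- sub$simplex[[cols[cc]]]
      for (drop in seq_along(v)) {
        m[rid[paste(v[-drop], collapse = ",")], cc] <- 1L
      }
    }
    m
  }
  vapply(0:qmax, function(q) {
    nq <- sum(sub$dim == q)
    rq <- if (q == 0) 0L else oracle_z2_rank(bnd_matrix(q))
    rq1 <- if (q < qmax) oracle_z2_rank(bnd_matrix(q + 1L)) else 0L
    as.integer(nq - rq - rq1)
  }, integer(1))
}

# Betti curve implied by a persistence diagram: number of classes of
# dimension q alive at value v (born at or before v, dead after v)
diagram_betti <- function(diag, q, v) {
  d <- diag[diag$dimension == q, ]
  sum(d$birth <= v & d$death > v)
}

# ---- random filtration generator --------------------------------------

# random filtration on <= n_max vertices: a random subset of the full
# complex, closed under faces, values consistent with nesting
random_filtration <- function(n_max = 6L, max_dim = 2L) {
  n <- sample(2:n_max, 1)
  simp <- list()
  for (q in 0:min(max_dim, n - 1L)) {
    combs <- utils::combn(n, q + 1L, simplify = FALSE)
    keep <- if (q == 0) combs else combs[runif(length(combs)) < 0.7]
    simp <- c(simp, keep)
  }
  # drop simplexes with a missing face
  ids <- vapply(simp, paste, character(1), collapse = ",")
  ok <- rep(TRUE, length(simp))
  for (i in seq_along(simp)) {
    v <- simp[[i]]
    if (length(v) == 1) next
    for (drop in seq_along(v)) {
      if (!(paste(v[-drop], collapse = ",") %in% ids)) ok[i] <- FALSE
    }
  }
  simp <- simp[ok]
  ids <- ids[ok]
  # values: vertex values random ints, coface >= max(face values)
  value <- stats::setNames(rep(NA_real_, length(simp)), ids)
  for (q in 0:max(vapply(simp, length, integer(1)) - 1L)) {
    for (i in which(vapply(simp, length, integer(1)) == q + 1L)) {
      v <- simp[[i]]
      floor_v <- if (q == 0) 0 else
        max(vapply(seq_along(v), function(d) value[paste(v[-d], collapse = ",")],
                   numeric(1)))
      value[ids[i]] <- floor_v + sample(0:2, 1)
    }
  }
  filtration(simp, unname(value))
}

# ---- sub-level set oracle ---------------------------------------------

# number of connected runs of TRUE in a logical vector
count_runs <- function(mask) {
  r <- rle(mask)
  sum(r$values)
}

# 0-dim sub-level diagram by explicit threshold sweep: at each distinct
# value h, components of {x <= h} are counted; births/deaths recovered
# from the component-count trajectory is not enough to get the pairing,
# so this oracle instead checks the MULTISET of births and deaths via
# the component counts: #finite pairs dead by h + #alive at h = #births
# at or below h.  For full pairing checks we compare against
# compute_persistence on the explicit lower-star filtration.
oracle_sublevel_betti0 <- function(x, h) count_runs(x <= h)

# lower-star filtration of a sampled series: vertex i at value x[i],
# edge (i, i+1) at max(x[i], x[i+1])
lower_star_filtration <- function(x) {
  n <- length(x)
  simp <- c(as.list(seq_len(n)),
            lapply(seq_len(n - 1L), function(i) c(i, i + 1L)))
  vals <- c(x, pmax(x[-n], x[-1]))
  filtration(simp, vals)
}

# ---- MST oracle -------------------------------------------------------

# Euclidean minimum-spanning-tree edge weights by Prim's algorithm
oracle_mst_weights <- function(X) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  if (n == 1) return(numeric(0))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]
  weights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    weights <- c(weights, unname(best[nxt]))
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  weights
}

# ---- misc -------------------------------------------------------------

# simple independent statistics for the 16-vector check
oracle_ps <- function(M, L) {
  one <- function(v, absolute_entropy) {
    if (!length(v)) return(rep(0, 8))
    mu <- mean(v)
    m2 <- sum((v - mu)^2) / length(v)
    ent <- function(w) {
      w <- w[w > 0]
      if (!length(w)) return(0)
      p <- w / sum(w)
      -sum(p * log(p))
    }
    c(mu,
      sqrt(m2),
      if (m2 > 0) (sum((v - mu)^3) / length(v)) / m2^(3 / 2) else 0,
      if (m2 > 0) (sum((v - mu)^4) / length(v)) / m2^2 else 0,
      unname(quantile(v, 0.25)), unname(quantile(v, 0.5)),
      unname(quantile(v, 0.75)),
      ent(if (absolute_entropy) abs(v) else v))
  }
  c(one(M, TRUE), one(L, FALSE))
}

# a tiny linearly separable feature tibble for classifier tests
separable_features <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per_class * 2, mean = -2, sd = 0.3), ncol = 2),
      matrix(rnorm(n_per_class * 2, mean = +2, sd = 0.3), ncol = 2)
    )
  })
  tibble::tibble(
    subject_id = rep(c("a", "b"), n_per_class),
    epoch = seq_len(2 * n_per_class),
    label = rep(c("W", "S"), each = n_per_class),
    f1 = x[, 1], f2 = x[, 2]
  )
}
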