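#' Bottleneck distance between two persistence diagrams
#'
#' The bottleneck distance is the smallest r such that the points of the
#' two diagrams (restricted to one homology dimension) can be matched —
#' with unmatched points allowed to go to the diagonal — moving no point
#' by more than r in the sup norm.  It is the metric in which persistence
#' diagrams are stable: a sup-norm perturbation of the underlying
#' function moves the diagram by no more than the perturbation.
#'
#' The computation is exact: candidate radii are the finitely many
#' point-to-point and point-to-diagonal costs, and feasibility at a
#' radius is decided by maximum bipartite matching (augmenting paths)
#' with a binary search over the candidates.  Intended for validation at
#' small diagram sizes (tens of points), not production scale.
#'
#' Essential (infinite-death) points are compared separately: if the two
#' diagrams have different numbers of them the distance is `Inf`;
#' otherwise the essential points are matched by their births and the
#' finite part is matched as above.
#'
#' @param d1,d2 [persistence_diagram()]s.
#' @param dim homology dimension to compare (default 0).
#' @return A non-negative number (possibly `Inf`).
#' @examples
#' d1 <- persistence_diagram(0, 0, 2)
#' d2 <- persistence_diagram(0, 0, 3)
#' bottleneck_distance(d1, d2) # 1
#' @export
bottleneck_distance <- function(d1, d2, dim = 0L) {
  p1 <- d1[d1$dimension == dim, ]
  p2 <- d2[d2$dimension == dim, ]
  e1 <- p1[is.infinite(p1$death), ]
  e2 <- p2[is.infinite(p2$death), ]
  if (nrow(e1) != nrow(e2)) return(Inf)
  ess_cost <- if (nrow(e1)) max(abs(sort(e1$birth) - sort(e2$birth))) else 0
  f1 <- as.matrix(p1[is.finite(p1$death), c("birth", "death")])
  f2 <- as.matrix(p2[is.finite(p2$death), c("birth", "death")])
  n1 <- nrow(f1); n2 <- nrow(f2)
  if (n1 == 0 && n2 == 0) return(ess_cost)

  diag_cost1 <- if (n1) (f1[, 2] - f1[, 1]) / 2 else numeric(0)
  diag_cost2 <- if (n2) (f2[, 2] - f2[, 1]) / 2 else numeric(0)
  if (n1 == 0 || n2 == 0) return(max(ess_cost, diag_cost1, diag_cost2))

  cross <- outer(seq_len(n1), seq_len(n2), function(i, j) {
    pmax(abs(f1[i, 1] - f2[j, 1]), abs(f1[i, 2] - f2[j, 2]))
  })

  feasible <- function(r) {
    # left: points of d1 plus one diagonal slot per point of d2
    # right: points of d2 plus one diagonal slot per point of d1
    # left i <= n1 matches right j <= n2 when cross[i, j] <= r;
    # a point matches its own diagonal slot when half-persistence <= r;
    # diagonal slots match each other freely (Kuhn's augmenting paths).
    nl <- n1 + n2
    adj <- function(i) {
      if (i <= n1) {
        js <- which(cross[i, ] <= r)
        if (diag_cost1[i] <= r) js <- c(js, n2 + i)
        js
      } else {
        j2 <- i - n1
        js <- (n2 + 1L):(n2 + n1)
        if (diag_cost2[j2] <= r) js <- c(j2, js)
        js
      }
    }
    match_r <- integer(n2 + n1) # right vertex -> matched left vertex
    seen <- logical(n2 + n1)
    augment <- function(i) {
      for (j in adj(i)) {
        if (seen[j]) next
        seen[j] <<- TRUE
        if (match_r[j] == 0L || augment(match_r[j])) {
          match_r[j] <<- i
          return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(nl)) {
      seen[] <- FALSE
      if (!augment(i)) return(FALSE)
    }
    TRUE
  }

  cand <- sort(unique(c(0, as.vector(cross), diag_cost1, diag_cost2)))
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  max(ess_cost, cand[lo])
}
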