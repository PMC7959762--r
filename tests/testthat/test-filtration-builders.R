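# ---- sub-level set filtration ----------------------------------------

test_that("sub-level diagram pairs minima with merging maxima", {
  d <- sublevel_diagram(c(0, 2, 1, 3))
  expect_equal(d$birth, c(0, 1))
  expect_equal(d$death, c(Inf, 2))

  # strictly monotone: single essential point
  d <- sublevel_diagram(1:10)
  expect_equal(nrow(d), 1)
  expect_equal(d$birth, 1)
  expect_equal(d$death, Inf)
  expect_error(sublevel_diagram(numeric(0)), "empty")
})

test_that("a k-period sine gives k min-max pairs", {
  k <- 4
  # start at a crest so the boundary samples are maxima, not extra minima
  t <- seq(pi / 2, pi / 2 + k * 2 * pi, length.out = 2000)
  x <- sin(t)
  d <- sublevel_diagram(x)
  expect_equal(nrow(d), k) # essential + (k - 1) finite
  fin <- d[is.finite(d$death), ]
  expect_equal(fin$birth, rep(-1, k - 1), tolerance = 1e-4)
  expect_equal(fin$death, rep(1, k - 1), tolerance = 1e-4)
})

test_that("sub-level diagram agrees with the persistence engine on the lower-star filtration", {
  withr::with_seed(7, {
    for (trial in 1:40) {
      x <- round(rnorm(sample(3:50, 1)), 2) # rounding forces ties too
      direct <- sublevel_diagram(x)
      via_core <- drop_zero_persistence(
        compute_persistence(lower_star_filtration(x), max_dim = 0)
      )
      expect_equal(as.data.frame(direct), as.data.frame(via_core),
                   info = paste("trial", trial))
    }
  })
})

test_that("sub-level component counts match the threshold-sweep oracle", {
  withr::with_seed(15, {
    for (trial in 1:20) {
      x <- rnorm(sample(5:50, 1))
      d <- sublevel_diagram(x)
      for (h in sort(unique(x))) {
        expect_equal(diagram_betti(d, 0, h), oracle_sublevel_betti0(x, h))
      }
    }
  })
})

# ---- Takens embedding -------------------------------------------------

test_that("takens embedding has the promised geometry", {
  x <- rnorm(360)
  cloud <- takens_embedding(x, p = 120, tau = 1)
  expect_equal(dim(cloud), c(241, 120))
  expect_equal(cloud[1, ], x[120:1])      # coordinates are delays
  expect_equal(cloud[241, ], x[360:241])

  expect_equal(takens_embedding(x, p = 1, tau = 3), matrix(x, ncol = 1))
  const <- takens_embedding(rep(2, 10), p = 4, tau = 2)
  expect_true(all(const == 2))
  expect_error(takens_embedding(rnorm(100), p = 120, tau = 1), "at least 120")
})

# ---- Vietoris-Rips ----------------------------------------------------

test_that("Rips diagrams of tiny configurations are exact", {
  # two points: merge at half the distance
  two <- rbind(c(0, 0), c(3, 0))
  d <- vr_diagrams(two)
  d0 <- d[d$dimension == 0, ]
  expect_equal(sort(d0$death), c(1.5, Inf))
  expect_equal(d0$birth, c(0, 0))

  # equilateral triangle: the loop is filled the instant it closes
  s <- 2
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  d <- vr_diagrams(tri)
  expect_equal(sum(d$dimension == 1), 0)

  # unit square: one loop, born 1/2, dead at sqrt(2)/2
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d1 <- vr_diagrams(sq)
  d1 <- d1[d1$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 0.5)
  expect_equal(d1$death, sqrt(2) / 2)

  expect_error(vr_diagrams(matrix(numeric(0), 0, 2)), "empty")
})

test_that("Rips dim-0 deaths are half the MST edge weights", {
  withr::with_seed(5, {
    for (trial in 1:30) {
      n <- sample(3:25, 1)
      X <- matrix(rnorm(n * sample(2:4, 1)), nrow = n)
      d <- vr_diagrams(X, max_dim = 0)
      finite <- sort(d$death[is.finite(d$death)])
      expect_equal(finite, sort(oracle_mst_weights(X)) / 2,
                   info = paste("trial", trial))
    }
  })
})

test_that("compiled Rips reduction matches the generic engine on small clouds", {
  withr::with_seed(13, {
    for (trial in 1:25) {
      n <- sample(4:8, 1)
      X <- matrix(rnorm(n * 2), nrow = n)
      fast <- vr_diagrams(X, max_dim = 1)

      # explicit filtration on the epsilon scale, reduced by the R engine
      D <- as.matrix(dist(X))
      simp <- as.list(seq_len(n))
      vals <- rep(0, n)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        simp <- c(simp, list(c(i, j))); vals <- c(vals, D[i, j] / 2)
      }
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        simp <- c(simp, list(c(i, j, k)))
        vals <- c(vals, max(D[i, j], D[i, k], D[j, k]) / 2)
      }
      slow <- drop_zero_persistence(
        compute_persistence(filtration(simp, vals), max_dim = 1)
      )
      expect_equal(as.data.frame(fast), as.data.frame(slow),
                   info = paste("trial", trial))
    }
  })
})

test_that("a finite scale cap truncates deaths to infinity", {
  # square with cap below the loop's filling scale
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d <- vr_diagrams(sq, max_scale = 0.6)
  d1 <- d[d$dimension == 1, ]
  expect_equal(d1$birth, 0.5)
  expect_equal(d1$death, Inf)
  # cap below the merge scale: components stay separate
  d0 <- vr_diagrams(sq, max_dim = 0, max_scale = 0.4)
  expect_equal(sum(is.infinite(d0$death)), 4)
})
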