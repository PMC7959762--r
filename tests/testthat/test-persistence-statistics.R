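test_that("multiset extraction follows the midpoint/lifespan rule", {
  d <- persistence_diagram(1, 3, 5)
  ml <- diagram_to_multisets(d)
  expect_equal(ml$M, 4)
  expect_equal(ml$L, 2)

  # essential point dropped
  d <- persistence_diagram(c(0, 0), c(0, 1), c(Inf, 2))
  ml <- diagram_to_multisets(d)
  expect_equal(ml$M, 1.5)
  expect_equal(ml$L, 1)

  d <- persistence_diagram(c(0, 0), c(1, 2), c(3, 6))
  ml <- diagram_to_multisets(d)
  expect_equal(sort(ml$M), c(2, 4))
  expect_equal(sort(ml$L), c(2, 4))

  empty <- diagram_to_multisets(persistence_diagram())
  expect_length(empty$M, 0)
  expect_length(empty$L, 0)
})

test_that("persistent entropy has its closed-form values and invariances", {
  a <- 0.7
  expect_equal(persistent_entropy(c(a, a)), log(2))
  expect_equal(persistent_entropy(a), 0)
  expect_equal(persistent_entropy(c(1, 3)),
               -(1 / 4) * log(1 / 4) - (3 / 4) * log(3 / 4))
  expect_equal(persistent_entropy(numeric(0)), 0)
  expect_equal(persistent_entropy(c(0, 0)), 0)
  expect_error(persistent_entropy(c(1, -1)), "non-negative")

  withr::with_seed(2, {
    for (trial in 1:20) {
      v <- runif(sample(2:10, 1), 0, 5)
      # scale invariance
      expect_equal(persistent_entropy(3.7 * v), persistent_entropy(v))
      # maximal iff uniform
      expect_lte(persistent_entropy(v), log(length(v)) + 1e-12)
    }
    expect_equal(persistent_entropy(rep(2, 9)), log(9))
  })
})

test_that("the 16 statistics match an independently coded oracle", {
  d <- persistence_diagram(c(0, 0, 0), c(0, 1, 2), c(4, 3, 6))
  got <- persistence_statistics(d)
  expect_length(got, 16)
  ml <- list(M = c(2, 2, 4), L = c(4, 2, 4))
  expect_equal(unname(got), oracle_ps(ml$M, ml$L))

  withr::with_seed(8, {
    for (trial in 1:15) {
      n <- sample(1:12, 1)
      b <- runif(n, -2, 2)
      d <- persistence_diagram(rep(0L, n), b, b + rexp(n))
      ml <- diagram_to_multisets(d)
      expect_equal(unname(persistence_statistics(d)), oracle_ps(ml$M, ml$L),
                   info = paste("trial", trial))
    }
  })
})

test_that("degenerate diagrams yield finite, documented fallbacks", {
  # single finite point
  d <- persistence_diagram(0, 1, 3)
  ps <- persistence_statistics(d)
  expect_equal(unname(ps["M_mean"]), 2)
  expect_equal(unname(ps[c("M_sd", "M_skew", "M_kurt")]), c(0, 0, 0))
  expect_equal(unname(ps[c("M_q25", "M_q50", "M_q75")]), c(2, 2, 2))
  expect_equal(unname(ps["M_entropy"]), 0)
  expect_equal(unname(ps["L_mean"]), 2)

  # empty diagram: all zeros
  expect_equal(unname(persistence_statistics(persistence_diagram())), rep(0, 16))
  # skewness of a symmetric multiset is 0
  d <- persistence_diagram(rep(0, 4), c(0, 1, 3, 4), c(10, 10, 10, 10))
  expect_equal(unname(persistence_statistics(d)["M_skew"]), 0)
  # all outputs always finite
  expect_true(all(is.finite(persistence_statistics(d))))
})

test_that("epoch features have the documented structure and equivariances", {
  withr::with_seed(10, w <- 60 + 5 * sin(seq(0, 12 * pi, length.out = 360)) +
                     rnorm(360, 0, 0.5))
  f <- epoch_features(w)
  expect_length(f, 48)
  expect_identical(names(f)[1:3], c("sl0_M_mean", "sl0_M_sd", "sl0_M_skew"))
  expect_true(all(is.finite(f)))

  # deterministic
  expect_identical(f, epoch_features(w))

  # shifting the window moves only the location statistics of the
  # sub-level block; the Rips blocks are translation invariant
  shift <- 7.5
  f2 <- epoch_features(w + shift)
  vr_cols <- grepl("^vr", names(f))
  expect_equal(f2[vr_cols], f[vr_cols])
  loc <- paste0("sl0_M_", c("mean", "q25", "q50", "q75"))
  expect_equal(unname(f2[loc]), unname(f[loc]) + shift)
  lspread <- paste0("sl0_L_", c("mean", "sd", "q25", "q50", "q75", "entropy"))
  expect_equal(f2[lspread], f[lspread])

  # constant window: sub-level block collapses to the fallback values,
  # Rips dim-0 deaths are all zero
  fc <- epoch_features(rep(0, 360))
  expect_equal(unname(fc[1:16]), rep(0, 16))
  expect_true(all(is.finite(fc)))
  expect_error(epoch_features(rnorm(100)), "shorter")
})

test_that("feature tables round-trip through CSV bit-identically", {
  withr::with_seed(3, {
    feats <- tibble::tibble(
      subject_id = c("s1", "s1", "s2"),
      epoch = 3:5,
      label = c("W", "N", "R")
    )
    m <- matrix(rnorm(3 * 48) * 10^sample(-8:8, 3 * 48, TRUE), nrow = 3)
  })
  colnames(m) <- hrvtda:::feature_names()
  feats <- dplyr::bind_cols(feats, tibble::as_tibble(m))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  back <- read_features(path)
  expect_identical(as.data.frame(back), as.data.frame(feats))
})
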