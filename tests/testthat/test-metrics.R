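test_that("confusion matrices respect the fixed class order", {
  cm <- confusion(rep(c("W", "S"), c(5, 7)), rep(c("W", "S"), c(5, 7)),
                  c("W", "S"))
  expect_equal(unname(cm), rbind(c(5L, 0L), c(0L, 7L)))

  # permuting the input leaves the matrix unchanged
  truth <- rep(c("W", "R", "N"), c(3, 4, 5))
  pred <- sample(rep(c("W", "R", "N"), 4))
  o <- sample(length(truth))
  expect_equal(confusion(truth, pred, c("W", "R", "N")),
               confusion(truth[o], pred[o], c("W", "R", "N")))

  expect_error(confusion("W", c("W", "S"), c("W", "S")), "length")
  expect_error(confusion("W", "X", c("W", "S")), "X")
})

test_that("the all-majority degenerate classifier scores as printed", {
  truth <- rep(c("W", "S"), c(9150, 54547))
  pred <- rep("S", length(truth))
  cm <- confusion(truth, pred, c("W", "S"))
  expect_equal(unname(cm), rbind(c(0L, 9150L), c(0L, 54547L)))
  met <- classification_metrics(cm)
  expect_equal(met$overall$acc, 54547 / (9150 + 54547))
  expect_equal(met$overall$acc, 0.85, tolerance = 0.01)
  expect_equal(met$by_class$se[met$by_class$class == "W"], 0)
  expect_true(met$by_class$degenerate[met$by_class$class == "W"])
})

test_that("metric arithmetic matches hand computation including kappa", {
  cm <- matrix(c(3L, 2L, 1L, 4L), 2, 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  # rows true: [[3, 1], [2, 4]]
  cm <- rbind(c(3L, 1L), c(2L, 4L))
  dimnames(cm) <- list(true = c("a", "b"), predicted = c("a", "b"))
  met <- classification_metrics(cm)
  expect_equal(met$by_class$se, c(3 / 4, 4 / 6))
  expect_equal(met$by_class$ppv, c(3 / 5, 4 / 5))
  expect_equal(met$overall$acc, 0.7)
  ea <- (4 * 5 + 6 * 5) / 100 # independently: marginal products / n^2
  expect_equal(met$overall$ea, ea)
  expect_equal(met$overall$kappa, (0.7 - ea) / (1 - ea))
  f1a <- 2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4)
  expect_equal(met$by_class$f1[1], f1a)
})

test_that("kappa is 1 for perfect prediction and near 0 under independence", {
  y <- rep(c("W", "R", "N"), c(10, 12, 8))
  met <- classification_metrics(confusion(y, y, c("W", "R", "N")))
  expect_equal(met$overall$acc, 1)
  expect_equal(met$overall$kappa, 1)
  expect_true(all(met$by_class$se == 1))

  withr::with_seed(19, {
    truth <- sample(c("W", "S"), 4000, replace = TRUE)
    pred <- sample(c("W", "S"), 4000, replace = TRUE, prob = c(0.3, 0.7))
    k <- classification_metrics(confusion(truth, pred, c("W", "S")))$overall$kappa
    expect_lt(abs(k), 0.05)
  })
})

test_that("per-subject reports average within subjects first", {
  pred <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 6),
    label = rep(c("W", "W", "W", "S", "S", "S"), 2),
    predicted = c("W", "W", "S", "S", "S", "S",  # s1: se_W = 2/3
                  "W", "S", "S", "S", "S", "W")  # s2: se_W = 1/3
  )
  rep_ <- per_subject_report(pred, c("W", "S"))
  sw <- rep_$summary[rep_$summary$metric == "se_W", ]
  expect_equal(sw$mean, mean(c(2 / 3, 1 / 3)))
  expect_equal(sw$sd, sd(c(2 / 3, 1 / 3)))

  # two identical subjects: zero dispersion
  pred2 <- pred
  pred2$predicted <- rep(c("W", "W", "S", "S", "S", "S"), 2)
  rep2 <- per_subject_report(pred2, c("W", "S"))
  expect_true(all(rep2$summary$sd == 0))

  # single subject: mean is the subject value, sd reported as 0
  rep1 <- per_subject_report(pred[pred$subject_id == "s1", ], c("W", "S"))
  expect_equal(rep1$summary$sd, rep(0, nrow(rep1$summary)))

  # pooled and averaged accuracy differ with unequal subject sizes
  pred3 <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", label = rep(c("W", "S"), c(1, 1)),
                   predicted = c("W", "S")),
    tibble::tibble(subject_id = "b", label = rep(c("W", "S"), c(4, 4)),
                   predicted = c("W", "W", "S", "S", "S", "S", "S", "S"))
  )
  rep3 <- per_subject_report(pred3, c("W", "S"))
  pooled_acc <- rep3$pooled$overall$acc
  avg_acc <- rep3$summary$mean[rep3$summary$metric == "acc"]
  expect_false(isTRUE(all.equal(pooled_acc, avg_acc)))

  # a subject missing a class is skipped for that rate, with a warning
  pred4 <- dplyr::bind_rows(
    pred[pred$subject_id == "s1", ],
    tibble::tibble(subject_id = "s3", label = rep("S", 4),
                   predicted = rep("S", 4))
  )
  expect_warning(rep4 <- per_subject_report(pred4, c("W", "S")), "degenerate")
  expect_equal(rep4$summary$mean[rep4$summary$metric == "se_W"], 2 / 3)
})

test_that("AUC behaves as a rank statistic", {
  truth <- rep(c("W", "S"), each = 5)
  expect_equal(auc_score(truth, c(6:10, 1:5), positive = "W"), 1)
  expect_equal(auc_score(truth, c(1:5, 6:10), positive = "W"), 0)
  withr::with_seed(23, {
    truth <- sample(c("W", "S"), 2000, replace = TRUE)
    score <- rnorm(2000)
    a <- auc_score(truth, score, positive = "W")
    expect_lt(abs(a - 0.5), 0.05)
    # label inversion flips the AUC
    expect_equal(auc_score(truth, score, positive = "S"), 1 - a)
  })
  expect_true(is.na(auc_score(rep("W", 3), 1:3, positive = "W")))
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    truth <- sample(c("W", "S"), 300, replace = TRUE)
    score <- rnorm(300) + (truth == "W")
  })
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("S", "W"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(auc_score(truth, score, positive = "W"), ref)
})

test_that("rank-sum screening controls the null and finds planted shifts", {
  withr::with_seed(31, {
    null_feats <- tibble::tibble(
      subject_id = rep(c("a", "b"), each = 100),
      epoch = 1:200,
      label = rep(rep(c("W", "S"), each = 50), 2),
      f1 = rnorm(200), f2 = rnorm(200), f3 = rnorm(200), f4 = rnorm(200)
    )
    scr <- feature_screening(null_feats)
    expect_false(any(scr$reject))
    expect_equal(attr(scr, "family_size"), 4)

    shifted <- null_feats
    shifted$f2 <- shifted$f2 + 3 * (shifted$label == "W")
    scr2 <- feature_screening(shifted)
    expect_true(scr2$reject[scr2$feature == "f2"])
    expect_false(any(scr2$reject[scr2$feature != "f2"]))
  })
  expect_error(feature_screening(null_feats[null_feats$label == "W", ]),
               "2 groups")
})

test_that("per-subject z-scores center and scale within subject", {
  withr::with_seed(37, {
    feats <- tibble::tibble(
      subject_id = rep(c("a", "b"), each = 30),
      epoch = 1:60, label = "W",
      f1 = c(rnorm(30, 10, 2), rnorm(30, -5, 7)),
      f2 = c(rnorm(30), rep(1, 30)) # constant within subject b
    )
  })
  expect_message(z <- zscore_by_subject(feats), "constant")
  for (s in c("a", "b")) {
    expect_equal(mean(z$f1[z$subject_id == s]), 0)
    expect_equal(sd(z$f1[z$subject_id == s]), 1)
  }
  expect_equal(z$f2[z$subject_id == "b"], rep(0, 30))
})
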