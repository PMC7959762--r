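classification_tasks <- function() {
  list(
    ws  = list(classes = c("W", "S"),      relabel = c(W = "W", R = "S", N = "S")),
    rn  = list(classes = c("R", "N"),      relabel = c(R = "R", N = "N")),
    wrn = list(classes = c("W", "R", "N"), relabel = c(W = "W", R = "R", N = "N"))
  )
}

#' Map raw sleep-stage labels to a classification task
#'
#' Tasks: `"ws"` wake vs sleep (REM and NREM merged into `"S"`),
#' `"rn"` REM vs NREM (wake epochs dropped — the task is posed within
#' sleep), `"wrn"` three-class wake/REM/NREM.  Class order follows the
#' reporting convention: wake, then REM, then NREM (or W, S / R, N).
#'
#' @param features feature tibble with a `label` column in
#'   \{"W", "R", "N"\}.
#' @param task `"ws"`, `"rn"` or `"wrn"`.
#' @return The tibble filtered to the task's epochs with `label`
#'   recoded to the task's classes.
#' @export
task_labels <- function(features, task = c("ws", "rn", "wrn")) {
  task <- match.arg(task)
  spec <- classification_tasks()[[task]]
  out <- features[features$label %in% names(spec$relabel), ]
  out$label <- unname(spec$relabel[out$label])
  out
}

#' Balance classes by down-sampling the majority
#'
#' Keeps every epoch of the smallest class and randomly selects the same
#' number, without replacement, from each larger class, so the training
#' set seen by the classifier is exactly balanced.  (Evaluation uses the
#' full test set; only training rows are ever balanced.)  The selection
#' is driven entirely by `seed`, so a fixed seed reproduces the subset.
#'
#' @param features labeled feature tibble.
#' @param seed integer seed for the subsampling draw (default 1).
#' @return The balanced tibble (class counts all equal to the minority
#'   count).
#' @export
balance_downsample <- function(features, seed = 1L) {
  counts <- table(features$label)
  if (any(counts == 0) || length(counts) < 2) {
    abort("every class must be non-empty to balance")
  }
  target <- min(counts)
  withr::with_seed(seed, {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(features$label == cl)
      if (length(idx) > target) sample(idx, target) else idx
    }))
  })
  features[sort(keep), ]
}

#' Train the linear-SVM sleep-stage classifier
#'
#' Fits a linear-kernel support vector machine on the 48 persistence
#' statistics (cost 1, no internal standardization).  With three
#' classes the fit is the one-versus-one construction: one binary
#' linear SVM per class pair, combined by voting.  Training data should
#' be balanced first (see [balance_downsample()]); a warning is issued
#' otherwise.
#'
#' @param features labeled feature tibble (metadata columns
#'   `subject_id`, `epoch`, `label` plus feature columns).
#' @param task classification task (see [task_labels()]); labels must
#'   already be the task's classes.
#' @param cost SVM regularization constant (default 1).
#' @param standardize z-score the features inside the model?  Default
#'   `FALSE`.
#' @return A `sleep_svm` model object.
#' @export
train_sleep_svm <- function(features, task = c("ws", "rn", "wrn"),
                            cost = 1, standardize = FALSE) {
  task <- match.arg(task)
  classes <- classification_tasks()[[task]]$classes
  present <- unique(features$label)
  if (length(present) < 2) abort("training data has a single class")
  if (!all(present %in% classes)) {
    abort(sprintf("labels %s do not belong to task '%s'",
                  paste(setdiff(present, classes), collapse = ", "), task))
  }
  counts <- table(features$label)
  if (length(unique(counts)) > 1) {
    warn("training classes are not balanced; see balance_downsample()")
  }
  x <- feature_matrix(features)
  y <- factor(features$label, levels = classes)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                    scale = standardize, probability = FALSE)
  structure(
    list(fit = fit, task = task, classes = classes,
         feature_names = colnames(x), cost = cost,
         standardize = standardize, n_train = nrow(x),
         class_counts = as.list(counts)),
    class = "sleep_svm"
  )
}

feature_matrix <- function(features) {
  meta <- c("subject_id", "epoch", "label", "end_time")
  x <- as.matrix(features[setdiff(names(features), meta)])
  if (!is.numeric(x)) abort("non-numeric feature columns")
  x
}

#' Predict sleep stages
#'
#' One predicted label per row of `features`; for two-class tasks the
#' signed distance to the separating hyperplane is returned alongside
#' (the score used for ROC/AUC).
#'
#' @param object a `sleep_svm` model.
#' @param features feature tibble with the same feature columns the
#'   model was trained on.
#' @param ... unused.
#' @return Tibble: the metadata columns of `features` plus `predicted`
#'   and (two-class tasks) `score`.
#' @export
predict.sleep_svm <- function(object, features, ...) {
  x <- feature_matrix(features)
  if (!identical(colnames(x), object$feature_names)) {
    abort("feature columns do not match the training features")
  }
  pred <- predict(object$fit, x, decision.values = TRUE)
  out <- dplyr::bind_cols(
    features[intersect(c("subject_id", "epoch", "label"), names(features))],
    tibble(predicted = as.character(pred))
  )
  if (length(object$classes) == 2) {
    dv <- attr(pred, "decision.values")
    # e1071 orients the decision value toward the first factor level
    sgn <- if (grepl(paste0("^", object$classes[1], "/"), colnames(dv)[1])) 1 else -1
    out$score <- sgn * as.numeric(dv[, 1])
  }
  out
}

#' @export
print.sleep_svm <- function(x, ...) {
  cat(sprintf(
    "Linear SVM sleep-stage model (task '%s', classes %s)\n  %d training epochs, cost %g%s\n",
    x$task, paste(x$classes, collapse = "/"), x$n_train, x$cost,
    if (length(x$classes) > 2) ", one-vs-one" else ""
  ))
  invisible(x)
}

#' @describeIn train_sleep_svm one row per binary decision boundary
#'   (one-vs-one pair): its class pair and intercept; for a two-class
#'   model also the hyperplane weight norm.
#' @param x,object a `sleep_svm` model.
#' @param ... unused.
#' @export
tidy.sleep_svm <- function(x, ...) {
  fit <- x$fit
  pairs <- utils::combn(x$classes, 2, paste, collapse = "/")
  out <- tibble(comparison = pairs, intercept = -fit$rho)
  if (length(x$classes) == 2) {
    w <- t(fit$coefs[, 1]) %*% fit$SV
    out$weight_norm <- sqrt(sum(w^2))
  }
  out
}

#' @describeIn train_sleep_svm one-row model summary (task, classes,
#'   training size, support-vector count).
#' @export
glance.sleep_svm <- function(x, ...) {
  tibble(task = x$task, n_classes = length(x$classes),
         n_train = x$n_train, n_support = x$fit$tot.nSV,
         cost = x$cost, standardized = x$standardize)
}
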