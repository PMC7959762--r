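#' Confusion matrix in a fixed class order
#'
#' Counts of (true class k, predicted class l) pairs, rows true and
#' columns predicted, in the reporting order wake, REM, NREM (or the
#' task's two classes).
#'
#' @param truth,predicted character vectors of equal length.
#' @param class_order character vector fixing the row/column order;
#'   every label present must belong to it.
#' @return An m x m integer matrix with dimnames
#'   `list(true = ..., predicted = ...)`.
#' @examples
#' confusion(c("W", "W", "S"), c("W", "S", "S"), c("W", "S"))
#' @export
confusion <- function(truth, predicted, class_order) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length")
  }
  unknown <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(unknown)) {
    abort(sprintf("labels not in `class_order`: %s",
                  paste(unknown, collapse = ", ")))
  }
  tf <- factor(truth, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  tab <- table(true = tf, predicted = pf)
  matrix(as.integer(tab), nrow = length(class_order),
         dimnames = list(true = class_order, predicted = class_order))
}

#' Classification metrics from a confusion matrix
#'
#' Per class k: sensitivity SE_k = M_kk / (row k sum), positive
#' predictivity +P_k = M_kk / (column k sum), and their harmonic mean
#' F1_k.  Overall: accuracy Acc = trace / total, the expected accuracy
#' EA = sum_p (row_p sum x column_p sum) / total^2 of a chance
#' classifier with the same marginals, and Cohen's kappa
#' (Acc - EA)/(1 - EA).  A class never observed or never predicted has
#' an undefined 0/0 rate; it is reported as 0 (with `degenerate = TRUE`
#' on that row), consistent with reading "no wake epoch recovered" as
#' zero sensitivity.
#'
#' @param cm confusion matrix from [confusion()].
#' @return A list with `by_class` (tibble: class, se, ppv, f1,
#'   degenerate) and `overall` (tibble: acc, ea, kappa, n).
#' @examples
#' cm <- confusion(rep(c("W", "S"), c(3, 7)),
#'                 rep("S", 10), c("W", "S"))
#' classification_metrics(cm)$overall
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  rows <- rowSums(cm)
  cols <- colSums(cm)
  diagv <- diag(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  se <- safe_div(diagv, rows)
  ppv <- safe_div(diagv, cols)
  f1 <- safe_div(2 * ppv * se, ppv + se)
  acc <- sum(diagv) / total
  ea <- sum(rows * cols) / total^2
  kappa <- if (ea < 1) (acc - ea) / (1 - ea) else 0
  list(
    by_class = tibble(
      class = rownames(cm), se = unname(se), ppv = unname(ppv),
      f1 = unname(f1), degenerate = unname(rows == 0 | cols == 0)
    ),
    overall = tibble(acc = acc, ea = ea, kappa = kappa, n = total)
  )
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random positive scores higher
#' than a random negative, with ties counted half (the Mann-Whitney
#' statistic).
#'
#' @param truth character or logical vector; `positive` names the
#'   positive class.
#' @param score numeric classifier scores, larger = more positive.
#' @param positive the positive class label (default the first class in
#'   `truth`'s sorted unique values is NOT assumed — pass it
#'   explicitly; for logical `truth`, `TRUE`).
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_score <- function(truth, score, positive = TRUE) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-subject evaluation report
#'
#' Computes the metric suite within every subject, then reports the
#' across-subject mean and sample standard deviation of each metric —
#' the convention for subject-level physiological studies — together
#' with the pooled (all-epochs) metrics.  Per-class rates that are
#' degenerate for a subject (class absent in truth or prediction) are
#' skipped in that subject's average, with a warning.  For two-class
#' tasks with a `score` column, per-subject AUC is included.
#'
#' @param predictions tibble from [predict.sleep_svm()] with columns
#'   `subject_id`, `label`, `predicted` and optionally `score`.
#' @param class_order fixed class order (first class is the AUC
#'   positive).
#' @return A list: `per_subject` (one row per subject and metric set),
#'   `summary` (mean and sd across subjects per metric), `pooled`
#'   (epochs pooled over subjects), `confusion` (pooled matrix).
#' @export
per_subject_report <- function(predictions, class_order) {
  stopifnot(all(c("subject_id", "label", "predicted") %in% names(predictions)))
  has_score <- "score" %in% names(predictions) && length(class_order) == 2

  one_subject <- function(df) {
    cm <- confusion(df$label, df$predicted, class_order)
    met <- classification_metrics(cm)
    row <- tibble(n = sum(cm), acc = met$overall$acc,
                  kappa = met$overall$kappa)
    for (i in seq_along(class_order)) {
      cl <- class_order[i]
      deg <- met$by_class$degenerate[i]
      row[[paste0("se_", cl)]] <- if (deg) NA_real_ else met$by_class$se[i]
      row[[paste0("ppv_", cl)]] <- if (deg) NA_real_ else met$by_class$ppv[i]
      row[[paste0("f1_", cl)]] <- if (deg) NA_real_ else met$by_class$f1[i]
    }
    if (has_score) {
      row$auc <- auc_score(df$label, df$score, positive = class_order[1])
    }
    row
  }

  per_subject <- predictions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ one_subject(.x)) |>
    dplyr::ungroup()
  if (anyNA(per_subject)) {
    warn("some per-subject class metrics were degenerate and skipped")
  }

  metric_cols <- setdiff(names(per_subject), c("subject_id", "n"))
  summary <- tibble(
    metric = metric_cols,
    mean = unname(vapply(per_subject[metric_cols],
                         function(x) mean(x, na.rm = TRUE), numeric(1))),
    sd = unname(vapply(per_subject[metric_cols], function(x) {
      if (sum(!is.na(x)) < 2) 0 else sd(x, na.rm = TRUE)
    }, numeric(1)))
  )

  cm <- confusion(predictions$label, predictions$predicted, class_order)
  pooled <- classification_metrics(cm)
  if (has_score) {
    pooled$overall$auc <- auc_score(predictions$label, predictions$score,
                                    positive = class_order[1])
  }
  list(per_subject = per_subject, summary = summary,
       pooled = pooled, confusion = cm)
}

#' Rank-sum screening of features between two groups
#'
#' For each feature: z-score the values within every subject (so
#' between-subject baseline differences do not masquerade as class
#' differences), then test the two groups with the Wilcoxon rank-sum
#' test for equal medians, Bonferroni-corrected over the features
#' actually tested at family-wise level `alpha`.  A feature constant
#' within a subject gets a zero z-score there (logged as a message).
#'
#' @param features labeled feature tibble (metadata `subject_id`,
#'   `epoch`, `label`).
#' @param alpha family-wise significance level (default 0.05).
#' @return Tibble: `feature`, `p_value`, `p_bonferroni`, `reject`,
#'   ordered as the feature columns; attribute `family_size` records
#'   the Bonferroni family.
#' @export
feature_screening <- function(features, alpha = 0.05) {
  groups <- unique(features$label)
  if (length(groups) != 2) abort("feature screening compares exactly 2 groups")
  meta <- c("subject_id", "epoch", "label", "end_time")
  fcols <- setdiff(names(features), meta)
  z <- zscore_by_subject(features, fcols)
  g1 <- z$label == groups[1]
  p <- vapply(fcols, function(f) {
    wilcox.test(z[[f]][g1], z[[f]][!g1], exact = FALSE)$p.value
  }, numeric(1))
  padj <- p.adjust(p, method = "bonferroni")
  out <- tibble(feature = fcols, p_value = unname(p),
                p_bonferroni = unname(padj),
                reject = unname(padj < alpha))
  attr(out, "family_size") <- length(fcols)
  out
}

#' Per-subject z-score normalization
#'
#' Centers and scales every feature within each subject.  Used before
#' group comparisons so that inter-individual level differences do not
#' drive the statistics.
#'
#' @param features labeled feature tibble.
#' @param cols feature columns to normalize (default: all non-metadata).
#' @return The tibble with the chosen columns replaced by within-subject
#'   z-scores (a subject-constant feature becomes all zeros there).
#' @export
zscore_by_subject <- function(features, cols = NULL) {
  meta <- c("subject_id", "epoch", "label", "end_time")
  if (is.null(cols)) cols <- setdiff(names(features), meta)
  constant_seen <- FALSE
  out <- features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cols), function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) {
        constant_seen <<- TRUE
        rep(0, length(x))
      } else {
        (x - mean(x)) / s
      }
    })) |>
    dplyr::ungroup()
  if (constant_seen) {
    rlang::inform("some features were constant within a subject; z-scores set to 0")
  }
  out
}
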