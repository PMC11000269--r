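# Paired diagnostic-efficiency statistics: confusion tables, sensitivity /
# specificity / predictive values with confidence intervals, empirical ROC
# curves, Bland-Altman limits of agreement.

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,fn,tn cell counts (test vs reference standard).
#' @param condition the condition being called, e.g. `"PSVC"`.
#' @return an object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn, condition = NA_character_) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("confusion_table: cells must be >= 0")
  if (sum(cells) == 0) stop("confusion_table: all cells are zero")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, condition = condition),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table%s (reference standard in columns):\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Tally a confusion table from paired per-patient calls
#'
#' The long-window (24 h) calls are the reference standard; the short-window
#' (2 h) calls are the test under evaluation. Both inputs are data frames
#' with columns `patient_id`, `condition`, `call` (`"positive"`/`"negative"`).
#'
#' `exclude_dual_positive = TRUE` drops patients whose reference calls are
#' positive for *both* conditions before tallying, which matches reporting
#' conventions that evaluate each condition on its single-condition group
#' plus all reference-negative patients.
#'
#' @param gold reference-standard calls (24 h).
#' @param test test calls (2 h).
#' @param condition `"PSVC"` or `"PVC"`.
#' @param exclude_dual_positive see Details.
#' @return a [confusion_table()].
#' @export
confusion_from_paired_calls <- function(gold, test, condition,
                                        exclude_dual_positive = FALSE) {
  need <- c("patient_id", "condition", "call")
  stopifnot(all(need %in% names(gold)), all(need %in% names(test)))
  gp <- sort(unique(gold$patient_id)); tp_ids <- sort(unique(test$patient_id))
  if (!identical(gp, tp_ids)) {
    only_g <- setdiff(gp, tp_ids); only_t <- setdiff(tp_ids, gp)
    stop("confusion_from_paired_calls: patient sets differ; only in gold: {",
         paste(only_g, collapse = ", "), "}; only in test: {",
         paste(only_t, collapse = ", "), "}")
  }
  pos_ids <- function(calls, cond) {
    unique(calls$patient_id[calls$condition == cond & calls$call == "positive"])
  }
  ids <- gp
  if (exclude_dual_positive) {
    dual <- intersect(pos_ids(gold, "PSVC"), pos_ids(gold, "PVC"))
    ids <- setdiff(ids, dual)
  }
  gold_pos <- intersect(ids, pos_ids(gold, condition))
  test_pos <- intersect(ids, pos_ids(test, condition))
  tp <- length(intersect(gold_pos, test_pos))
  fn <- length(setdiff(gold_pos, test_pos))
  fp <- length(setdiff(test_pos, gold_pos))
  tn <- length(ids) - tp - fn - fp
  confusion_table(tp = tp, fp = fp, fn = fn, tn = tn, condition = condition)
}

prop_ci <- function(k, n, conf_level, method) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half; hi <- p + half
  } else {  # wilson
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- ctr - half; hi <- ctr + half
  }
  c(max(0, lo), min(1, hi)) * 100
}

#' Diagnostic-efficiency metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, each as a percentage rounded to two
#' decimals (half away from zero) with a 95% confidence interval (Wald by
#' default, Wilson available), clipped to `[0, 100]`. A metric whose
#' denominator is zero is reported `NA` with a warning.
#'
#' @param ct a [confusion_table()].
#' @param conf_level confidence level for the intervals.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return an object of class `diagnostic_summary`: data frame with one row
#'   per metric (`estimate`, `lower`, `upper` in percent) plus attributes
#'   `condition` and `n`.
#' @export
diagnostic_metrics <- function(ct, conf_level = 0.95,
                               ci_method = c("wald", "wilson")) {
  stopifnot(inherits(ct, "confusion_table"))
  ci_method <- match.arg(ci_method)
  num <- c(sensitivity = ct$tp, specificity = ct$tn, ppv = ct$tp, npv = ct$tn)
  den <- c(sensitivity = ct$tp + ct$fn, specificity = ct$tn + ct$fp,
           ppv = ct$tp + ct$fp, npv = ct$tn + ct$fn)
  est <- lower <- upper <- rep(NA_real_, 4)
  for (i in seq_len(4)) {
    if (den[i] == 0) {
      warning(sprintf("diagnostic_metrics: %s undefined (zero denominator)", names(den)[i]))
      next
    }
    est[i] <- round_half_away(100 * num[i] / den[i], 2)
    ci <- prop_ci(num[i], den[i], conf_level, ci_method)
    lower[i] <- min(ci[1], est[i]); upper[i] <- max(ci[2], est[i])
  }
  out <- data.frame(metric = names(den), estimate = est,
                    lower = lower, upper = upper, numerator = unname(num),
                    denominator = unname(den), stringsAsFactors = FALSE)
  structure(out, class = c("diagnostic_summary", "data.frame"),
            condition = ct$condition, n = ct$tp + ct$fp + ct$fn + ct$tn,
            conf_level = conf_level, ci_method = ci_method)
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("Diagnostic value%s (n = %d, %s %g%% CI):\n",
              if (is.na(cond)) "" else paste0(" [", cond, "]"),
              attr(x, "n"), attr(x, "ci_method"), 100 * attr(x, "conf_level")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %6.2f%% (%5.2f-%6.2f)  [%d/%d]\n", x$metric[i],
                x$estimate[i], x$lower[i], x$upper[i],
                x$numerator[i], x$denominator[i]))
  }
  invisible(x)
}

#' Detection rate as a percentage
#'
#' @param detected number of patients detected.
#' @param group_n group size (> 0).
#' @return `100 * detected / group_n`, rounded half away from zero to one
#'   decimal.
#' @export
detection_rate <- function(detected, group_n) {
  if (any(group_n <= 0)) stop("detection_rate: group_n must be > 0")
  if (any(detected < 0 | detected > group_n)) {
    stop("detection_rate: need 0 <= detected <= group_n")
  }
  round_half_away(100 * detected / group_n, 1)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct score value as a `score >= threshold` positivity
#' rule, traces the empirical ROC through (0,0) and (1,1), and computes the
#' area by the trapezoid rule — which equals the pairwise concordance
#' probability (ties counted 1/2). The AUC confidence interval uses the
#' Hanley-McNeil standard error.
#'
#' @param scores numeric predictor per patient (higher = more positive).
#' @param gold logical (or `"positive"`/`"negative"`) reference calls.
#' @param conf_level confidence level for the AUC interval.
#' @return an object of class `roc_result`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, gold, conf_level = 0.95) {
  if (is.character(gold) || is.factor(gold)) gold <- as.character(gold) == "positive"
  gold <- as.logical(gold)
  stopifnot(length(scores) == length(gold), !anyNA(scores), !anyNA(gold))
  n_pos <- sum(gold); n_neg <- sum(!gold)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve: need at least one positive and one negative reference call")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[gold] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!gold] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  # Hanley-McNeil SE
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  structure(list(points = pts, auc = auc, auc_ci = ci, se = se,
                 n_pos = n_pos, n_neg = n_neg, conf_level = conf_level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC %.3f (%g%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as `first - second`; the limits of agreement are
#' `mean(diff) +/- 1.96 sd(diff)` with the n-1 sd denominator.
#'
#' @param first,second paired measurements (e.g. 24 h and 2 h event rates
#'   per hour).
#' @param z multiplier for the limits (1.96 for 95% limits).
#' @return an object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, plus the per-pair `means` and `diffs`.
#' @export
bland_altman <- function(first, second, z = 1.96) {
  stopifnot(length(first) == length(second))
  if (length(first) < 3) stop("bland_altman: need at least 3 pairs")
  d <- first - second
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - z * s, loa_high = m + z * s, z = z,
                 n = length(d), means = (first + second) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.3f, SD %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 16, cex = 0.6,
                 xlab = "mean of pair", ylab = "difference (first - second)", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2), col = c("firebrick", "black", "firebrick"))
  invisible(x)
}

#' Evaluate a paired-window cohort end to end
#'
#' Takes per-patient paired counts (as from [simulate_cohort()]), calls
#' positivity for both windows and both conditions, and computes for each
#' condition: the confusion table (24 h reference), diagnostic metrics,
#' an ROC curve using the short-window count as the continuous predictor,
#' and Bland-Altman agreement between the two windows on the events/hour
#' scale (24 h count / 24 vs 2 h count / 2).
#'
#' @param cohort data frame with columns `patient_id`, `psvc_count_2h`,
#'   `pvc_count_2h`, `psvc_count_24h`, `pvc_count_24h`.
#' @param criteria a [positivity_criteria()].
#' @param window_short,window_long window lengths in hours (defaults read
#'   from the cohort attributes when present).
#' @return an object of class `cohort_evaluation`: per-condition list with
#'   `confusion`, `metrics`, `roc`, `bland_altman`, plus `calls` (the
#'   per-patient call table).
#' @export
evaluate_cohort <- function(cohort, criteria = positivity_criteria(),
                            window_short = NULL, window_long = NULL) {
  if (is.null(window_short)) window_short <- attr(cohort, "window_short") %||% 2
  if (is.null(window_long)) window_long <- attr(cohort, "window_long") %||% 24
  need <- c("patient_id", "psvc_count_2h", "pvc_count_2h",
            "psvc_count_24h", "pvc_count_24h")
  stopifnot(all(need %in% names(cohort)))
  calls <- data.frame(
    patient_id = cohort$patient_id,
    psvc_call_2h = call_positivity(cohort$psvc_count_2h, window_short, criteria),
    pvc_call_2h = call_positivity(cohort$pvc_count_2h, window_short, criteria),
    psvc_call_24h = call_positivity(cohort$psvc_count_24h, window_long, criteria),
    pvc_call_24h = call_positivity(cohort$pvc_count_24h, window_long, criteria),
    stringsAsFactors = FALSE)
  long_fmt <- function(df, cols, window) {
    do.call(rbind, lapply(names(cols), function(cond) {
      data.frame(patient_id = df$patient_id, condition = cond,
                 call = df[[cols[[cond]]]], stringsAsFactors = FALSE)
    }))
  }
  gold <- long_fmt(calls, c(PSVC = "psvc_call_24h", PVC = "pvc_call_24h"))
  test <- long_fmt(calls, c(PSVC = "psvc_call_2h", PVC = "pvc_call_2h"))
  per_condition <- lapply(c(PSVC = "PSVC", PVC = "PVC"), function(cond) {
    ct <- confusion_from_paired_calls(gold, test, cond)
    cnt2 <- cohort[[if (cond == "PSVC") "psvc_count_2h" else "pvc_count_2h"]]
    cnt24 <- cohort[[if (cond == "PSVC") "psvc_count_24h" else "pvc_count_24h"]]
    gold_call <- calls[[if (cond == "PSVC") "psvc_call_24h" else "pvc_call_24h"]]
    roc <- if (length(unique(gold_call)) == 2) {
      roc_curve(cnt2, gold_call)
    } else NULL
    list(confusion = ct,
         metrics = diagnostic_metrics(ct),
         roc = roc,
         bland_altman = bland_altman(cnt24 / window_long, cnt2 / window_short))
  })
  structure(list(PSVC = per_condition$PSVC, PVC = per_condition$PVC,
                 calls = calls, window_short = window_short,
                 window_long = window_long, n = nrow(cohort)),
            class = "cohort_evaluation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("Paired-window cohort evaluation: n = %d patients, %g h test vs %g h reference\n\n",
              x$n, x$window_short, x$window_long))
  for (cond in c("PSVC", "PVC")) {
    print(x[[cond]]$confusion)
    print(x[[cond]]$metrics)
    if (!is.null(x[[cond]]$roc)) print(x[[cond]]$roc)
    print(x[[cond]]$bland_altman)
    cat("\n")
  }
  invisible(x)
}

#' Serialise a cohort evaluation to JSON
#'
#' @param x a [evaluate_cohort()] result.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
cohort_evaluation_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort_evaluation"))
  as_list <- function(cond) {
    ct <- x[[cond]]$confusion
    mt <- x[[cond]]$metrics
    out <- list(confusion = list(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn),
                metrics = stats::setNames(
                  lapply(seq_len(nrow(mt)), function(i) {
                    list(estimate = mt$estimate[i], lower = mt$lower[i],
                         upper = mt$upper[i])
                  }), mt$metric),
                bland_altman = x[[cond]]$bland_altman[
                  c("mean_diff", "sd_diff", "loa_low", "loa_high", "n")])
    if (!is.null(x[[cond]]$roc)) {
      out$auc <- x[[cond]]$roc$auc
      out$auc_ci <- x[[cond]]$roc$auc_ci
    }
    out
  }
  obj <- list(n = x$n, window_short = x$window_short, window_long = x$window_long,
              PSVC = as_list("PSVC"), PVC = as_list("PVC"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
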