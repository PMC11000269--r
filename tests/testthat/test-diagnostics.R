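# Diagnostic-efficiency statistics: confusion tables, metrics, ROC,
# Bland-Altman, cohort evaluation.

test_that("paired calls tally into the expected confusion cells", {
  mk <- function(ids, pos) {
    data.frame(patient_id = ids, condition = "PVC",
               call = ifelse(ids %in% pos, "positive", "negative"))
  }
  ids <- sprintf("p%02d", 1:10)
  gold <- mk(ids, ids[1:4])
  ct <- confusion_from_paired_calls(gold, gold, "PVC")
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(4, 0, 0, 6))
  test <- mk(ids, ids[c(1, 2, 3, 5)])
  ct2 <- confusion_from_paired_calls(gold, test, "PVC")
  expect_equal(c(ct2$tp, ct2$fp, ct2$fn, ct2$tn), c(3, 1, 1, 5))
  expect_error(confusion_from_paired_calls(gold, mk(sprintf("q%02d", 1:10), NULL), "PVC"),
               "patient sets differ")
})

test_that("metric formulas and rounding match hand-computed percentages", {
  ct <- confusion_table(tp = 5, fp = 0, fn = 0, tn = 7)
  dm <- diagnostic_metrics(ct)
  expect_equal(dm$estimate, rep(100, 4))
  expect_true(all(dm$lower <= dm$estimate & dm$estimate <= dm$upper))
  ct2 <- confusion_table(tp = 1, fp = 2, fn = 1, tn = 2)
  dm2 <- diagnostic_metrics(ct2)
  expect_equal(dm2$estimate[dm2$metric == "sensitivity"], 50)
  expect_equal(dm2$estimate[dm2$metric == "ppv"], 33.33)
  expect_error(confusion_table(0, 0, 0, 0), "zero")
  # zero denominators (no reference positives) -> NA with warnings for both
  # affected metrics
  w <- capture_warnings(dm3 <- diagnostic_metrics(confusion_table(0, 0, 0, 5)))
  expect_length(w, 2)
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(dm3$estimate[dm3$metric == "sensitivity"]))
  expect_true(is.na(dm3$estimate[dm3$metric == "ppv"]))
})

test_that("ppv from cells equals ppv from Bayes' rule across random tables", {
  set.seed(5)
  for (i in 1:200) {
    cells <- rmultinom(1, size = sample(20:500, 1), prob = runif(4, 0.05, 1))
    tp <- cells[1] + 1; fp <- cells[2] + 1; fn <- cells[3] + 1; tn <- cells[4] + 1
    dm <- diagnostic_metrics(confusion_table(tp, fp, fn, tn))
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    prev <- (tp + fn) / (tp + fp + fn + tn)
    bayes_ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
    expect_equal(tp / (tp + fp), bayes_ppv, tolerance = 1e-12)
    expect_true(all(dm$estimate >= 0 & dm$estimate <= 100))
    expect_true(all(dm$lower >= 0 & dm$upper <= 100))
  }
})

test_that("wilson intervals are available and differ from wald on small tables", {
  ct <- confusion_table(tp = 19, fp = 6, fn = 5, tn = 132)
  wald <- diagnostic_metrics(ct, ci_method = "wald")
  wil <- diagnostic_metrics(ct, ci_method = "wilson")
  expect_equal(wald$estimate, wil$estimate)
  expect_false(isTRUE(all.equal(wald$lower, wil$lower)))
  expect_true(all(wil$lower <= wil$estimate & wil$estimate <= wil$upper))
})

test_that("detection rates round half away from zero to one decimal", {
  expect_equal(detection_rate(4, 24), 16.7)
  expect_equal(detection_rate(6, 23), 26.1)
  expect_equal(detection_rate(5, 8), 62.5)
  expect_equal(detection_rate(8, 8), 100.0)
  expect_equal(detection_rate(0, 24), 0.0)
  expect_equal(detection_rate(1, 16), 6.3)     # 6.25 rounds away from zero
  expect_error(detection_rate(5, 0), "group_n")
  expect_error(detection_rate(9, 8), "detected")
})

test_that("trapezoid AUC equals the pairwise concordance oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    gold <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- if (i %% 2) rnorm(n) else sample(0:5, n, replace = TRUE)  # force ties
    roc <- roc_curve(scores, gold)
    expect_equal(roc$auc, concordance_auc(scores, gold), tolerance = 1e-12)
    expect_equal(roc$points$fpr[1], 0); expect_equal(roc$points$tpr[1], 0)
    expect_equal(tail(roc$points$fpr, 1), 1); expect_equal(tail(roc$points$tpr, 1), 1)
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("ROC handles separable, null, and degenerate inputs", {
  gold <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(roc_curve(c(rnorm(10, 10), rnorm(10, -10)), gold)$auc, 1.0)
  expect_error(roc_curve(rnorm(5), rep(TRUE, 5)), "at least one")
  set.seed(3)
  g <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  auc <- roc_curve(rnorm(10000), g)$auc
  n1 <- sum(g); n0 <- sum(!g)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))     # Mann-Whitney null SE
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("Bland-Altman limits follow the mean +/- 1.96 sd construction", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0); expect_equal(ba$loa_high - ba$loa_low, 0)
  set.seed(8)
  a <- rnorm(10000, 0, 2); b <- numeric(10000)
  ba2 <- bland_altman(a, b)
  se_loa <- 2 * sqrt(3) / sqrt(10000)            # approx se of the limit
  expect_lt(abs(ba2$loa_high - 1.96 * 2), 3 * se_loa)
  # antisymmetry under pair swap
  ba3 <- bland_altman(b, a)
  expect_equal(ba3$mean_diff, -ba2$mean_diff)
  expect_equal(ba3$loa_low, -ba2$loa_high)
  expect_equal(ba3$loa_high, -ba2$loa_low)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("cohort evaluation is deterministic and respects the Poisson oracle at extreme rates", {
  # every patient far from the 30/h boundary: near-perfect 2h vs 24h agreement
  set.seed(2)
  n <- 400
  hi <- sample(c(TRUE, FALSE), n, replace = TRUE)
  rates <- ifelse(hi, 100, 0.5)
  sp <- cohort_spec(n_patients = n,
                    rate_distribution = list(kind = "fixed", psvc = 1, pvc = 1),
                    seed = 3)
  ch <- simulate_cohort(sp)
  # overwrite counts with the extreme-rate draws (keeps the cohort shape)
  set.seed(4)
  ch$psvc_count_24h <- rpois(n, rates * 24)
  ch$psvc_count_2h <- rbinom(n, ch$psvc_count_24h, 2 / 24)
  ch$pvc_count_24h <- rpois(n, rates * 24)
  ch$pvc_count_2h <- rbinom(n, ch$pvc_count_24h, 2 / 24)
  ev <- evaluate_cohort(ch)
  sens <- ev$PSVC$metrics$estimate[ev$PSVC$metrics$metric == "sensitivity"]
  spec <- ev$PSVC$metrics$estimate[ev$PSVC$metrics$metric == "specificity"]
  expect_gte(sens, 99); expect_gte(spec, 99)
  # determinism: same cohort in, identical evaluation out
  ev2 <- evaluate_cohort(ch)
  expect_identical(serialize(ev, NULL), serialize(ev2, NULL))
  # JSON serialisation carries the cells and metrics
  js <- jsonlite::fromJSON(cohort_evaluation_json(ev))
  expect_equal(js$PSVC$confusion$tp, ev$PSVC$confusion$tp)
  expect_equal(js$n, n)
})

test_that("agreement degrades for cohorts concentrated at the threshold", {
  mk_cohort <- function(rates, seed) {
    n <- length(rates)
    set.seed(seed)
    c24 <- rpois(n, rates * 24)
    data.frame(patient_id = seq_len(n),
               psvc_count_24h = c24, psvc_count_2h = rbinom(n, c24, 2 / 24),
               pvc_count_24h = c24, pvc_count_2h = rbinom(n, c24, 2 / 24))
  }
  agree <- function(ch) {
    with(evaluate_cohort(ch)$calls, mean(psvc_call_2h == psvc_call_24h))
  }
  at_thr <- agree(mk_cohort(rep(30, 600), 5))
  extreme <- agree(mk_cohort(rep(c(5, 90), 300), 6))
  expect_lt(at_thr, extreme)
})
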