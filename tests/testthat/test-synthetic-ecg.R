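# Synthetic ECG generator: schedules, waveform rendering, cohort counts.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(fs = 50), "fs")
  expect_error(sim_config(coupling_frac_pvc = 1.2), "coupling_frac_pvc")
  expect_error(sim_config(pvc_rate = -1), "pvc_rate")
  expect_error(cohort_spec(rate_distribution = list(kind = "nope")),
               "rate_distribution")
  expect_error(cohort_spec(window_short = 30), "window_short")
})

test_that("event-free schedules are all sinus at the configured rate", {
  cfg <- sim_config(duration = 300, pvc_rate = 0, psvc_rate = 0,
                    rr_sd = 0.02, seed = 1)
  s <- simulate_rr_train(cfg)
  expect_true(all(s$labels == "N"))
  expect_true(all(diff(s$times) > 0))
  expect_equal(mean(diff(s$times)), 60 / cfg$mean_hr, tolerance = 0.01)
})

test_that("compensatory and non-compensatory pause identities hold exactly at rr_sd = 0", {
  cfg <- sim_config(duration = 900, pvc_rate = 40, psvc_rate = 40,
                    rr_sd = 0, seed = 3)
  s <- suppressMessages(simulate_rr_train(cfg))
  expect_gt(sum(s$labels == "PVC"), 0)
  expect_gt(sum(s$labels == "PSVC"), 0)
  n <- length(s$times)
  for (i in which(s$labels == "PVC")) {
    if (i > 1 && i < n && s$labels[i - 1] == "N" && s$labels[i + 1] == "N") {
      expect_equal((s$times[i] - s$times[i - 1]) + (s$times[i + 1] - s$times[i]),
                   2 * s$base_rr, tolerance = 1e-9)
    }
  }
  for (i in which(s$labels == "PSVC")) {
    if (i < n && s$labels[i + 1] == "N") {
      expect_equal(s$times[i + 1] - s$times[i], s$base_rr, tolerance = 1e-9)
    }
  }
})

test_that("premature-event counts follow the configured Poisson rate", {
  # oracle: counts ~ Poisson(rate * duration); check the Monte-Carlo mean
  # over 200 seeds against the closed-form mean within 3 standard errors,
  # and the dispersion by a chi-square goodness-of-fit
  n_seeds <- 200
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(duration = 7200, pvc_rate = 30, psvc_rate = 0,
                      mean_hr = 70, seed = s)
    sum(suppressMessages(simulate_rr_train(cfg))$labels == "PVC")
  }, numeric(1))
  lambda <- 30 * 2
  se <- sqrt(lambda / n_seeds)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # chi-square GOF on binned counts vs Poisson(60), alpha = 0.01
  brk <- c(-Inf, qpois(c(0.2, 0.4, 0.6, 0.8), lambda), Inf)
  obs <- table(cut(counts, brk))
  p_bin <- diff(c(0, ppois(brk[2:5], lambda), 1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p_bin))
  expect_gt(gof$p.value, 0.01)
})

test_that("identical seeds give bit-identical schedules, signals and cohorts", {
  cfg <- sim_config(duration = 60, pvc_rate = 60, psvc_rate = 60, seed = 11)
  s1 <- suppressMessages(simulate_rr_train(cfg))
  s2 <- suppressMessages(simulate_rr_train(cfg))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  r1 <- render_ecg(s1, config = cfg)
  r2 <- render_ecg(s2, config = cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  sp <- cohort_spec(seed = 13)
  expect_identical(serialize(simulate_cohort(sp), NULL),
                   serialize(simulate_cohort(sp), NULL))
})

test_that("rendering places template peaks at annotated R samples", {
  cfg <- sim_config(duration = 10, mean_hr = 60, pvc_rate = 0, psvc_rate = 0,
                    noise_sd = 0, wander_amp = 0, rr_sd = 0, seed = 1)
  s <- simulate_rr_train(cfg)
  out <- render_ecg(s, config = cfg)
  expect_equal(nrow(out$annotation), length(s$times))
  # the global maximum of a clean sinus render is an R peak
  peak <- which.max(out$record$samples) - 1L
  expect_true(peak %in% out$annotation$sample)
  # every annotated R sample is a local maximum of the clean signal
  # (v is 1-based, r is a 0-based sample index -> position 12 in the window)
  v <- out$record$samples
  for (r in out$annotation$sample) {
    expect_equal(which.max(v[(r - 10):(r + 12)]), 12)
  }
})

test_that("rendered PVC QRS support is at least 1.5x the sinus QRS support", {
  sim <- fixture_clean_sim()
  v <- sim$record$samples
  fs <- sim$config$fs
  qrs_support <- function(r) {
    w <- v[(r - round(0.1 * fs) + 1):(r + round(0.1 * fs) + 1)]
    sum(abs(w) > 0.1 * max(abs(w)))
  }
  n_idx <- sim$annotation$sample[sim$annotation$label == "N"]
  pvc_idx <- sim$annotation$sample[sim$annotation$label == "PVC"]
  expect_gte(length(pvc_idx), 2)
  med_n <- median(vapply(n_idx, qrs_support, numeric(1)))
  med_pvc <- median(vapply(pvc_idx, qrs_support, numeric(1)))
  expect_gte(med_pvc, 1.5 * med_n)
})

test_that("rendering fails on labels without templates", {
  cfg <- sim_config(duration = 10, seed = 1)
  s <- simulate_rr_train(cfg)
  s$labels[1] <- "PVC"
  expect_error(render_ecg(s, templates = default_beat_templates()["N"],
                          config = cfg),
               "no template")
})

test_that("cohort counts respect the Poisson/binomial sub-sampling structure", {
  sp <- cohort_spec(n_patients = 4000,
                    rate_distribution = list(kind = "fixed", psvc = 30, pvc = 10),
                    seed = 5)
  ch <- simulate_cohort(sp)
  # expectation identities: E[2h count] = 2 * rate, E[24h] = 24 * rate
  expect_equal(mean(ch$psvc_count_24h), 720, tolerance = 0.01)
  expect_equal(mean(ch$psvc_count_2h), 60, tolerance = 0.03)
  expect_true(all(ch$psvc_count_2h <= ch$psvc_count_24h))
  # thinning: marginal 2h counts are Poisson(2 * rate) -> variance = mean
  expect_equal(var(ch$pvc_count_2h) / mean(ch$pvc_count_2h), 1, tolerance = 0.1)
  # zero rate -> all counts zero
  sp0 <- cohort_spec(n_patients = 50,
                     rate_distribution = list(kind = "fixed", psvc = 0, pvc = 0),
                     seed = 2)
  ch0 <- simulate_cohort(sp0)
  expect_true(all(ch0$psvc_count_24h == 0 & ch0$pvc_count_2h == 0))
})

test_that("group-structured cohorts keep rates on the assigned side of 30/hour", {
  sp <- cohort_spec(seed = 9)   # default: 115/24/23/8 case-mix
  ch <- simulate_cohort(sp)
  expect_equal(nrow(ch), 170)
  expect_equal(as.vector(table(ch$group)[c("NC", "PSVC", "PVC", "PSVC+PVC")]),
               c(115, 24, 23, 8))
  hi_ps <- ch$group %in% c("PSVC", "PSVC+PVC")
  expect_true(all(ch$true_psvc_rate[hi_ps] > 30))
  expect_true(all(ch$true_psvc_rate[!hi_ps] < 30))
})
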