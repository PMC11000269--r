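# Synthetic single-lead ECG: beat templates, RR-train simulation, waveform
# rendering, and count-level cohort simulation.

#' Beat template
#'
#' A morphological template for one beat class, built as a sum of Gaussian
#' bumps (the standard analytic ECG morphology model). Each component is a
#' bump `amp * exp(-(t - center)^2 / (2 width^2))` in mV, with `center` in
#' seconds relative to the R peak.
#'
#' @param label beat class, one of `"N"`, `"PVC"`, `"PSVC"`.
#' @param components data frame with columns `amp` (mV), `center` (s),
#'   `width` (s), one row per bump (P, Q, R, S, T as applicable).
#' @param qrs_width nominal QRS duration in seconds.
#' @return an object of class `beat_template`.
#' @seealso [default_beat_templates()]
#' @export
beat_template <- function(label, components, qrs_width) {
  label <- match.arg(label, c("N", "PVC", "PSVC"))
  stopifnot(is.data.frame(components),
            all(c("amp", "center", "width") %in% names(components)))
  if (any(components$width <= 0)) stop_config("components$width", "must be > 0")
  if (qrs_width <= 0) stop_config("qrs_width", "must be > 0")
  r_row <- which.min(abs(components$center))
  if (max(abs(components$amp)) > abs(components$amp[r_row])) {
    stop_config("components", "R bump (center nearest 0) must have the largest magnitude")
  }
  structure(list(label = label, components = components, qrs_width = qrs_width),
            class = "beat_template")
}

#' Default beat templates
#'
#' Templates for the three beat classes handled by the package:
#' * `N` — sinus beat: upright P, narrow QRS, upright T.
#' * `PVC` — ventricular premature beat: no P wave, QRS at least twice the
#'   sinus width, discordant (inverted) T.
#' * `PSVC` — supraventricular premature beat: no sinus P (the ectopic P' is
#'   buried in the preceding T at typical coupling), QRS as narrow as the
#'   sinus beat.
#'
#' Amplitudes are typical for a chest (CM2/V2-like) lead, in mV.
#'
#' @return named list of [beat_template()] objects.
#' @export
default_beat_templates <- function() {
  n <- beat_template("N", data.frame(
    amp    = c(0.12, -0.12, 1.10, -0.25, 0.30),
    center = c(-0.18, -0.035, 0.00, 0.035, 0.22),
    width  = c(0.025, 0.010, 0.012, 0.012, 0.050)
  ), qrs_width = 0.08)
  pvc <- beat_template("PVC", data.frame(
    amp    = c(-0.30, 1.40, -0.55, -0.45),
    center = c(-0.060, 0.00, 0.070, 0.280),
    width  = c(0.030, 0.035, 0.035, 0.070)
  ), qrs_width = 0.16)
  psvc <- beat_template("PSVC", data.frame(
    amp    = c(-0.10, 0.95, -0.22, 0.26),
    center = c(-0.035, 0.00, 0.035, 0.20),
    width  = c(0.010, 0.012, 0.012, 0.045)
  ), qrs_width = 0.08)
  stopifnot(pvc$qrs_width >= 2 * n$qrs_width, psvc$qrs_width == n$qrs_width)
  list(N = n, PVC = pvc, PSVC = psvc)
}

#' Simulation configuration
#'
#' Parameters of one synthetic single-lead recording.
#'
#' @param fs sampling rate in Hz (>= 100).
#' @param duration recording length in seconds.
#' @param mean_hr mean sinus heart rate in beats/min.
#' @param rr_sd standard deviation of the sinus RR interval in seconds.
#' @param pvc_rate,psvc_rate premature-beat rates in events/hour.
#' @param coupling_frac_pvc,coupling_frac_psvc coupling interval of a
#'   premature beat as a fraction (0, 1) of the preceding RR.
#' @param noise_sd additive white-noise standard deviation in mV.
#' @param wander_amp,wander_freq baseline-wander sinusoid amplitude (mV) and
#'   frequency (Hz).
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(fs = 250, duration = 7200, mean_hr = 70, rr_sd = 0.04,
                       pvc_rate = 0, psvc_rate = 0,
                       coupling_frac_pvc = 0.60, coupling_frac_psvc = 0.70,
                       noise_sd = 0.03, wander_amp = 0.10, wander_freq = 0.25,
                       seed = 1L) {
  if (fs < 100) stop_config("fs", "must be >= 100 Hz")
  if (duration <= 0) stop_config("duration", "must be > 0")
  if (mean_hr <= 0) stop_config("mean_hr", "must be > 0")
  if (rr_sd < 0) stop_config("rr_sd", "must be >= 0")
  if (pvc_rate < 0) stop_config("pvc_rate", "must be >= 0")
  if (psvc_rate < 0) stop_config("psvc_rate", "must be >= 0")
  if (coupling_frac_pvc <= 0 || coupling_frac_pvc >= 1) {
    stop_config("coupling_frac_pvc", "must be in (0, 1)")
  }
  if (coupling_frac_psvc <= 0 || coupling_frac_psvc >= 1) {
    stop_config("coupling_frac_psvc", "must be in (0, 1)")
  }
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (wander_amp < 0) stop_config("wander_amp", "must be >= 0")
  if (wander_freq <= 0) stop_config("wander_freq", "must be > 0")
  structure(list(fs = fs, duration = duration, mean_hr = mean_hr, rr_sd = rr_sd,
                 pvc_rate = pvc_rate, psvc_rate = psvc_rate,
                 coupling_frac_pvc = coupling_frac_pvc,
                 coupling_frac_psvc = coupling_frac_psvc,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 wander_freq = wander_freq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a beat schedule (RR train with premature events)
#'
#' Sinus beats are laid down with RR intervals drawn from
#' `Normal(60/mean_hr, rr_sd)` truncated to > 0.2 s. Premature events arrive
#' as marked Poisson point processes at `pvc_rate` / `psvc_rate` per hour:
#'
#' * a PVC replaces a sinus slot at `coupling_frac_pvc` of the preceding RR
#'   and the next sinus beat keeps its original time, producing a
#'   compensatory pause (pre + post interval = two sinus cycles, exact when
#'   `rr_sd = 0`);
#' * a PSVC fires at `coupling_frac_psvc` of the preceding RR and resets the
#'   sinus clock, so the following interval is one plain sinus RR
#'   (non-compensatory pause).
#'
#' Premature events drawn into adjacent slots collide; collisions are dropped
#' with a message (couplets and bigeminy are out of scope).
#'
#' @param config a [sim_config()].
#' @return an object of class `beat_schedule`: list with `times` (s, strictly
#'   increasing), `labels` (aligned character vector), `base_rr` (s).
#' @export
simulate_rr_train <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    base_rr <- 60 / config$mean_hr
    n_max <- ceiling(config$duration / base_rr * 1.5) + 10
    rr <- stats::rnorm(n_max, base_rr, config$rr_sd)
    while (any(bad <- rr <= 0.2)) rr[bad] <- stats::rnorm(sum(bad), base_rr, config$rr_sd)
    times <- 0.5 + cumsum(rr)                       # 0.5 s lead-in
    times <- times[times < config$duration - 0.5]
    n <- length(times)
    labels <- rep("N", n)
    if (n < 3) {
      structure(list(times = times, labels = labels, base_rr = base_rr),
                class = "beat_schedule")
    } else {
    dur_h <- config$duration / 3600
    n_pvc <- stats::rpois(1, config$pvc_rate * dur_h)
    n_psvc <- stats::rpois(1, config$psvc_rate * dur_h)
    interior <- 2:(n - 1)
    k <- min(n_pvc + n_psvc, length(interior))
    slots <- if (k > 0) sort(sample(interior, k)) else integer(0)
    # drop adjacent collisions (keep the earlier event of each adjacent pair;
    # a run a, a+1, a+2 keeps a and a+2)
    if (length(slots) > 1) {
      kept <- slots[1]
      for (s in slots[-1]) if (s - kept[length(kept)] > 1) kept <- c(kept, s)
      if (length(kept) < length(slots)) {
        message(sprintf("simulate_rr_train: dropped %d premature event(s) in adjacent slots",
                        length(slots) - length(kept)))
      }
      slots <- kept
    }
    n_eff <- length(slots)
    n_pvc_eff <- min(n_pvc, n_eff)
    is_pvc <- rep(FALSE, n_eff)
    if (n_eff > 0 && n_pvc_eff > 0) {
      is_pvc[sample(n_eff, n_pvc_eff)] <- TRUE
    }

    rr_local <- c(NA, diff(times))                  # rr_local[i] = times[i] - times[i-1]
    shift <- 0
    for (j in seq_along(slots)) {
      i <- slots[j]
      prev_t <- times[i - 1]
      rr_i <- rr_local[i]                     # unshifted gap; rigid shifts preserve it
      if (is_pvc[j]) {
        times[i] <- prev_t + config$coupling_frac_pvc * rr_i
        labels[i] <- "PVC"
      } else {
        new_t <- prev_t + config$coupling_frac_psvc * rr_i
        delta <- new_t - times[i]             # < 0: clock resets earlier
        times[i:n] <- times[i:n] + delta
        labels[i] <- "PSVC"
      }
    }
    keep <- times > 0 & times < config$duration
    structure(list(times = times[keep], labels = labels[keep], base_rr = base_rr),
              class = "beat_schedule")
    }
  })
}

template_waveform <- function(template, fs, pre = 0.35, post = 0.45) {
  pre_n <- round(pre * fs); post_n <- round(post * fs)
  t <- (-pre_n:post_n) / fs                # grid hits t = 0 (the R peak) exactly
  y <- numeric(length(t))
  for (k in seq_len(nrow(template$components))) {
    cmp <- template$components[k, ]
    y <- y + cmp$amp * exp(-(t - cmp$center)^2 / (2 * cmp$width^2))
  }
  list(y = y, r_offset = pre_n)            # 0-based index of the R sample
}

#' Render an ECG waveform from a beat schedule
#'
#' Places each beat's template at its scheduled time (rounded to the sample
#' grid), then adds a sinusoidal baseline wander and white noise.
#'
#' @param schedule a [simulate_rr_train()] result.
#' @param templates named list of [beat_template()] covering all labels in
#'   the schedule; default [default_beat_templates()].
#' @param config the [sim_config()] used for the schedule (supplies `fs`,
#'   `duration`, noise and wander parameters, and the seed for the noise
#'   draw).
#' @return list with `record` (an `ecg_record`: `samples` in mV, `fs`,
#'   `lead_name`) and `annotation` (data frame `sample` — 0-based R-peak
#'   sample index — and `label`).
#' @export
render_ecg <- function(schedule, templates = default_beat_templates(), config) {
  stopifnot(inherits(schedule, "beat_schedule"), inherits(config, "sim_config"))
  missing_t <- setdiff(unique(schedule$labels), names(templates))
  if (length(missing_t)) {
    stop("render_ecg: no template for label(s): ", paste(missing_t, collapse = ", "))
  }
  if (length(schedule$times) && max(schedule$times) >= config$duration) {
    stop("render_ecg: schedule does not fit within config$duration")
  }
  fs <- config$fs
  n <- round(config$duration * fs)
  sig <- numeric(n)
  waves <- lapply(templates, template_waveform, fs = fs)
  r_idx <- round(schedule$times * fs)                 # 0-based
  for (b in seq_along(r_idx)) {
    w <- waves[[schedule$labels[b]]]
    a <- r_idx[b] - w$r_offset + 1                    # 1-based slice
    z <- a + length(w$y) - 1
    lo <- max(1, a); hi <- min(n, z)
    if (lo <= hi) sig[lo:hi] <- sig[lo:hi] + w$y[(lo - a + 1):(hi - a + 1)]
  }
  with_seed(sub_seed(config$seed, 104729L), {
    if (config$wander_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / fs
      sig <- sig + config$wander_amp * sin(2 * pi * config$wander_freq * tt + phase)
    }
    if (config$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, config$noise_sd)
  })
  record <- structure(list(samples = sig, fs = fs, lead_name = "CM2"),
                      class = "ecg_record")
  annotation <- data.frame(sample = r_idx, label = schedule$labels,
                           stringsAsFactors = FALSE)
  list(record = record, annotation = annotation)
}

#' Cohort specification for paired-window count simulation
#'
#' Describes a cohort of patients wearing a long-window (24 h) and a short
#' (2 h) recorder simultaneously; per-patient true PSVC and PVC rates are
#' drawn from `rate_distribution`.
#'
#' `rate_distribution` is one of:
#' * `list(kind = "fixed", psvc = r1, pvc = r2)` — every patient has the
#'   given rates (events/hour);
#' * `list(kind = "lognormal", meanlog_psvc=, sdlog_psvc=, meanlog_pvc=,
#'   sdlog_pvc=)` — independent log-normal rates;
#' * `list(kind = "groups", n_nc=, n_psvc=, n_pvc=, n_dual=, low=, high=)` —
#'   a four-group case-mix (negative controls, PSVC-only, PVC-only, dual).
#'   `low`/`high` are `c(meanlog, sdlog)` for the sub- and supra-threshold
#'   log-normal rate draws, truncated to stay on their side of the 30/hour
#'   positivity boundary (below 20/h, above 40/h respectively).
#'
#' @param n_patients number of patients (ignored for `kind = "groups"`,
#'   where group sizes determine it).
#' @param rate_distribution see Details.
#' @param window_long,window_short window lengths in hours.
#' @param window_placement `"uniform"` or `"start"`; with homogeneous Poisson
#'   events the short-window counts are exchangeable, so placement only
#'   matters as a documentation of the design.
#' @param seed master RNG seed; per-patient sub-seeds are derived as
#'   `(seed * 1000003 + i) mod 2147483629`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 170,
                        rate_distribution = list(
                          kind = "groups", n_nc = 115, n_psvc = 24, n_pvc = 23,
                          n_dual = 8, low = c(log(3), 0.8), high = c(log(80), 0.4)),
                        window_long = 24, window_short = 2,
                        window_placement = c("uniform", "start"), seed = 1L) {
  window_placement <- match.arg(window_placement)
  if (n_patients < 1) stop_config("n_patients", "must be >= 1")
  if (window_short > window_long) stop_config("window_short", "must be <= window_long")
  if (window_long <= 0) stop_config("window_long", "must be > 0")
  if (!is.list(rate_distribution) || is.null(rate_distribution$kind) ||
      !rate_distribution$kind %in% c("fixed", "lognormal", "groups")) {
    stop_config("rate_distribution", "kind must be 'fixed', 'lognormal' or 'groups'")
  }
  if (rate_distribution$kind == "groups") {
    n_patients <- with(rate_distribution, n_nc + n_psvc + n_pvc + n_dual)
  }
  structure(list(n_patients = n_patients, rate_distribution = rate_distribution,
                 window_long = window_long, window_short = window_short,
                 window_placement = window_placement, seed = as.integer(seed)),
            class = "cohort_spec")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (it in 1:200) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(x, lower), upper)
}

draw_cohort_rates <- function(spec) {
  rd <- spec$rate_distribution
  n <- spec$n_patients
  switch(rd$kind,
    fixed = data.frame(group = rep("fixed", n),
                       true_psvc_rate = rep(rd$psvc, n),
                       true_pvc_rate = rep(rd$pvc, n)),
    lognormal = data.frame(
      group = rep("lognormal", n),
      true_psvc_rate = stats::rlnorm(n, rd$meanlog_psvc, rd$sdlog_psvc),
      true_pvc_rate = stats::rlnorm(n, rd$meanlog_pvc, rd$sdlog_pvc)),
    groups = {
      grp <- rep(c("NC", "PSVC", "PVC", "PSVC+PVC"),
                 times = c(rd$n_nc, rd$n_psvc, rd$n_pvc, rd$n_dual))
      lo <- function(m) rlnorm_trunc(m, rd$low[1], rd$low[2], upper = 20)
      hi <- function(m) rlnorm_trunc(m, rd$high[1], rd$high[2], lower = 40)
      d <- data.frame(group = grp, true_psvc_rate = NA_real_, true_pvc_rate = NA_real_)
      ps_hi <- grp %in% c("PSVC", "PSVC+PVC")
      pv_hi <- grp %in% c("PVC", "PSVC+PVC")
      d$true_psvc_rate[ps_hi] <- hi(sum(ps_hi)); d$true_psvc_rate[!ps_hi] <- lo(sum(!ps_hi))
      d$true_pvc_rate[pv_hi] <- hi(sum(pv_hi)); d$true_pvc_rate[!pv_hi] <- lo(sum(!pv_hi))
      d
    })
}

#' Simulate a paired-window cohort at count level
#'
#' For each patient the long-window count is `Poisson(rate * window_long)`
#' and the short-window count is drawn conditionally as
#' `Binomial(long_count, window_short / window_long)` — the short window
#' subsamples the same event realisation, matching simultaneous wear.
#' Marginally the short count is therefore `Poisson(rate * window_short)`
#' (Poisson thinning).
#'
#' @param spec a [cohort_spec()].
#' @return data frame with one row per patient: `patient_id`, `group`,
#'   `psvc_count_2h`, `pvc_count_2h`, `psvc_count_24h`, `pvc_count_24h`
#'   (column names follow the default windows; the actual windows used are
#'   attached as attributes `window_short`/`window_long`), `true_psvc_rate`,
#'   `true_pvc_rate`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rates <- with_seed(spec$seed, draw_cohort_rates(spec))
  n <- spec$n_patients
  p_thin <- spec$window_short / spec$window_long
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    group = rates$group,
    psvc_count_2h = NA_integer_, pvc_count_2h = NA_integer_,
    psvc_count_24h = NA_integer_, pvc_count_24h = NA_integer_,
    true_psvc_rate = rates$true_psvc_rate,
    true_pvc_rate = rates$true_pvc_rate,
    stringsAsFactors = FALSE)
  # vectorised draw with per-patient sub-seed reproducibility: draw all
  # patients from one stream seeded by the master; per-patient streams are
  # only needed for parallel generation, so we derive one stream per block
  for (i in seq_len(n)) {
    with_seed(sub_seed(spec$seed, i), {
      long_ps <- stats::rpois(1, rates$true_psvc_rate[i] * spec$window_long)
      long_pv <- stats::rpois(1, rates$true_pvc_rate[i] * spec$window_long)
      out$psvc_count_24h[i] <- long_ps
      out$pvc_count_24h[i] <- long_pv
      out$psvc_count_2h[i] <- stats::rbinom(1, long_ps, p_thin)
      out$pvc_count_2h[i] <- stats::rbinom(1, long_pv, p_thin)
    })
  }
  attr(out, "window_short") <- spec$window_short
  attr(out, "window_long") <- spec$window_long
  out
}
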