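# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A clean 2-minute recording with both premature classes, plus its schedule.
fixture_clean_sim <- function() {
  memo("clean_sim", {
    cfg <- sim_config(duration = 180, pvc_rate = 90, psvc_rate = 90,
                      noise_sd = 0, wander_amp = 0, rr_sd = 0.03, seed = 42)
    sch <- suppressMessages(simulate_rr_train(cfg))
    sim <- render_ecg(sch, config = cfg)
    list(config = cfg, schedule = sch, record = sim$record,
         annotation = sim$annotation)
  })
}

# A moderately noisy 5-minute recording.
fixture_noisy_sim <- function() {
  memo("noisy_sim", {
    cfg <- sim_config(duration = 300, pvc_rate = 30, psvc_rate = 30,
                      noise_sd = 0.05, wander_amp = 0.1, seed = 7)
    sch <- suppressMessages(simulate_rr_train(cfg))
    sim <- render_ecg(sch, config = cfg)
    list(config = cfg, schedule = sch, record = sim$record,
         annotation = sim$annotation)
  })
}

# Labelled beat segments pooled over a few synthetic patients (for the
# classifier tests): returns segments, labels, patient ids.
fixture_beat_dataset <- function() {
  memo("beat_dataset", {
    segs <- list(); labs <- list(); pats <- list()
    for (i in 1:6) {
      cfg <- sim_config(duration = 480, pvc_rate = 90, psvc_rate = 90,
                        noise_sd = 0.02, seed = 900 + i)
      sim <- render_ecg(suppressMessages(simulate_rr_train(cfg)), config = cfg)
      rec <- preprocess_ecg(sim$record)
      det <- detect_qrs(rec)
      mm <- match_beats(det, sim$annotation$sample, cfg$fs, 50)
      sg <- suppressMessages(segment_beats(rec, det))
      dl <- rep(NA_character_, length(det))
      dl[mm$pairs$det_idx] <- sim$annotation$label[mm$pairs$truth_idx]
      sl <- dl[match(sg$r_indices, det)]
      keep <- which(!is.na(sl))
      segs[[i]] <- sg$segments[keep, , drop = FALSE]
      labs[[i]] <- sl[keep]
      pats[[i]] <- rep(sprintf("P%02d", i), length(keep))
    }
    list(x = do.call(rbind, segs), labels = unlist(labs),
         patient = unlist(pats))
  })
}

# A small trained classifier on a class-balanced subsample of the dataset.
fixture_trained_model <- function() {
  memo("trained_model", {
    d <- fixture_beat_dataset()
    set.seed(101)
    idx <- unlist(lapply(unique(d$patient), function(p) {
      r <- which(d$patient == p)
      prem <- r[d$labels[r] != "N"]
      nn <- r[d$labels[r] == "N"]
      c(prem, sample(nn, min(length(nn), 80)))
    }))
    beat_classifier(d$x[idx, ], d$labels[idx], patient = d$patient[idx],
                    split_ratio = c(4, 1, 1), epochs = 15, batch_size = 64,
                    learning_rate = 1e-3, seed = 5,
                    spec = model_spec(ncol(d$x), channels = 12))
  })
}

# Brute-force pairwise concordance (ties counted 1/2): the independent AUC
# oracle.
concordance_auc <- function(scores, gold) {
  pos <- scores[gold]; neg <- scores[!gold]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
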