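# Beat pipeline: band-pass preprocessing, Pan-Tompkins style QRS detection,
# beat segmentation, RR series and inter-beat-interval scattergram.

#' Construct an ECG record
#'
#' @param samples numeric vector of amplitudes in mV.
#' @param fs sampling rate in Hz.
#' @param lead_name lead label, e.g. `"CM2"`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_name = "CM2") {
  if (fs <= 0) stop_config("fs", "must be > 0")
  if (length(samples) < 2 * fs) {
    stop("ecg_record: need at least 2 s of signal (2*fs samples)")
  }
  structure(list(samples = as.numeric(samples), fs = fs, lead_name = lead_name),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("Single-lead ECG record (%s): %.1f s at %g Hz (%d samples)\n",
              x$lead_name, length(x$samples) / x$fs, x$fs, length(x$samples)))
  invisible(x)
}

bandpass <- function(x, fs, low, high, order = 3) {
  ny <- fs / 2
  bf <- signal::butter(order, c(low / ny, high / ny), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Band-pass preprocess an ECG record
#'
#' Zero-phase Butterworth band-pass (default 0.5–40 Hz) removing baseline
#' wander and high-frequency noise while leaving R-peak locations essentially
#' unshifted (zero-phase filtering).
#'
#' @param record an [ecg_record()].
#' @param low,high passband edges in Hz.
#' @param order Butterworth order (applied forwards and backwards).
#' @return a filtered `ecg_record` of identical length and sampling rate.
#' @export
preprocess_ecg <- function(record, low = 0.5, high = 40, order = 3) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  if (n < 3 * (order + 1) * 2) stop("preprocess_ecg: signal too short for filter warm-up")
  high <- min(high, 0.49 * record$fs)
  out <- record
  out$samples <- bandpass(record$samples, record$fs, low, high, order)
  out
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect QRS complexes
#'
#' Pan-Tompkins style detector: band-pass 5–15 Hz to isolate QRS energy,
#' differentiate, square, moving-window integrate (150 ms), then pick
#' integrated-signal peaks with adaptive signal/noise thresholds, a 200 ms
#' refractory period and a search-back pass for long gaps. Each accepted
#' detection is refined to the local absolute maximum of the input signal
#' within ±60 ms.
#'
#' Thresholds are initialised from the integrated candidate-peak heights
#' (translation-invariant, so zero-padding a record shifts every detection by
#' exactly the pad length).
#'
#' @param record a (preferably preprocessed) [ecg_record()].
#' @param refractory minimum separation between detections in seconds.
#' @param search_back enable search-back for missed beats.
#' @return integer vector of strictly increasing 0-based R-peak sample
#'   indices (empty if nothing detected).
#' @export
detect_qrs <- function(record, refractory = 0.2, search_back = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  filt <- bandpass(x, fs, 5, 15, order = 2)
  der <- c(0, diff(filt)) * fs
  sq <- der^2
  wlen <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 1))
  integ[is.na(integ)] <- 0

  cand <- local_maxima(integ)
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) return(integer(0))
  h <- integ[cand]
  spki <- 0.7 * stats::quantile(h, 0.98, names = FALSE)
  npki <- 0.1 * spki
  thr <- function() npki + 0.25 * (spki - npki)

  refr <- round(refractory * fs)
  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (k in seq_along(cand)) {
    i <- cand[k]; hi <- h[k]
    if (i - last < refr) next
    if (hi >= thr()) {
      if (length(accepted)) rr_hist <- c(rr_hist, i - last)
      if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      accepted <- c(accepted, i)
      last <- i
      spki <- 0.125 * hi + 0.875 * spki
    } else {
      npki <- 0.125 * hi + 0.875 * npki
      if (search_back && length(rr_hist) >= 2) {
        rr_avg <- mean(rr_hist)
        if (i - last > 1.66 * rr_avg) {
          gap <- cand > last + refr & cand < i - refr
          if (any(gap)) {
            hb <- h[gap]
            best <- which(gap)[which.max(hb)]
            if (h[best] > 0.5 * thr()) {
              j <- cand[best]
              rr_hist <- c(rr_hist, j - last)
              if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
              accepted <- c(accepted, j)
              last <- j
              spki <- 0.25 * h[best] + 0.75 * spki
            }
          }
        }
      }
    }
  }
  if (!length(accepted)) return(integer(0))

  # refine: integrated-peak lag -> local |signal| maximum within +/- 60 ms
  half <- round(0.060 * fs)
  n <- length(x)
  refined <- vapply(accepted, function(i) {
    lo <- max(1, i - wlen - half); hi2 <- min(n, i + half)
    lo + which.max(abs(x[lo:hi2])) - 1
  }, numeric(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  as.integer(refined - 1L)   # 0-based
}

#' Segment beats around detected R peaks
#'
#' Extracts a fixed window (`window_pre` s before to `window_post` s after
#' each R peak) and standardises each segment to zero mean and unit variance.
#' Beats whose window would overrun the record edge are dropped (count
#' reported via `message()`).
#'
#' @param record an [ecg_record()].
#' @param r_indices strictly increasing 0-based R-peak sample indices.
#' @param window_pre,window_post window extent in seconds.
#' @return an object of class `beat_segments`: list with `segments`
#'   (matrix, one standardised beat per row), `r_indices` (0-based, beats
#'   kept), `window_pre`, `window_post`, `fs`.
#' @export
segment_beats <- function(record, r_indices, window_pre = 0.25, window_post = 0.45) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(r_indices) > 1 && any(diff(r_indices) <= 0)) {
    stop("segment_beats: r_indices must be strictly increasing")
  }
  fs <- record$fs
  n <- length(record$samples)
  if (any(r_indices < 0 | r_indices >= n)) {
    stop("segment_beats: r_indices outside record bounds")
  }
  pre <- round(window_pre * fs)
  len <- round((window_pre + window_post) * fs)
  start <- r_indices - pre + 1L              # 1-based slice start
  ok <- start >= 1L & (start + len - 1L) <= n
  if (any(!ok)) message(sprintf("segment_beats: dropped %d edge beat(s)", sum(!ok)))
  start <- start[ok]
  m <- length(start)
  seg <- matrix(0, m, len)
  for (b in seq_len(m)) seg[b, ] <- record$samples[start[b]:(start[b] + len - 1L)]
  mu <- rowMeans(seg)
  seg <- seg - mu
  sdv <- sqrt(rowSums(seg^2) / (len - 1))
  nz <- sdv > 0
  seg[nz, ] <- seg[nz, , drop = FALSE] / sdv[nz]
  structure(list(segments = seg, r_indices = as.integer(r_indices[ok]),
                 window_pre = window_pre, window_post = window_post, fs = fs),
            class = "beat_segments")
}

#' RR-interval series
#'
#' @param r_indices strictly increasing R-peak sample indices.
#' @param fs sampling rate in Hz.
#' @return RR intervals in milliseconds (`length(r_indices) - 1` values).
#' @export
rr_series <- function(r_indices, fs) {
  if (length(r_indices) < 2) return(numeric(0))
  diff(r_indices) / fs * 1000
}

#' Inter-beat-interval (Lorenz/Poincaré) scattergram
#'
#' Pairs each RR interval with the next: a beat train of `n` beats yields
#' `n - 2` points. Premature beats show as characteristic off-diagonal
#' points (short RR followed by long RR for a compensatory PVC).
#'
#' @param rr RR intervals in ms (from [rr_series()]).
#' @param beat_labels optional labels of the underlying beats (length
#'   `length(rr) + 1`); each point is tagged with the class of the beat
#'   terminating its first interval.
#' @return object of class `ibi_scattergram`: data frame with `rr_n_ms`,
#'   `rr_next_ms` and optional `label`.
#' @export
ibi_scattergram <- function(rr, beat_labels = NULL) {
  if (length(rr) < 2) {
    warning("ibi_scattergram: fewer than 3 beats; empty scattergram")
    pts <- data.frame(rr_n_ms = numeric(0), rr_next_ms = numeric(0))
    return(structure(pts, class = c("ibi_scattergram", "data.frame")))
  }
  stopifnot(all(rr > 0))
  m <- length(rr) - 1
  pts <- data.frame(rr_n_ms = rr[seq_len(m)], rr_next_ms = rr[seq_len(m) + 1])
  if (!is.null(beat_labels)) {
    stopifnot(length(beat_labels) == length(rr) + 1)
    pts$label <- beat_labels[seq_len(m) + 1]
  }
  structure(pts, class = c("ibi_scattergram", "data.frame"))
}

#' @export
plot.ibi_scattergram <- function(x, ...) {
  cols <- if ("label" %in% names(x)) {
    c(N = "black", PSVC = "dodgerblue", PVC = "firebrick")[x$label]
  } else "black"
  graphics::plot(x$rr_n_ms, x$rr_next_ms, col = cols, pch = 16, cex = 0.5,
                 xlab = "RR(n) [ms]", ylab = "RR(n+1) [ms]", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
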