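# Synthetic single-lead rhythm strips for the seven arrhythmia classes.
# Beats are sum-of-Gaussians P-QRS-T templates strung along a class-specific
# RR-interval process; this is deliberately a statistical emulator (rate,
# regularity, morphology, ectopy, fibrillatory baseline), not a dynamical
# heart model.

#' Parameter set defining one synthetic rhythm class
#'
#' Defaults encode the textbook distinctions between the classes:
#' * N: 60-100 bpm, regular (RR CV 3%), narrow QRS, P wave present.
#' * AF: 100-150 bpm, grossly irregular (RR CV 25%), absent P waves,
#'   band-limited 4-9 Hz fibrillatory baseline.
#' * AT: 150-200 bpm, regular, narrow QRS.
#' * PAC: sinus rate with premature narrow-complex beats (25% of beats, 40%
#'   premature, followed by a compensatory pause).
#' * PVC: sinus rate with premature wide-complex high-amplitude beats.
#' * SBR: 40-55 bpm, regular, narrow QRS.
#' * VT: 150-210 bpm, wide QRS (160 ms), no P wave.
#'
#' Invariants enforced: SBR upper rate < 60; N within 60-100; AT lower rate
#' >= 150; VT lower rate >= 100; AF has RR CV >= 0.15 and zero P amplitude;
#' N/SBR/AT have RR CV <= 0.05; PVC/VT QRS width >= 120 ms while N/PAC/AT
#' stay < 120 ms.
#'
#' @param cls one of the seven class labels.
#' @param ... named overrides of the class defaults (checked against the
#'   invariants above).
#' @return Object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(cls = arrhythmia_classes(), ...) {
  cls <- match.arg(cls)
  morph <- function(p, qrs, t, amp = 1) {
    list(p_amp = p, qrs_width_ms = qrs, t_amp = t, qrs_amp = amp)
  }
  spec <- switch(cls,
    N = list(rate_bpm = c(62, 98), rr_cv = 0.03,
             morphology = morph(0.15, 80, 0.30),
             ectopy = list(prob = 0, template = NULL),
             baseline = list(amp = 0, band = c(4, 9))),
    AF = list(rate_bpm = c(100, 150), rr_cv = 0.25,
              morphology = morph(0, 85, 0.25),
              ectopy = list(prob = 0, template = NULL),
              baseline = list(amp = 0.08, band = c(4, 9))),
    AT = list(rate_bpm = c(150, 200), rr_cv = 0.02,
              morphology = morph(0.10, 85, 0.20),
              ectopy = list(prob = 0, template = NULL),
              baseline = list(amp = 0, band = c(4, 9))),
    PAC = list(rate_bpm = c(62, 98), rr_cv = 0.03,
               morphology = morph(0.15, 80, 0.30),
               ectopy = list(prob = 0.25, premature = 0.6, symbol = "A",
                             template = morph(0.05, 80, 0.25, amp = 0.9)),
               baseline = list(amp = 0, band = c(4, 9))),
    PVC = list(rate_bpm = c(62, 98), rr_cv = 0.03,
               morphology = morph(0.15, 80, 0.30),
               ectopy = list(prob = 0.25, premature = 0.6, symbol = "V",
                             template = morph(0, 150, -0.35, amp = 1.4)),
               baseline = list(amp = 0, band = c(4, 9))),
    SBR = list(rate_bpm = c(40, 55), rr_cv = 0.03,
               morphology = morph(0.15, 80, 0.30),
               ectopy = list(prob = 0, template = NULL),
               baseline = list(amp = 0, band = c(4, 9))),
    VT = list(rate_bpm = c(150, 210), rr_cv = 0.04,
              morphology = morph(0, 160, -0.30, amp = 1.2),
              ectopy = list(prob = 0, template = NULL),
              baseline = list(amp = 0, band = c(4, 9))))
  spec <- utils::modifyList(spec, list(...))
  spec$cls <- cls
  validate_rhythm_spec(spec)
  structure(spec, class = "rhythm_spec")
}

validate_rhythm_spec <- function(s) {
  r <- s$rate_bpm
  if (r[1] > r[2]) stop("infeasible rate band: low > high")
  chk <- function(cond, msg) if (!cond) stop("rhythm_spec invariant: ", msg)
  switch(s$cls,
    SBR = chk(r[2] < 60, "SBR upper rate must be < 60 bpm"),
    N = chk(r[1] >= 60 && r[2] <= 100, "N rate band must lie in [60, 100]"),
    AT = chk(r[1] >= 150, "AT lower rate must be >= 150 bpm"),
    VT = chk(r[1] >= 100, "VT lower rate must be >= 100 bpm"),
    invisible(NULL))
  if (s$cls == "AF") {
    chk(s$rr_cv >= 0.15, "AF RR CV must be >= 0.15")
    chk(s$morphology$p_amp == 0, "AF must have zero P amplitude")
  }
  if (s$cls %in% c("N", "SBR", "AT")) {
    chk(s$rr_cv <= 0.05, paste(s$cls, "RR CV must be <= 0.05"))
  }
  wide <- if (s$cls == "PVC") s$ectopy$template$qrs_width_ms
          else s$morphology$qrs_width_ms
  if (s$cls %in% c("PVC", "VT")) chk(wide >= 120, "PVC/VT QRS must be >= 120 ms")
  if (s$cls %in% c("N", "PAC", "AT")) {
    chk(s$morphology$qrs_width_ms < 120, "narrow-complex QRS must be < 120 ms")
  }
  invisible(TRUE)
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec %s: %g-%g bpm, RR CV %g, QRS %g ms, P %g mV%s>\n",
              x$cls, x$rate_bpm[1], x$rate_bpm[2], x$rr_cv,
              x$morphology$qrs_width_ms, x$morphology$p_amp,
              if (x$ectopy$prob > 0)
                sprintf(", ectopy %g%%", 100 * x$ectopy$prob) else ""))
  invisible(x)
}

#' Render a single-beat waveform template
#'
#' One cardiac cycle of length `rr_s` seconds: Gaussian bumps for the P wave
#' (phase 0.20 of the cycle), QRS complex (phase 0.40), and T wave (phase
#' 0.65). The QRS width parameter (milliseconds, full width ~ 4 standard
#' deviations) controls the central bump; P and T have fixed physiologic
#' widths.
#'
#' @param morphology list with `p_amp`, `qrs_width_ms`, `t_amp`, `qrs_amp`
#'   (see [rhythm_spec()]).
#' @param fs sampling frequency (Hz).
#' @param rr_s cycle length in seconds.
#' @return Numeric waveform of `round(rr_s * fs)` samples.
#' @export
beat_template <- function(morphology, fs, rr_s = 0.8) {
  if (fs <= 0) stop("fs must be > 0")
  if (morphology$qrs_width_ms <= 0) stop("QRS width must be positive")
  n <- max(1L, round(rr_s * fs))
  t <- (seq_len(n) - 1) / fs
  g <- function(center, sd) exp(-0.5 * ((t - center) / sd)^2)
  qrs_sd <- morphology$qrs_width_ms / 1000 / 4
  amp <- if (is.null(morphology$qrs_amp)) 1 else morphology$qrs_amp
  morphology$p_amp * g(0.20 * rr_s, 0.025) +
    amp * g(0.40 * rr_s, qrs_sd) +
    morphology$t_amp * g(0.65 * rr_s, 0.060)
}

#' Generate a synthetic rhythm strip
#'
#' RR intervals are drawn around a per-record base rate sampled uniformly
#' from the class band, with multiplicative Gaussian jitter of the class's
#' RR coefficient of variation (truncated at 40% of the mean). Ectopic beats
#' replace a beat with the ectopic template at 60% of the normal interval
#' followed by a compensatory pause of 140%, so the mean rate is preserved.
#' AF adds a band-limited fibrillatory baseline; all classes get additive
#' white measurement noise (2% of QRS amplitude by default). Fully
#' reproducible from the seed. QRS peak positions are stored as annotations
#' (`N` for normal, the ectopic symbol for ectopic beats).
#'
#' @param spec a [rhythm_spec()].
#' @param duration_s strip duration in seconds (> 0).
#' @param fs sampling frequency (Hz).
#' @param seed integer seed.
#' @param noise_sd measurement-noise standard deviation in millivolts.
#' @return An [ecg_record()] with `label = spec$cls`.
#' @export
generate_rhythm <- function(spec, duration_s, fs = 360, seed = 1L,
                            noise_sd = 0.02) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (spec$rate_bpm[1] > spec$rate_bpm[2]) stop("infeasible rate band: low > high")
  set.seed(seed)
  n_total <- round(duration_s * fs)
  base_rate <- runif(1, spec$rate_bpm[1], spec$rate_bpm[2])
  rr_mean <- 60 / base_rate
  sig <- numeric(n_total)
  ann_sample <- integer(0); ann_symbol <- character(0)
  t0 <- 0
  pending_pause <- FALSE
  while (t0 < duration_s) {
    ectopic <- !pending_pause && spec$ectopy$prob > 0 &&
      runif(1) < spec$ectopy$prob
    rr <- rr_mean * max(0.4, 1 + spec$rr_cv * rnorm(1))
    if (ectopic) {
      rr <- rr * spec$ectopy$premature
      pending_pause <- TRUE
      morph <- spec$ectopy$template
      sym <- spec$ectopy$symbol
    } else {
      if (pending_pause) {
        rr <- rr * (2 - spec$ectopy$premature)  # compensatory pause
        pending_pause <- FALSE
      }
      morph <- spec$morphology
      sym <- if (spec$cls == "VT") "V" else "N"
    }
    beat <- beat_template(morph, fs, rr)
    i0 <- round(t0 * fs)
    idx <- (i0 + 1):min(i0 + length(beat), n_total)
    if (length(idx) > 0 && idx[1] <= n_total) {
      sig[idx] <- sig[idx] + beat[seq_along(idx)]
      peak <- i0 + round(0.40 * rr * fs)  # QRS phase offset
      if (peak < n_total) {
        ann_sample <- c(ann_sample, as.integer(peak))
        ann_symbol <- c(ann_symbol, sym)
      }
    }
    t0 <- t0 + rr
  }
  if (spec$baseline$amp > 0) {
    tt <- (seq_len(n_total) - 1) / fs
    fib <- numeric(n_total)
    for (k in 1:6) {
      f <- runif(1, spec$baseline$band[1], spec$baseline$band[2])
      fib <- fib + runif(1, 0.5, 1) * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
    }
    sig <- sig + spec$baseline$amp * fib / 3
  }
  qrs_amp <- if (is.null(spec$morphology$qrs_amp)) 1 else spec$morphology$qrs_amp
  sig <- sig + rnorm(n_total, sd = noise_sd * qrs_amp)
  ecg_record(sig, fs,
             record_id = sprintf("sim_%s_%d", spec$cls, seed),
             annotations = data.frame(sample = ann_sample,
                                      symbol = ann_symbol,
                                      stringsAsFactors = FALSE),
             label = spec$cls)
}

#' Build a labeled synthetic segment dataset
#'
#' Generates exactly `class_counts[cls]` segments per class, each cut from
#' its own independently seeded strip, and a manifest of per-class counts.
#'
#' @param class_counts named vector of non-negative counts over the class
#'   labels (e.g. `round(reference_class_counts() * 0.01)`).
#' @param segment_len segment length in samples.
#' @param fs sampling frequency (Hz).
#' @param seed master seed; each segment derives its own child seed.
#' @return Object of class `ecg_dataset`: list with `segments` (list of
#'   [ecg_segment()]), `manifest` (data frame `class`, `n`).
#' @export
make_dataset <- function(class_counts, segment_len = 2000L, fs = 360,
                         seed = 1L) {
  stopifnot(all(class_counts >= 0))
  segments <- list()
  duration <- segment_len / fs + 1
  k <- 0L
  for (cls in names(class_counts)) {
    spec <- rhythm_spec(cls)
    nc <- class_counts[[cls]]
    for (r in seq_len(nc)) {
      k <- k + 1L
      rec <- generate_rhythm(spec, duration, fs, seed = derive_seed(seed, k))
      segments[[k]] <- ecg_segment(rec$samples[seq_len(segment_len)],
                                   label = cls,
                                   source_record = rec$record_id,
                                   start_index = 0L)
    }
  }
  manifest <- data.frame(class = names(class_counts),
                         n = as.integer(class_counts),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(segments = segments, manifest = manifest,
                 segment_len = as.integer(segment_len), fs = fs, seed = seed),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset: %d segments of %d samples @ %g Hz, seed %d>\n",
              length(x$segments), x$segment_len, x$fs, x$seed))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

# ---- rule-based reference classifier ---------------------------------------

# Detect QRS peaks: local maxima above 45% of the global maximum, separated
# by at least 180 ms.
detect_beats <- function(values, fs) {
  thr <- 0.45 * max(values)
  mind <- round(0.18 * fs)
  n <- length(values)
  cand <- which(values > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[values[cand] >= values[cand - 1] & values[cand] >= values[cand + 1]]
  peaks <- integer(0)
  for (p in cand) {
    if (length(peaks) == 0 || p - peaks[length(peaks)] >= mind) {
      peaks <- c(peaks, p)
    } else if (values[p] > values[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  peaks
}

# Width (ms) of the complex around a peak, at 30% of its height (~3.1 sd
# for a Gaussian bump; the 30% level stays above the T-wave amplitudes so
# adjacent waves do not merge into the measured complex).
beat_width_ms <- function(values, peak, fs) {
  thr <- values[peak] * 0.3
  l <- peak
  while (l > 1 && values[l - 1] > thr) l <- l - 1
  r <- peak
  n <- length(values)
  while (r < n && values[r + 1] > thr) r <- r + 1
  (r - l + 1) / fs * 1000
}

#' Rule-based rhythm classifier (rate / regularity / QRS width / P wave)
#'
#' A deliberately simple decision rule used as a separability reference for
#' the synthetic generator: detects QRS peaks, then classifies from mean
#' heart rate, RR-interval irregularity (coefficient of variation and the
#' fraction of premature intervals), and complex width at 20% height. Not
#' intended for real ECGs.
#'
#' @param values numeric segment.
#' @param fs sampling frequency (Hz).
#' @return A class label (or `"unknown"` when fewer than 3 beats are found).
#' @export
rule_classify_segment <- function(values, fs = 360) {
  peaks <- detect_beats(values, fs)
  if (length(peaks) < 3) return("unknown")
  rr <- diff(peaks) / fs
  rate <- 60 / mean(rr)
  cv <- sd(rr) / mean(rr)
  widths <- vapply(peaks, function(p) beat_width_ms(values, p, fs), numeric(1))
  wide_frac <- mean(widths >= 90)
  short_frac <- mean(rr < 0.8 * median(rr))  # premature intervals
  if (rate >= 140 && cv < 0.08) {
    if (median(widths) >= 90) "VT" else "AT"
  } else if (rate < 60) {
    "SBR"
  } else if (wide_frac > 0.05 && wide_frac < 0.6) {
    "PVC"
  } else if (cv >= 0.10 || short_frac >= 0.08) {
    if (rate >= 100) "AF" else "PAC"
  } else {
    "N"
  }
}
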