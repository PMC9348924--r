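# Run code with a private, reproducible RNG stream, leaving the caller's
# RNG state untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Parameters of the synthetic heart-sound generator
#'
#' Describes one simulated phonocardiogram: periodic cardiac cycles, each
#' with an S1 sound at cycle start and an S2 sound after the systolic
#' interval, an optional band-limited systolic murmur, and additive
#' wide-band sensor noise. Amplitudes are dimensionless; times are in
#' seconds.
#'
#' @param heart_rate Beats per minute (> 0).
#' @param s1_amp,s2_amp Peak amplitudes of the S1 and S2 events (>= 0).
#' @param s1_freq,s2_freq Dominant frequencies of S1 and S2 in Hz. S1 is
#'   the lower-pitched "lub" (default 35 Hz), S2 the shorter, higher "dub"
#'   (default 60 Hz).
#' @param event_duration Duration of each sound event in seconds (> 0).
#' @param s1_s2_gap Systolic interval from the end of S1 to the start of
#'   S2, in seconds. The events must fit in one cycle:
#'   `s1_s2_gap + 2 * event_duration < 60 / heart_rate`.
#' @param murmur_amp Amplitude of band-limited (100–400 Hz) noise filling
#'   the systolic gap; 0 disables the murmur.
#' @param noise_sd Standard deviation of additive white Gaussian sensor
#'   noise applied to the whole record.
#' @param fs Sampling rate in Hz (default 2000: heart-sound energy lies
#'   below ~600 Hz, so 2000 Hz is comfortably above Nyquist).
#' @param duration Record length in seconds.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   same parameters and seed.
#' @return An object of class `pcg_params`.
#' @seealso [generate_pcg()], [pcg_preset()]
#' @export
pcg_params <- function(heart_rate = 72, s1_amp = 2.0, s2_amp = 1.6,
                       s1_freq = 35, s2_freq = 60, event_duration = 0.12,
                       s1_s2_gap = 0.25, murmur_amp = 0, noise_sd = 0.02,
                       fs = 2000, duration = 10, seed = 0L) {
  p <- list(heart_rate = heart_rate, s1_amp = s1_amp, s2_amp = s2_amp,
            s1_freq = s1_freq, s2_freq = s2_freq,
            event_duration = event_duration, s1_s2_gap = s1_s2_gap,
            murmur_amp = murmur_amp, noise_sd = noise_sd, fs = fs,
            duration = duration, seed = as.integer(seed))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in setdiff(names(p), "seed")) {
    if (!num1(p[[nm]])) stop("argument error: `", nm,
                             "` must be a single finite number")
  }
  if (p$heart_rate <= 0 || p$fs <= 0 || p$duration <= 0 ||
      p$event_duration <= 0) {
    stop("argument error: heart_rate, fs, duration, event_duration must be > 0")
  }
  if (p$s1_amp < 0 || p$s2_amp < 0 || p$murmur_amp < 0 || p$noise_sd < 0 ||
      p$s1_s2_gap < 0) {
    stop("argument error: amplitudes, noise_sd and s1_s2_gap must be >= 0")
  }
  if (p$s1_s2_gap + 2 * p$event_duration >= 60 / p$heart_rate) {
    stop("argument error: S1/S2 events do not fit within one cardiac cycle ",
         "(require s1_s2_gap + 2*event_duration < 60/heart_rate)")
  }
  structure(p, class = "pcg_params")
}

#' @export
print.pcg_params <- function(x, ...) {
  cat("<pcg_params> ", x$heart_rate, " bpm, ", x$duration, " s @ ", x$fs,
      " Hz\n", sep = "")
  cat("  S1: amp ", x$s1_amp, " @ ", x$s1_freq, " Hz; S2: amp ", x$s2_amp,
      " @ ", x$s2_freq, " Hz; event ", x$event_duration, " s, gap ",
      x$s1_s2_gap, " s\n", sep = "")
  cat("  murmur_amp ", x$murmur_amp, ", noise_sd ", x$noise_sd, ", seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# One heart-sound event: a sinusoid at freq under a smooth raised
# (Hann-squared) envelope with a mild exponential decay — the same shape
# every cycle, so event peaks recur at a fixed within-cycle offset.
sound_event <- function(t_rel, amp, freq, dur) {
  env <- sin(pi * t_rel / dur)^2 * exp(-2 * t_rel / dur)
  amp * env * sin(2 * pi * freq * t_rel)
}

#' Generate a synthetic phonocardiogram
#'
#' Renders the cardiac-cycle model of [pcg_params()] into a sampled signal:
#' each cycle holds an S1 event at cycle start, an S2 event
#' `event_duration + s1_s2_gap` later, optionally a band-limited murmur in
#' the systolic gap, with white sensor noise added throughout. Output is
#' deterministic given the parameter seed and leaves the global RNG state
#' untouched.
#'
#' @param params A [pcg_params()] object.
#' @return A [pcg_signal()] of length `round(duration * fs)`.
#' @examples
#' s <- generate_pcg(pcg_params(duration = 2))
#' s
#' @export
generate_pcg <- function(params) {
  if (!inherits(params, "pcg_params")) {
    stop("argument error: `params` must come from pcg_params()")
  }
  p <- params
  n <- round(p$duration * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  x <- numeric(n)
  cycle <- 60 / p$heart_rate
  n_cycles <- ceiling(p$duration / cycle)

  place_event <- function(x, t0, amp, freq) {
    if (amp == 0) return(x)
    i0 <- floor(t0 * p$fs) + 1L
    i1 <- min(n, ceiling((t0 + p$event_duration) * p$fs) + 1L)
    if (i0 > n) return(x)
    idx <- i0:i1
    tr <- t[idx] - t0
    keep <- tr >= 0 & tr <= p$event_duration
    x[idx[keep]] <- x[idx[keep]] +
      sound_event(tr[keep], amp, freq, p$event_duration)
    x
  }

  for (c in seq_len(n_cycles)) {
    t0 <- (c - 1) * cycle
    x <- place_event(x, t0, p$s1_amp, p$s1_freq)
    x <- place_event(x, t0 + p$event_duration + p$s1_s2_gap, p$s2_amp,
                     p$s2_freq)
  }

  x <- x + with_seed(p$seed, {
    noise <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else
      numeric(n)
    if (p$murmur_amp > 0) {
      # band-limited (100-400 Hz) noise, unit-sd, gated to the systolic gaps
      # by a raised-cosine window
      bp <- signal::butter(4, c(100, 400) / (p$fs / 2), type = "pass")
      mn <- signal::filtfilt(bp, stats::rnorm(n))
      mn <- mn / stats::sd(mn)
      gate <- numeric(n)
      for (c in seq_len(n_cycles)) {
        g0 <- (c - 1) * cycle + p$event_duration
        tr <- t - g0
        inside <- tr >= 0 & tr <= p$s1_s2_gap
        gate[inside] <- pmax(gate[inside], sin(pi * tr[inside] / p$s1_s2_gap)^2)
      }
      noise <- noise + p$murmur_amp * mn * gate
    }
    noise
  })
  label <- attr(params, "label")
  pcg_signal(x, fs = p$fs,
             source = if (is.null(label)) "synthetic" else
               paste0("synthetic:", label))
}

#' Calibrated simulator presets for screening experiments
#'
#' Two parameter sets calibrated so that, after the default
#' denoise-then-extract pipeline, the resulting features fall well inside
#' the published normal ("healthy") and abnormal ("unhealthy") threshold
#' ranges used by [default_thresholds()]. The healthy preset produces
#' strong S1/S2 sounds (absolute mean above 0.09, variance above 0.015,
#' wavelet energy far above 0.5e-5). The unhealthy preset models the
#' weak-heart-sound presentation: a near-silent record whose wavelet
#' energy stays below 2e-8 — a scale the abnormal energy bound forces,
#' since mean-square >= (mean absolute)^2 ties the energy bound to an
#' absolute mean of at most ~1.4e-4 — with a faint systolic murmur.
#'
#' @param name `"healthy"` or `"unhealthy"`.
#' @param seed Integer seed stored in the returned parameters.
#' @param duration Record length in seconds.
#' @return A [pcg_params()] object carrying a `label` attribute with the
#'   ground-truth class.
#' @examples
#' screen_pcg(generate_pcg(pcg_preset("healthy", seed = 1)))$overall
#' @export
pcg_preset <- function(name = c("healthy", "unhealthy"), seed = 0L,
                       duration = 10) {
  if (!is.character(name) || !(name[1L] %in% c("healthy", "unhealthy"))) {
    stop("argument error: unknown preset; use \"healthy\" or \"unhealthy\"")
  }
  name <- name[1L]
  p <- if (name == "healthy") {
    pcg_params(heart_rate = 72, s1_amp = 3.8, s2_amp = 3.0,
               s1_freq = 35, s2_freq = 60, event_duration = 0.12,
               s1_s2_gap = 0.25, murmur_amp = 0, noise_sd = 0.02,
               fs = 2000, duration = duration, seed = seed)
  } else {
    pcg_params(heart_rate = 80, s1_amp = 4e-4, s2_amp = 3e-4,
               s1_freq = 35, s2_freq = 60, event_duration = 0.12,
               s1_s2_gap = 0.24, murmur_amp = 1e-4, noise_sd = 1e-4,
               fs = 2000, duration = duration, seed = seed)
  }
  attr(p, "label") <- name
  p
}

#' Add white Gaussian noise to a signal
#'
#' Test harness for the denoising stage: returns the signal plus i.i.d.
#' Gaussian noise of standard deviation `sd`, reproducible given `seed`.
#'
#' @param signal A [pcg_signal()].
#' @param sd Noise standard deviation (>= 0); 0 returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @return A [pcg_signal()] with the same sampling rate.
#' @export
add_noise <- function(signal, sd, seed = 0L) {
  if (!inherits(signal, "pcg_signal")) {
    stop("argument error: `signal` must be a pcg_signal")
  }
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("argument error: `sd` must be a single value >= 0")
  }
  if (sd == 0) return(signal)
  noise <- with_seed(seed, stats::rnorm(length(signal$samples), 0, sd))
  pcg_signal(signal$samples + noise, fs = signal$fs,
             source = paste0(signal$source, " + noise(sd=", sd, ")"))
}
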