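#' Mean absolute amplitude
#'
#' `mean(abs(x))` over the whole record. A healthy heart sound, being
#' louder, has a larger absolute mean than a weak (unhealthy) one; this is
#' the first of the three screening statistics.
#'
#' @param signal A [pcg_signal()] or numeric vector.
#' @return A single nonnegative value.
#' @export
abs_mean <- function(signal) {
  x <- as_samples(signal)
  if (length(x) == 0L) stop("argument error: empty signal")
  mean(abs(x))
}

#' Amplitude variance (population)
#'
#' `mean((x - mean(x))^2)` — the population variance with divisor n,
#' matching the 1/n convention of the wavelet-energy statistic. Second of
#' the three screening statistics; healthy records have the larger
#' variance.
#'
#' @inheritParams abs_mean
#' @return A single nonnegative value.
#' @export
pcg_variance <- function(signal) {
  x <- as_samples(signal)
  if (length(x) == 0L) stop("argument error: empty signal")
  mean((x - mean(x))^2)
}

#' Mean wavelet-coefficient energy
#'
#' The energy statistic `sum(coefficients^2) / n`, where the sum runs over
#' every coefficient of a multilevel decomposition (the deepest
#' approximation band and all detail bands) and `n` is the analysed
#' signal's original sample count. For an orthogonal periodized transform
#' with no thresholding this equals the raw mean square `sum(x^2) / n`
#' (Parseval), and it stays well defined after detail bands have been
#' shrunk by denoising.
#'
#' @param decomp A `pcg_decomposition` from [pcg_decompose()].
#' @return A single nonnegative value (amplitude-squared units).
#' @export
dwt_energy <- function(decomp) {
  if (!inherits(decomp, "pcg_decomposition")) {
    stop("argument error: `decomp` must be a pcg_decomposition")
  }
  total <- sum(decomp$cA^2) + sum(vapply(decomp$cD,
                                         function(d) sum(d^2), numeric(1)))
  total / decomp$n_original
}

#' Extract the screening feature vector
#'
#' Computes the three discriminative statistics used for screening:
#' absolute mean, variance, and mean wavelet-coefficient energy. By
#' default the signal is first denoised ([pcg_denoise()]); the amplitude
#' statistics are then taken on the denoised samples and the energy on the
#' thresholded decomposition that produced them, mirroring the pipeline in
#' which denoising precedes analysis. With `denoise_first = FALSE` all
#' three are computed from the raw signal and its untouched decomposition.
#'
#' @param signal A [pcg_signal()].
#' @param wavelet Wavelet name or [wavelet_spec()] (default `"sym4"`).
#' @param level Decomposition depth (default 4).
#' @param denoise_first Logical; denoise before measuring (default TRUE).
#' @return An object of class `pcg_features`: list with `abs_mean`,
#'   `variance`, `dwt_energy`.
#' @examples
#' f <- extract_features(generate_pcg(pcg_preset("healthy")))
#' unlist(f)
#' @export
extract_features <- function(signal, wavelet = "sym4", level = 4L,
                             denoise_first = TRUE) {
  if (!inherits(signal, "pcg_signal")) {
    stop("argument error: `signal` must be a pcg_signal")
  }
  if (denoise_first) {
    den <- denoise_impl(signal, wavelet, level)
    sig <- den$signal
    dec <- den$decomposition
  } else {
    sig <- signal
    dec <- pcg_decompose(signal, wavelet, level)
  }
  structure(
    list(abs_mean = abs_mean(sig), variance = pcg_variance(sig),
         dwt_energy = dwt_energy(dec)),
    class = "pcg_features",
    denoised = denoise_first
  )
}

#' @export
print.pcg_features <- function(x, ...) {
  cat("<pcg_features>",
      if (isTRUE(attr(x, "denoised"))) "(after denoising)" else "(raw)", "\n")
  cat(sprintf("  abs_mean:   %.6g\n  variance:   %.6g\n  dwt_energy: %.6g\n",
              x$abs_mean, x$variance, x$dwt_energy))
  invisible(x)
}

#' Short-time Fourier spectrogram
#'
#' Magnitude of the short-time Fourier transform with a Hann window:
#' frames hop by `window_length - overlap` samples and the frequency axis
#' spans 0 to `fs / 2`. Defaults (256-sample window, 50% overlap at
#' 2000 Hz) give 128 ms frames — long enough to resolve the 30–70 Hz
#' S1/S2 content, short enough to separate events in time.
#'
#' @param signal A [pcg_signal()].
#' @param window_length Window length in samples (<= signal length).
#' @param overlap Overlap between consecutive windows in samples
#'   (`0 <= overlap < window_length`).
#' @return An object of class `pcg_spectrogram`: list with `times` (frame
#'   centres, seconds), `freqs` (bin centres, Hz), and `magnitudes`
#'   (frames x bins, nonnegative).
#' @export
pcg_spectrogram <- function(signal, window_length = 256L,
                            overlap = window_length %/% 2L) {
  if (!inherits(signal, "pcg_signal")) {
    stop("argument error: `signal` must be a pcg_signal")
  }
  n <- length(signal$samples)
  if (!is.numeric(window_length) || window_length < 2L || window_length > n) {
    stop("argument error: need 2 <= window_length <= signal length")
  }
  if (!is.numeric(overlap) || overlap < 0L || overlap >= window_length) {
    stop("argument error: need 0 <= overlap < window_length")
  }
  sp <- signal::specgram(signal$samples, n = window_length, Fs = signal$fs,
                         window = signal::hanning(window_length),
                         overlap = overlap)
  structure(
    list(times = as.numeric(sp$t), freqs = as.numeric(sp$f),
         magnitudes = t(Mod(sp$S))),
    class = "pcg_spectrogram"
  )
}

#' @export
print.pcg_spectrogram <- function(x, ...) {
  cat("<pcg_spectrogram> ", nrow(x$magnitudes), " frames x ",
      ncol(x$magnitudes), " bins (0-", max(x$freqs), " Hz)\n", sep = "")
  invisible(x)
}

#' @export
plot.pcg_spectrogram <- function(x, ...) {
  graphics::image(x$times, x$freqs, log1p(x$magnitudes),
                  xlab = "time [s]", ylab = "frequency [Hz]", ...)
  invisible(x)
}

#' Fit a normal distribution to the amplitude histogram
#'
#' Moment fit of the Gaussian bell curve to the amplitude distribution:
#' `mu` is the sample mean and `sigma` the population standard deviation.
#' The amplitude density of a quiet record is narrow (small sigma, tall
#' peak); a loud record spreads out. [gaussian_pdf()] evaluates the fitted
#' density; the degenerate `sigma = 0` case is defined as `Inf` at `mu`
#' and 0 elsewhere.
#'
#' @param signal A [pcg_signal()] or numeric vector of at least 2 samples.
#' @return An object of class `pcg_gaussian` with elements `mu`, `sigma`.
#' @export
fit_gaussian <- function(signal) {
  x <- as_samples(signal)
  if (length(x) < 2L) stop("argument error: need at least 2 samples")
  structure(list(mu = mean(x), sigma = sqrt(mean((x - mean(x))^2))),
            class = "pcg_gaussian")
}

#' @rdname fit_gaussian
#' @param fit A `pcg_gaussian` from [fit_gaussian()].
#' @param x Amplitude value(s) at which to evaluate the density.
#' @export
gaussian_pdf <- function(fit, x) {
  if (!inherits(fit, "pcg_gaussian")) {
    stop("argument error: `fit` must come from fit_gaussian()")
  }
  if (fit$sigma == 0) {
    return(ifelse(x == fit$mu, Inf, 0))
  }
  stats::dnorm(x, mean = fit$mu, sd = fit$sigma)
}

#' @export
print.pcg_gaussian <- function(x, ...) {
  cat(sprintf("<pcg_gaussian> mu = %.6g, sigma = %.6g\n", x$mu, x$sigma))
  invisible(x)
}
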