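#' Phonocardiogram signal container
#'
#' Bundles a sampled heart-sound amplitude series with its sampling rate.
#' Amplitudes are dimensionless and nominally in \[-1, 1\] (integer PCM audio
#' is rescaled on read); no gain normalisation is ever applied, because the
#' default screening thresholds (see [default_thresholds()]) are absolute
#' amplitude statistics and a gain step would invalidate them.
#'
#' @param samples Numeric vector of amplitudes; must be non-empty and finite.
#' @param fs Sampling rate in Hz; must be positive.
#' @param source Free-text provenance tag (file name, simulator preset, ...).
#'
#' @return An object of class `pcg_signal`: a list with elements `samples`,
#'   `fs` and `source`.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1 / 2000)), fs = 2000)
#' s
#' @export
pcg_signal <- function(samples, fs, source = "unknown") {
  if (!is.numeric(samples)) {
    stop("argument error: `samples` must be numeric")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("empty-input error: `samples` must contain at least one value")
  }
  if (!all(is.finite(samples))) {
    stop("validation error: `samples` must be finite (no NA/NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("argument error: `fs` must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         source = as.character(source)[1L]),
    class = "pcg_signal"
  )
}

#' @export
print.pcg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat("<pcg_signal> ", n, " samples @ ", x$fs, " Hz (",
      format(n / x$fs, digits = 4), " s)\n", sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  cat("  range: [", format(min(x$samples), digits = 4), ", ",
      format(max(x$samples), digits = 4), "], rms: ",
      format(sqrt(mean(x$samples^2)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) length(x$samples)

#' @export
plot.pcg_signal <- function(x, ..., xlab = "time [s]", ylab = "amplitude") {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = xlab, ylab = ylab,
                 main = x$source, ...)
  invisible(x)
}

# Accept either a pcg_signal or a bare numeric vector in feature helpers.
as_samples <- function(x) {
  if (inherits(x, "pcg_signal")) return(x$samples)
  if (is.numeric(x)) return(as.numeric(x))
  stop("argument error: expected a pcg_signal or a numeric vector")
}
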