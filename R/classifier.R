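#' Per-feature decision boundaries
#'
#' A pair of boundaries for one screening feature: values at or below
#' `unhealthy_max` are labelled unhealthy, values at or above `healthy_min`
#' healthy, and the open interval between them is indeterminate. The
#' boundaries are treated as belonging to their classes because they are
#' the extreme observed values of each class (the maximum over abnormal
#' samples and the minimum over normal samples).
#'
#' @param unhealthy_max Label unhealthy at or below this value.
#' @param healthy_min Label healthy at or above this value; must exceed
#'   `unhealthy_max`.
#' @return An object of class `feature_thresholds`.
#' @export
feature_thresholds <- function(unhealthy_max, healthy_min) {
  if (!is.numeric(unhealthy_max) || !is.numeric(healthy_min) ||
      length(unhealthy_max) != 1L || length(healthy_min) != 1L ||
      !is.finite(unhealthy_max) || !is.finite(healthy_min)) {
    stop("configuration error: thresholds must be single finite numbers")
  }
  if (unhealthy_max >= healthy_min) {
    stop("configuration error: unhealthy_max must be < healthy_min")
  }
  structure(list(unhealthy_max = unhealthy_max, healthy_min = healthy_min),
            class = "feature_thresholds")
}

#' Screening threshold configuration
#'
#' Bundles the per-feature decision boundaries for the three screening
#' statistics. The defaults are the published ranges for distinguishing
#' normal from abnormal heart sounds: absolute mean 0.07 / 0.09, variance
#' 0.01 / 0.015, wavelet energy 2e-8 / 0.5e-5 (each pair is
#' abnormal-maximum / normal-minimum). These are absolute amplitude
#' statistics — they presume un-normalised signal gain (see
#' [pcg_signal()]).
#'
#' @param mean,variance,energy [feature_thresholds()] for each feature.
#' @return An object of class `pcg_thresholds`.
#' @export
threshold_config <- function(mean = feature_thresholds(0.07, 0.09),
                             variance = feature_thresholds(0.01, 0.015),
                             energy = feature_thresholds(2e-8, 0.5e-5)) {
  for (th in list(mean, variance, energy)) {
    if (!inherits(th, "feature_thresholds")) {
      stop("configuration error: each member must come from feature_thresholds()")
    }
  }
  structure(list(mean = mean, variance = variance, energy = energy),
            class = "pcg_thresholds")
}

#' @rdname threshold_config
#' @export
default_thresholds <- function() threshold_config()

#' @export
print.pcg_thresholds <- function(x, ...) {
  cat("<pcg_thresholds> (unhealthy <= | indeterminate | healthy >=)\n")
  for (nm in names(x)) {
    cat(sprintf("  %-9s %.3g | %.3g\n", nm, x[[nm]]$unhealthy_max,
                x[[nm]]$healthy_min))
  }
  invisible(x)
}

#' Classify one feature value against its boundaries
#'
#' @param value Observed feature value.
#' @param thresholds A [feature_thresholds()] pair.
#' @return `"healthy"`, `"unhealthy"`, or `"indeterminate"`.
#' @examples
#' classify_feature(0.10, feature_thresholds(0.07, 0.09))  # healthy
#' classify_feature(0.08, feature_thresholds(0.07, 0.09))  # indeterminate
#' @export
classify_feature <- function(value, thresholds) {
  if (!inherits(thresholds, "feature_thresholds")) {
    stop("configuration error: `thresholds` must come from feature_thresholds()")
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("argument error: `value` must be a single number")
  }
  if (value >= thresholds$healthy_min) "healthy"
  else if (value <= thresholds$unhealthy_max) "unhealthy"
  else "indeterminate"
}

#' Combine per-feature verdicts into a screening result
#'
#' Labels each of the three features with [classify_feature()] and takes a
#' majority vote among the non-indeterminate verdicts: the overall label
#' is the strictly more frequent of healthy/unhealthy, and indeterminate
#' when neither has a strict majority (ties or all-indeterminate).
#'
#' @param features A `pcg_features` from [extract_features()].
#' @param config A [threshold_config()]; defaults to the published ranges.
#' @return An object of class `pcg_classification`: list with
#'   `per_feature` (named labels), `votes` (counts per label, summing
#'   to 3), `overall`, plus the `features` and `config` used.
#' @export
classify_pcg <- function(features, config = default_thresholds()) {
  if (!inherits(features, "pcg_features")) {
    stop("argument error: `features` must come from extract_features()")
  }
  if (!inherits(config, "pcg_thresholds")) {
    stop("configuration error: `config` must come from threshold_config()")
  }
  per_feature <- c(
    mean = classify_feature(features$abs_mean, config$mean),
    variance = classify_feature(features$variance, config$variance),
    energy = classify_feature(features$dwt_energy, config$energy)
  )
  labels <- c("healthy", "unhealthy", "indeterminate")
  votes <- vapply(labels, function(l) sum(per_feature == l), integer(1))
  overall <- if (votes[["healthy"]] > votes[["unhealthy"]]) "healthy"
  else if (votes[["unhealthy"]] > votes[["healthy"]]) "unhealthy"
  else "indeterminate"
  structure(
    list(per_feature = per_feature, votes = votes, overall = overall,
         features = features, config = config),
    class = "pcg_classification"
  )
}

#' @export
print.pcg_classification <- function(x, ...) {
  cat("<pcg_classification> overall: ", toupper(x$overall), "\n", sep = "")
  vals <- c(x$features$abs_mean, x$features$variance, x$features$dwt_energy)
  nms <- c("mean", "variance", "energy")
  for (i in seq_along(nms)) {
    cat(sprintf("  %-9s %-13s (value %.6g)\n", nms[i],
                x$per_feature[[nms[i]]], vals[i]))
  }
  cat("  votes: healthy ", x$votes[["healthy"]], ", unhealthy ",
      x$votes[["unhealthy"]], ", indeterminate ",
      x$votes[["indeterminate"]], "\n", sep = "")
  invisible(x)
}

#' End-to-end heart-sound screening
#'
#' The full pipeline on one recording: wavelet soft-threshold denoising
#' (sym4, level 4 by default), feature extraction, and threshold-rule
#' classification. The returned report carries the feature vector for
#' auditability.
#'
#' @param signal A [pcg_signal()].
#' @param config A [threshold_config()].
#' @param wavelet Wavelet name or [wavelet_spec()].
#' @param level Decomposition depth.
#' @param denoise_first Logical; denoise before feature extraction
#'   (default TRUE).
#' @return A `pcg_classification`, see [classify_pcg()].
#' @examples
#' screen_pcg(generate_pcg(pcg_preset("unhealthy")))
#' @export
screen_pcg <- function(signal, config = default_thresholds(),
                       wavelet = "sym4", level = 4L, denoise_first = TRUE) {
  features <- extract_features(signal, wavelet, level, denoise_first)
  classify_pcg(features, config)
}
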