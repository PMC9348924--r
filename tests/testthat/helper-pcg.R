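# Shared fixtures and independent oracles, built in code at test time.

# SNR of x against a clean reference, in dB.
snr_db <- function(clean, x) {
  10 * log10(sum(clean^2) / sum((x - clean)^2))
}

# Brute-force n x n analysis matrix for one periodized DWT level: row m is
# the lowpass filter circularly placed at offset 2(m-1), rows n/2+m the
# highpass. Built directly from the filter taps, independently of
# dwt_single()'s vectorised path.
dwt_analysis_matrix <- function(n, wavelet = "sym4") {
  w <- wavelet_spec(wavelet)
  L <- length(w$dec_lo)
  W <- matrix(0, n, n)
  for (m in seq_len(n / 2)) {
    for (k in seq_len(L)) {
      i <- (2 * (m - 1) + k - 1) %% n + 1
      W[m, i] <- W[m, i] + w$dec_lo[k]
      W[n / 2 + m, i] <- W[n / 2 + m, i] + w$dec_hi[k]
    }
  }
  W
}

# Independent minimal PCM16 WAV writer (supports multi-channel), so that
# read_wav() is tested against bytes it did not itself produce.
write_pcm16_wav <- function(path, channels, fs) {
  # `channels`: list of integer vectors (one per channel), values in
  # [-32768, 32767]
  frames <- length(channels[[1L]])
  nch <- length(channels)
  inter <- as.integer(do.call(rbind, channels))  # interleave
  data_bytes <- 2L * frames * nch
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(1L); w16(nch); w32(fs); w32(fs * 2L * nch)
  w16(2L * nch); w16(16L)
  writeChar("data", con, eos = NULL); w32(data_bytes)
  writeBin(inter, con, size = 2L, endian = "little")
  invisible(path)
}

# Construct a pcg_features object directly (for classifier unit tests).
make_features <- function(abs_mean, variance, dwt_energy) {
  structure(list(abs_mean = abs_mean, variance = variance,
                 dwt_energy = dwt_energy),
            class = "pcg_features")
}

# Locate S1 peaks on a noise-free, S1-only synthetic signal: local maxima
# above half the global maximum, clustered, one representative per cluster.
find_s1_peaks <- function(x, min_sep) {
  n <- length(x)
  is_peak <- x > 0.5 * max(x) &
    x >= c(-Inf, x[-n]) & x >= c(x[-1], Inf)
  pk <- which(is_peak)
  clusters <- split(pk, cumsum(c(1, diff(pk) > min_sep)))
  vapply(clusters, function(i) i[which.max(x[i])], numeric(1))
}

# Bisection recovery of a label boundary from classify_feature() alone.
# `target_label`: the label whose onset (as value increases) is sought.
bisect_boundary <- function(thresholds, target_label, lo, hi, iters = 80L) {
  is_target <- function(v) classify_feature(v, thresholds) == target_label
  stopifnot(!is_target(lo), is_target(hi))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (is_target(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Same, for a label that switches OFF as the value increases (unhealthy):
# returns the largest value still carrying the label.
bisect_boundary_upper <- function(thresholds, target_label, lo, hi,
                                  iters = 80L) {
  is_target <- function(v) classify_feature(v, thresholds) == target_label
  stopifnot(is_target(lo), !is_target(hi))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (is_target(mid)) lo <- mid else hi <- mid
  }
  lo
}
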