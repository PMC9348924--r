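test_that("abs_mean and variance follow their definitions", {
  expect_equal(abs_mean(c(1, -1, 1, -1)), 1.0)
  expect_equal(abs_mean(numeric(3) + 0), 0)
  expect_equal(abs_mean(c(0.2, -0.1, 0.3)), 0.2)
  expect_error(abs_mean(numeric(0)), "empty")

  expect_equal(pcg_variance(rep(4, 10)), 0)
  expect_equal(pcg_variance(c(1, -1)), 1.0)      # population divisor n
  expect_equal(pcg_variance(c(0, 1, 2)), 2 / 3)
  expect_error(pcg_variance(numeric(0)), "empty")
})

test_that("dwt_energy equals the raw mean square without thresholding", {
  d0 <- pcg_decompose(pcg_signal(numeric(32) + 0, 2000), level = 4)
  expect_equal(dwt_energy(d0), 0)

  d1 <- pcg_decompose(pcg_signal(rep(0.3, 64), 2000), level = 4)
  expect_lt(abs(dwt_energy(d1) - 0.09), 1e-9)

  set.seed(31)
  x <- rnorm(32)
  d2 <- pcg_decompose(pcg_signal(x, 2000), level = 4)
  expect_lt(abs(dwt_energy(d2) - sum(x^2) / 32), 1e-9)
})

test_that("extract_features handles degenerate and calibrated signals", {
  z <- extract_features(pcg_signal(numeric(64) + 0, 2000))
  expect_equal(unlist(z, use.names = FALSE), c(0, 0, 0))

  cst <- extract_features(pcg_signal(rep(0.5, 128), 2000))
  expect_lt(abs(cst$abs_mean - 0.5), 1e-9)
  expect_lt(cst$variance, 1e-9)
  expect_lt(abs(cst$dwt_energy - 0.25), 1e-9)

  # raw vs denoised paths agree on a noise-free record
  s <- generate_pcg(pcg_params(noise_sd = 0, duration = 2))
  raw <- extract_features(s, denoise_first = FALSE)
  expect_lt(abs(raw$dwt_energy - mean(s$samples^2)), 1e-9)
  expect_gte(raw$dwt_energy, raw$abs_mean^2)  # Jensen on one raw signal
})

test_that("spectrogram localises tones in frequency and time", {
  fs <- 2000
  z <- pcg_spectrogram(pcg_signal(numeric(1024) + 0, fs))
  expect_true(all(z$magnitudes == 0))
  expect_equal(dim(z$magnitudes), c(length(z$times), length(z$freqs)))

  t <- (0:8191) / fs
  tone <- pcg_signal(sin(2 * pi * 100 * t), fs)
  sp <- pcg_spectrogram(tone, window_length = 256)
  target_bin <- which.min(abs(sp$freqs - 100))
  peak_bins <- apply(sp$magnitudes, 1, which.max)
  expect_true(all(peak_bins == target_bin))

  # two disjoint tones: early frames near 50 Hz, late frames near 200 Hz
  x2 <- c(sin(2 * pi * 50 * t[1:4096]), sin(2 * pi * 200 * t[1:4096]))
  sp2 <- pcg_spectrogram(pcg_signal(x2, fs), window_length = 256)
  nf <- length(sp2$times)
  early <- apply(sp2$magnitudes[1:(nf %/% 3), ], 1, which.max)
  late <- apply(sp2$magnitudes[(2 * nf %/% 3):nf, ], 1, which.max)
  expect_true(all(abs(sp2$freqs[early] - 50) < 16))
  expect_true(all(abs(sp2$freqs[late] - 200) < 16))

  expect_error(pcg_spectrogram(tone, window_length = 0), "argument error")
  expect_error(pcg_spectrogram(tone, window_length = 256, overlap = 256),
               "argument error")
})

test_that("gaussian amplitude fit matches moments and closed-form pdf", {
  fit <- fit_gaussian(c(-1, 1))
  expect_equal(fit$mu, 0)
  expect_equal(fit$sigma, 1)
  expect_equal(gaussian_pdf(fit, 0), 1 / sqrt(2 * pi))
  d <- 0.37
  expect_equal(gaussian_pdf(fit, fit$mu + d), gaussian_pdf(fit, fit$mu - d))
  expect_error(fit_gaussian(0.5), "at least 2")

  # degenerate sigma = 0
  flat <- fit_gaussian(rep(0.2, 5))
  expect_identical(gaussian_pdf(flat, 0.2), Inf)
  expect_identical(gaussian_pdf(flat, 0.3), 0)

  set.seed(32)
  big <- fit_gaussian(rnorm(1e5, mean = 0.1, sd = 0.05))
  expect_lt(abs(big$mu - 0.1), 0.002)
  expect_lt(abs(big$sigma - 0.05) / 0.05, 0.02)
})

test_that("the quieter record has the taller amplitude-density peak", {
  set.seed(33)
  loud <- fit_gaussian(rnorm(5000, sd = 0.5))
  quiet <- fit_gaussian(rnorm(5000, sd = 0.01))
  expect_lt(gaussian_pdf(loud, loud$mu), gaussian_pdf(quiet, quiet$mu))
})

test_that("amplitude statistics are permutation-invariant", {
  set.seed(34)
  x <- rnorm(200)
  y <- sample(x)
  expect_equal(abs_mean(x), abs_mean(y))
  expect_equal(pcg_variance(x), pcg_variance(y))
})
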