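test_that("sym4 filter bank satisfies the orthonormality invariants", {
  w <- wavelet_spec("sym4")
  expect_length(w$dec_lo, 8L)
  expect_lt(abs(sum(w$dec_lo) - sqrt(2)), 1e-10)
  expect_lt(abs(sum(w$dec_hi)), 1e-10)
  expect_equal(w$rec_lo, rev(w$dec_lo))
  expect_error(wavelet_spec("db93"), "unknown wavelet")
})

test_that("single-level DWT matches the explicit orthogonal-matrix oracle", {
  set.seed(21)
  for (n in seq(8L, 32L, by = 2L)) {
    W <- dwt_analysis_matrix(n)
    # the brute-force matrix itself must be orthogonal
    expect_lt(max(abs(crossprod(W) - diag(n))), 1e-10)
    x <- rnorm(n)
    d <- dwt_single(x, mode = "periodization")
    ref <- as.numeric(W %*% x)
    expect_lt(max(abs(d$cA - ref[1:(n / 2)])), 1e-10)
    expect_lt(max(abs(d$cD - ref[(n / 2 + 1):n])), 1e-10)
  }
})

test_that("constants map to cA = c*sqrt(2), zeros map to zeros", {
  d <- dwt_single(rep(2.5, 8))
  expect_lt(max(abs(d$cA - 2.5 * sqrt(2))), 1e-10)
  expect_lt(max(abs(d$cD)), 1e-10)
  z <- dwt_single(numeric(16) + 0)
  expect_true(all(z$cA == 0) && all(z$cD == 0))
})

test_that("dwt/idwt argument errors are raised", {
  expect_error(dwt_single(numeric(0)), "empty")
  expect_error(dwt_single(rnorm(8), mode = "reflect"), "unknown boundary")
  expect_error(dwt_single(rnorm(7), mode = "periodization"), "even")
  expect_error(idwt_single(rnorm(4), rnorm(3)), "equal length")
})

test_that("single-level round trip is exact in both boundary modes", {
  set.seed(22)
  for (n in c(8L, 16L, 30L, 128L)) {
    x <- rnorm(n)
    d <- dwt_single(x, mode = "periodization")
    expect_lt(max(abs(idwt_single(d$cA, d$cD) - x)), 1e-10)
  }
  for (n in c(5L, 9L, 16L, 127L)) {
    x <- rnorm(n)
    d <- dwt_single(x, mode = "zero")
    r <- idwt_single(d$cA, d$cD, mode = "zero", n = n)
    expect_lt(max(abs(r - x)), 1e-10)
  }
})

test_that("multilevel cascade has the right shape and base case", {
  x <- pcg_signal(rnorm(64), 2000)
  d1 <- pcg_decompose(x, level = 1)
  s <- dwt_single(x$samples)
  expect_equal(d1$cA, s$cA)
  expect_equal(d1$cD[[1]], s$cD)

  d4 <- pcg_decompose(x, level = 4)
  expect_equal(lengths(d4$cD), c(4L, 8L, 16L, 32L))  # deepest first
  expect_length(d4$cA, 4L)
  expect_error(pcg_decompose(x, level = 7), "too deep")
  expect_error(pcg_decompose(x, level = 0), "positive integer")
})

test_that("multilevel decompose/reconstruct is a perfect inverse", {
  set.seed(23)
  for (n in c(16L, 40L, 333L, 1024L)) {
    x <- pcg_signal(rnorm(n), 2000)
    for (mode in c("periodization", "zero")) {
      d <- pcg_decompose(x, level = 4, mode = mode)
      r <- pcg_reconstruct(d, fs = 2000)
      expect_length(r, n)
      expect_lt(max(abs(r$samples - x$samples)), 1e-9)
    }
  }
})

test_that("coefficient energy obeys Parseval under periodization", {
  set.seed(24)
  for (n in c(32L, 100L, 1000L)) {
    x <- rnorm(n)
    d <- pcg_decompose(pcg_signal(x, 2000), level = 4)
    # compare per-sample energies so the tolerance is scale-meaningful
    expect_lt(abs(dwt_energy(d) - mean(x^2)), 1e-9)
  }
})

test_that("constants live in the approximation band", {
  x <- pcg_signal(rep(0.7, 64), 2000)
  d <- pcg_decompose(x, level = 4)
  d$cD <- lapply(d$cD, function(v) v * 0)
  r <- pcg_reconstruct(d, fs = 2000)
  expect_lt(max(abs(r$samples - 0.7)), 1e-9)
})

test_that("a Nyquist-alternating signal survives removal of cA", {
  x <- rep(c(1, -1), 16)
  d <- pcg_decompose(pcg_signal(x, 2000), level = 1)
  d$cA <- d$cA * 0
  r <- pcg_reconstruct(d, fs = 2000)
  expect_gte(sum(r$samples^2) / sum(x^2), 0.99)
})

test_that("mad_sigma matches its definition and is consistent", {
  expect_equal(mad_sigma(0.6745), 1.0)
  expect_equal(mad_sigma(numeric(5) + 0), 0)
  expect_error(mad_sigma(numeric(0)), "empty")
  set.seed(25)
  est <- mad_sigma(rnorm(1e5, sd = 2))
  expect_lt(abs(est - 2) / 2, 0.02)
})

test_that("universal threshold follows its closed form", {
  expect_equal(universal_threshold(3, 1), 0)
  expect_equal(universal_threshold(0, 1000), 0)
  n <- round(exp(2))
  expect_equal(universal_threshold(1, n), sqrt(2 * log(n)), tolerance = 1e-12)
  expect_error(universal_threshold(1, 0), "argument error")
  expect_error(universal_threshold(-1, 10), "argument error")
})

test_that("soft thresholding shrinks toward zero element-wise", {
  expect_equal(soft_threshold(c(1.0, -0.5, 0.2), 0.3), c(0.7, -0.2, 0.0))
  x <- c(-2, 0.1, 5)
  expect_equal(soft_threshold(x, 0), x)
  expect_true(all(soft_threshold(x, 5) == 0))
  expect_error(soft_threshold(x, -0.1), "argument error")
})

test_that("denoising is linear-degenerate on silence and constants", {
  z <- pcg_signal(numeric(64) + 0, 2000)
  expect_true(all(pcg_denoise(z)$samples == 0))
  cst <- pcg_signal(rep(0.4, 128), 2000)
  expect_lt(max(abs(pcg_denoise(cst)$samples - 0.4)), 1e-9)
})

test_that("denoising raises SNR on a noisy synthetic heart sound", {
  clean <- generate_pcg(pcg_params(noise_sd = 0, duration = 5, seed = 99))
  noisy <- add_noise(clean, sd = 0.05, seed = 1)
  den <- pcg_denoise(noisy)
  expect_gt(snr_db(clean$samples, den$samples),
            snr_db(clean$samples, noisy$samples))
  # global-threshold variant also runs and helps
  deng <- pcg_denoise(noisy, threshold_scope = "global")
  expect_gt(snr_db(clean$samples, deng$samples),
            snr_db(clean$samples, noisy$samples))
})

test_that("soft shrinkage in an orthogonal basis never expands the norm", {
  set.seed(26)
  for (i in 1:50) {
    n <- sample(c(64L, 100L, 256L), 1)
    x <- pcg_signal(rnorm(n, sd = runif(1, 0.01, 2)), 2000)
    den <- pcg_denoise(x, level = sample(1:4, 1))
    expect_lte(sqrt(sum(den$samples^2)), sqrt(sum(x$samples^2)) + 1e-9)
  }
})
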