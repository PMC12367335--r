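test_that("filter banks satisfy the orthonormal wavelet identities", {
  for (name in list_wavelets()) {
    spec <- wavelet_spec(name)
    L <- length(spec$dec_lo)
    expect_true(L %% 2 == 0 && L >= 2)
    expect_equal(sum(spec$dec_lo), sqrt(2), tolerance = 1e-10)
    expect_equal(sum(spec$dec_lo^2), 1, tolerance = 1e-12)
    # quadrature mirror: alternating-sign time reversal
    expect_equal(spec$dec_hi, rev(spec$dec_lo) * (-1)^(seq_len(L) - 1),
                 tolerance = 1e-12)
    # even-shift orthogonality of the low-pass filter
    if (L > 2) {
      for (s in seq(2, L - 2, by = 2)) {
        expect_equal(sum(spec$dec_lo[seq_len(L - s)] * spec$dec_lo[(s + 1):L]), 0,
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(wavelet_spec("sym97"), "unknown wavelet")
})

test_that("Haar analysis of a constant block gives sqrt(2)-scaled approximations", {
  out <- analysis_step(c(1, 1, 1, 1), wavelet_spec("haar"), "periodic")
  expect_equal(out$approx, c(sqrt(2), sqrt(2)))
  expect_equal(out$detail, c(0, 0))
  out0 <- analysis_step(c(1, 1, 1, 1), wavelet_spec("haar"), "zero")
  expect_equal(out0$approx, c(sqrt(2), sqrt(2)))
})

test_that("constant signals map to c*sum(dec_lo) approximations and zero details", {
  for (name in c("haar", "db2", "db4")) {
    spec <- wavelet_spec(name)
    out <- analysis_step(rep(3.5, 32), spec, "symmetric")
    expect_equal(out$approx, rep(3.5 * sum(spec$dec_lo), 16), tolerance = 1e-12)
    expect_equal(out$detail, rep(0, 16), tolerance = 1e-12)
  }
})

test_that("the analysis step is linear", {
  set.seed(31)
  spec <- wavelet_spec("db2")
  for (rep_ in 1:5) {
    x <- rnorm(20); y <- rnorm(20); a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lhs <- analysis_step(a * x + b * y, spec, "periodic")
    rx <- analysis_step(x, spec, "periodic")
    ry <- analysis_step(y, spec, "periodic")
    expect_equal(lhs$approx, a * rx$approx + b * ry$approx, tolerance = 1e-12)
    expect_equal(lhs$detail, a * rx$detail + b * ry$detail, tolerance = 1e-12)
  }
})

test_that("analysis matches the brute-force pad-convolve-downsample oracle", {
  set.seed(7)
  specs <- lapply(c("haar", "db2", "db4"), wavelet_spec)
  modes <- c("symmetric", "zero", "periodic")
  for (rep_ in 1:100) {
    spec <- specs[[1 + rep_ %% 3]]
    mode <- modes[1 + rep_ %% 2]
    n <- sample(length(spec$dec_lo):64, 1)
    x <- rnorm(n)
    got <- analysis_step(x, spec, mode)
    want <- oracle_analysis(x, spec, mode)
    expect_lt(max(abs(got$approx - want$approx)), 1e-10)
    expect_lt(max(abs(got$detail - want$detail)), 1e-10)
  }
})

test_that("orthogonal filter banks reconstruct perfectly under periodic padding", {
  set.seed(11)
  for (name in c("haar", "db2", "db4")) {
    spec <- wavelet_spec(name)
    x <- rnorm(64)
    st <- analysis_step(x, spec, "periodic")
    expect_lt(max(abs(synthesis_step(st$approx, st$detail, spec, 64) - x)), 1e-8)
    # multi-level round trip with details retained at each stage
    for (level in 1:3) {
      stack <- list(); cur <- x
      for (j in seq_len(level)) {
        st <- analysis_step(cur, spec, "periodic")
        stack[[j]] <- st$detail
        cur <- st$approx
      }
      for (j in rev(seq_len(level))) {
        cur <- synthesis_step(cur, stack[[j]], spec)
      }
      expect_lt(max(abs(cur - x)), 1e-8)
    }
  }
})

test_that("analysis conserves energy under periodic padding (Parseval)", {
  set.seed(13)
  for (name in c("haar", "db4")) {
    spec <- wavelet_spec(name)
    x <- rnorm(128)
    st <- analysis_step(x, spec, "periodic")
    expect_equal(sum(st$approx^2) + sum(st$detail^2), sum(x^2), tolerance = 1e-8)
  }
})

test_that("synthesis of all-zero coefficients is all-zero and validates lengths", {
  spec <- wavelet_spec("db2")
  expect_equal(synthesis_step(numeric(8), numeric(8), spec), numeric(16))
  expect_error(synthesis_step(numeric(8), numeric(7), spec), "same length")
})

test_that("denoise handles identity, constants and minimum-length errors", {
  x <- rnorm(40)
  expect_identical(denoise(x, denoise_config(level = 0)), x)
  out <- denoise(rep(2.5, 32), denoise_config(level = 2, wavelet = "haar"))
  expect_equal(out, rep(5, 8), tolerance = 1e-12)  # c * (sqrt 2)^2
  expect_error(denoise(rnorm(6), denoise_config(level = 2, wavelet = "db4")),
               "minimum")
  expect_error(analysis_step(rnorm(4), wavelet_spec("db4")), "too short")
  expect_error(analysis_step(c(1, NA, 3, 4, 5, 6, 7, 8), wavelet_spec("db4")),
               "non-finite")
})

test_that("a clean low-frequency sinusoid is less distorted than a noisy one", {
  set.seed(17)
  n <- 256
  clean <- sin(2 * pi * (1:n) / 64)
  cfg <- denoise_config(level = 2, output_mode = "reconstruction",
                        padding_mode = "periodic")
  rel_l2 <- function(x) sqrt(sum((denoise(x, cfg) - clean)^2) / sum(clean^2))
  noisy <- clean + rnorm(n, sd = 1)
  expect_lt(rel_l2(clean), rel_l2(noisy))
})

test_that("reconstruction-mode denoising suppresses white noise around a smooth trend", {
  set.seed(19)
  cfg <- denoise_config(level = 2, output_mode = "reconstruction")
  wins <- 0L
  for (r in 1:20) {
    n <- 144
    trend <- 80 + 5 * sin(2 * pi * (1:n) / 96) + 0.01 * (1:n)
    x <- trend + rnorm(n, sd = 3)
    mse_raw <- mean((x - trend)^2)
    mse_den <- mean((denoise(x, cfg) - trend)^2)
    wins <- wins + (mse_den < mse_raw)
  }
  expect_equal(wins, 20L)
})

test_that("low-pass denoising preserves a constant offset (DC gain one)", {
  set.seed(23)
  x <- rnorm(96)
  for (mode in c("symmetric", "periodic")) {
    cfg <- denoise_config(level = 2, output_mode = "reconstruction",
                          padding_mode = mode)
    expect_equal(denoise(x + 7.5, cfg), denoise(x, cfg) + 7.5, tolerance = 1e-10)
  }
})
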