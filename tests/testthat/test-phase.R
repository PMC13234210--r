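test_that("bandpass preserves in-band and attenuates out-of-band sinusoids", {
  t <- (0:239) * 2
  in_band <- cos(2 * pi * 0.05 * t)
  out_band <- cos(2 * pi * 0.2 * t)
  x <- cbind(a = in_band, b = out_band)

  y <- bandpass(x, tr = 2, low_hz = 0.01, high_hz = 0.1)
  interior <- 30:210
  envelope <- function(col) {  # analytic-signal amplitude
    n <- length(col)
    h <- numeric(n)
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
    Mod(fft(fft(col) * h, inverse = TRUE) / n)
  }
  expect_lt(max(abs(envelope(y[, "a"])[interior] - 1)), 0.05)
  # >= 10 dB attenuation at 0.2 Hz
  expect_lt(max(envelope(y[, "b"])[interior]), 10^(-10 / 20))

  # constant signal is removed entirely with the mean
  expect_equal(max(abs(bandpass(matrix(5, 100, 2), tr = 2))), 0,
               tolerance = 1e-9)

  expect_error(bandpass(x, tr = 2, low_hz = 0.1, high_hz = 0.3),
               class = "leidar_invalid_band")
  expect_error(bandpass(x, tr = 2, low_hz = 0.1, high_hz = 0.05),
               class = "leidar_invalid_band")
})

test_that("instantaneous phase of a cosine follows the analytic formula", {
  t_idx <- 0:239
  x <- cos(2 * pi * 0.05 * t_idx * 2)
  theta <- instantaneous_phase(cbind(x, x))
  interior <- 10:230
  expected <- (2 * pi * 0.05 * t_idx * 2)[interior]
  delta <- Arg(exp(1i * (theta[interior, 1] - expected)))
  expect_lt(max(abs(delta)), 0.05)
  # identical columns give identical phases
  expect_identical(theta[, 1], theta[, 2])

  degenerate <- cbind(roiA = x, roiB = rep(0, 240))
  err <- expect_error(instantaneous_phase(degenerate),
                      class = "leidar_degenerate_signal")
  expect_match(conditionMessage(err), "roiB")
})

test_that("phase-locking frames follow cos(theta_n - theta_p)", {
  f <- phase_locking_matrix(c(0, 0, pi))
  expect_equal(f, rbind(c(1, 1, -1), c(1, 1, -1), c(-1, -1, 1)),
               tolerance = 1e-12)
  expect_equal(phase_locking_matrix(c(0, pi / 3))[1, 2], 0.5,
               tolerance = 1e-12)
  expect_equal(phase_locking_matrix(rep(1.3, 4)),
               matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("phase-locking frames are symmetric with unit diagonal on random data", {
  set.seed(5)
  for (i in 1:20) {
    f <- phase_locking_matrix(runif(12, -pi, pi))
    expect_equal(f, t(f), tolerance = 1e-12)
    expect_equal(diag(f), rep(1, 12), tolerance = 1e-12)
    expect_true(all(f >= -1 - 1e-12 & f <= 1 + 1e-12))
  }
})

test_that("leading eigenvector matches hand-computed cases and sign convention", {
  v <- leading_eigenvector(matrix(1, 3, 3))
  expect_equal(as.numeric(v), rep(-1, 3) / sqrt(3), tolerance = 1e-9)

  v <- leading_eigenvector(rbind(c(1, 0.5), c(0.5, 1)))
  expect_equal(as.numeric(v), c(-1, -1) / sqrt(2), tolerance = 1e-9)

  v <- leading_eigenvector(phase_locking_matrix(c(0, 0, pi)))
  expect_equal(as.numeric(v), c(-1, -1, 1) / sqrt(3), tolerance = 1e-9)
})

test_that("leading eigenvector agrees with a power-iteration oracle", {
  set.seed(11)
  for (n in c(3, 4, 6)) {
    for (rep in 1:10) {
      a <- matrix(rnorm(n * n), n)
      m <- (a + t(a)) / 2
      v <- leading_eigenvector(m)
      expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
      expect_lte(mean(v), 0)
      o <- power_iteration_eigenvector(m)
      expect_gt(abs_cosine(v, o), 1 - 1e-9)
    }
  }
})

test_that("eigenvector series trims edges and recovers noiseless patterns", {
  states <- make_planted_states(20, 2, seed = 3)
  x <- synthesize_subject(rep(1L, 240), states, phase_noise_kappa = Inf,
                          amplitude_noise_sd = 0, seed = 1)
  es <- eigenvector_series(x, tr = 2)
  expect_equal(nrow(es$v1), 238)
  expect_equal(es$kept, 2:239)
  sims <- apply(es$v1, 1, abs_cosine, b = states[1, ])
  expect_true(all(sims >= 0.999))
  # unit norm and sign convention on every row
  expect_equal(sqrt(rowSums(es$v1^2)), rep(1, 238), tolerance = 1e-9)
  expect_true(all(rowMeans(es$v1) <= 1e-12))

  es0 <- eigenvector_series(x, tr = 2, trim_edges = 0)
  expect_equal(nrow(es0$v1), 240)

  # the rank-2 fast path agrees with the generic symmetric eigensolver
  theta <- instantaneous_phase(bandpass(x, tr = 2))
  for (t in c(5, 100, 200)) {
    v_generic <- leading_eigenvector(phase_locking_matrix(theta[t, ]))
    expect_gt(abs_cosine(es0$v1[t, ], v_generic), 1 - 1e-9)
  }
})
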