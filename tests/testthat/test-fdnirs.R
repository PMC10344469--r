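test_that("modulation QC retains and rejects frames per the 20% rule", {
  rec <- fd_record(c(9, 18, 27, 36),
                   AC = matrix(0.5, 3, 4), DC = matrix(1, 3, 4),
                   phase = matrix(0.1, 3, 4))
  expect_true(all(qc_modulation(rec)))
  AC <- matrix(0.5, 3, 4); AC[2, 3] <- 0.19
  rec2 <- fd_record(c(9, 18, 27, 36), AC, matrix(1, 3, 4),
                    matrix(0.1, 3, 4))
  expect_equal(qc_modulation(rec2), c(TRUE, FALSE, TRUE))
  # mixed record vs brute-force elementwise oracle
  set.seed(3)
  AC <- matrix(runif(40, 0.05, 0.6), 10, 4)
  DC <- matrix(1, 10, 4)
  rec3 <- fd_record(c(9, 18, 27, 36), AC, DC, matrix(0, 10, 4))
  oracle <- vapply(1:10, function(i) all(AC[i, ] / DC[i, ] > 0.2),
                   logical(1))
  expect_equal(as.logical(qc_modulation(rec3)), oracle)
  # saturated and non-finite frames are rejected
  DC <- matrix(1, 3, 4); DC[2, 1] <- 70000
  rec_sat <- fd_record(c(9, 18, 27, 36), matrix(0.5, 3, 4), DC,
                       matrix(0, 3, 4))
  expect_equal(qc_modulation(rec_sat, saturation = 65535),
               c(TRUE, FALSE, TRUE))
  ph <- matrix(0, 3, 4); ph[3, 2] <- NaN
  rec_nan <- fd_record(c(9, 18, 27, 36), matrix(0.5, 3, 4),
                       matrix(1, 3, 4), ph)
  expect_equal(qc_modulation(rec_nan), c(TRUE, TRUE, FALSE))
  # all rejected -> flagged empty, no exception
  rec4 <- fd_record(c(9, 18), AC = matrix(0.1, 1, 2), DC = matrix(1, 1, 2),
                    phase = matrix(0, 1, 2))
  m <- qc_modulation(rec4)
  expect_false(any(m))
  expect_true(attr(m, "empty"))
})

test_that("multi-distance fit inverts the semi-infinite FD model on a grid", {
  for (ma in c(0.005, 0.015, 0.03)) for (ms in c(0.5, 1, 2)) {
    f <- multi_distance_fit(simulate_fd_record(ma, ms))
    expect_rel_equal(f$mu_a_mean, ma, 0.05)
    expect_rel_equal(f$mu_s_prime_mean, ms, 0.05)
  }
})

test_that("multi-distance fit is gain- and phase-offset-invariant", {
  rec <- simulate_fd_record(0.012, 1.2)
  f0 <- multi_distance_fit(rec)
  rec2 <- rec; rec2$AC <- 2 * rec$AC
  f2 <- multi_distance_fit(rec2)
  expect_equal(f2$mu_a_mean, f0$mu_a_mean)
  expect_equal(f2$mu_s_prime_mean, f0$mu_s_prime_mean)
  rec3 <- rec; rec3$phase <- rec$phase + 0.7
  f3 <- multi_distance_fit(rec3)
  expect_equal(f3$mu_a_mean, f0$mu_a_mean)
  expect_equal(f3$mu_s_prime_mean, f0$mu_s_prime_mean)
})

test_that("wrong-sign slopes are flagged as estimation failures", {
  rec <- simulate_fd_record(0.01, 1)
  rec$AC[1, ] <- rev(rec$AC[1, ])  # increasing ln(r^2 AC): S_AC > 0
  f <- multi_distance_fit(rec)
  expect_false(f$ok[1])
  expect_true(is.na(f$mu_a[1]))
})

test_that("robust median removes 1.5-IQR outliers and otherwise matches median", {
  expect_equal(robust_median(c(1, 1, 1, 1, 100)), 1)
  expect_equal(robust_median(rep(7, 5)), 7)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(robust_median(x), median(x))
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(30)
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    if (all(x >= q[1] - 1.5 * diff(q) & x <= q[2] + 1.5 * diff(q)))
      expect_equal(robust_median(x), median(x))
  }
  expect_error(robust_median(NA_real_), "finite")
})

test_that("boxcar smoothing matches the convolution oracle with edge truncation", {
  grid <- seq(350, 1000, length.out = 201)
  spec <- absorbance_spectrum(grid, rep(2.5, 201))
  expect_equal(smooth_boxcar(spec, 15)$absorbance, rep(2.5, 201))
  imp <- rep(0, 201); imp[100] <- 1
  sm <- smooth_boxcar(absorbance_spectrum(grid, imp), 15)
  expect_equal(sm$absorbance[93:107], rep(1 / 15, 15))
  expect_equal(sm$absorbance[c(92, 108)], c(0, 0))
  y <- sin(grid / 30)
  expect_equal(smooth_boxcar(absorbance_spectrum(grid, y), 1)$absorbance, y)
  expect_error(smooth_boxcar(absorbance_spectrum(grid, y), 4), "odd")
  expect_error(smooth_boxcar(absorbance_spectrum(grid[1:5], y[1:5]), 7),
               "length")
})

test_that("absorbance calibration recovers the affine map from anchors", {
  b <- fix_basis()
  lam <- seq(650, 950, by = 1)
  mu <- compose_mu_a(tissue_composition(0.006, 0.98, 0.1, 2e-5, 0.2), b, lam)
  spec <- absorbance_spectrum(lam, mu)
  anchors <- data.frame(lambda = seq(710, 890, by = 30),
                        mu_a = approx(lam, mu, seq(710, 890, by = 30))$y)
  cal <- calibrate_absorbance(spec, anchors)
  expect_equal(cal$gain, 1, tolerance = 1e-8)
  expect_equal(cal$offset, 0, tolerance = 1e-10)
  spec2 <- absorbance_spectrum(lam, 2 * mu + 3)
  cal2 <- calibrate_absorbance(spec2, anchors)
  expect_equal(cal2$gain, 0.5, tolerance = 1e-8)
  expect_equal(cal2$offset, -1.5, tolerance = 1e-8)
  expect_equal(cal2$mu_a, mu, tolerance = 1e-8)
  expect_error(calibrate_absorbance(spec, anchors[1, , drop = FALSE]),
               "2 anchors")
})

test_that("composition fit round-trips the fitted blubber weights", {
  b <- fix_basis()
  lam <- 700:900
  truth <- c(B = 0.006, S = 0.98, W = 0.1, M = 0.00002, F = 0.2)
  y <- compose_mu_a(tissue_composition(truth["B"], truth["S"], truth["W"],
                                       truth["M"], truth["F"]), b, lam)
  fit <- fit_composition(lam, y, b)
  got <- unlist(fit$composition[c("B", "S", "W", "M", "F")])
  expect_true(all(abs(got - truth) < 1e-3))
  expect_lt(fit$residual, 1e-10 * sum(y^2))
})

test_that("composition fit achieves zero residual on in-bounds spectra", {
  b <- fix_basis()
  lam <- seq(700, 900, by = 2)
  set.seed(5)
  for (i in 1:5) {
    truth <- c(B = runif(1, 0, 0.05), S = runif(1), W = runif(1, 0.1, 0.9),
               M = runif(1, 0, 1e-4), F = runif(1, 0.2, 0.8))
    y <- compose_mu_a(as.list(truth), b, lam)
    fit <- fit_composition(lam, y, b)
    expect_lt(fit$residual, 1e-10 * sum(y^2))
  }
})

test_that("composition fit handles constructed and degenerate spectra", {
  b <- fix_basis()
  lam <- seq(700, 900, by = 1)
  y <- 0.5 * basis_mu_a(b, "water", lam) + 0.2 * basis_mu_a(b, "fat", lam)
  fit <- fit_composition(lam, y, b)
  expect_equal(fit$composition$W, 0.5, tolerance = 1e-6)
  fz <- fit_composition(lam, rep(0, length(lam)), b)
  expect_equal(fz$composition$B, 0)
  expect_equal(fz$composition$W, 0.1)
  expect_equal(fz$composition$M, 0)
  expect_equal(fz$composition$F, 0.2)
  expect_error(fit_composition(seq(750, 850, 1), rep(0.01, 101), b),
               "700-900")
})

test_that("power-law fit recovers coefficients exactly on noiseless data", {
  lam <- seq(700, 900, length.out = 21)
  fit <- fit_power_law(lam, power_law_mus(1546, 0.8038, lam))
  expect_rel_equal(fit$a, 1546, 1e-6)
  expect_rel_equal(fit$b, 0.8038, 1e-6)
  # two points: closed-form log-log interpolation
  l2 <- c(700, 900); y2 <- c(0.9, 0.6)
  f2 <- fit_power_law(l2, y2)
  bb <- -log(y2[2] / y2[1]) / log(l2[2] / l2[1])
  expect_equal(f2$b, bb, tolerance = 1e-9)
  expect_equal(f2$a, y2[1] * l2[1]^bb, tolerance = 1e-6)
  # order invariance
  set.seed(6)
  lam <- seq(700, 900, by = 25)
  y <- power_law_mus(1200, 1.1, lam) * exp(rnorm(length(lam), 0, 0.02))
  o <- sample(length(lam))
  f1 <- fit_power_law(lam, y); f2 <- fit_power_law(lam[o], y[o])
  expect_equal(f1$a, f2$a, tolerance = 1e-5)
  expect_equal(f1$b, f2$b, tolerance = 1e-6)
  expect_error(fit_power_law(lam, -y), "> 0")
})

test_that("FD record IO round-trips through CSV", {
  rec <- simulate_fd_record(0.01, 1, n_frames = 3, noise_sd = 0.01, seed = 9)
  tab <- expand.grid(time_s = 1:3, distance_mm = rec$distances)
  tab$AC <- as.vector(rec$AC); tab$DC <- as.vector(rec$DC)
  tab$phase_rad <- as.vector(rec$phase)
  path <- tempfile(fileext = ".csv")
  writeLines(c("# mod_freq_hz: 130e6", "# medium_ri: 1.4"), path)
  suppressWarnings(write.table(tab, path, sep = ",", row.names = FALSE,
                               append = TRUE, quote = FALSE))
  rec2 <- read_fd_csv(path)
  expect_equal(rec2$AC, rec$AC, ignore_attr = TRUE)
  expect_equal(rec2$mod_freq, 130e6)
  f1 <- multi_distance_fit(rec); f2 <- multi_distance_fit(rec2)
  expect_equal(f1$mu_a_mean, f2$mu_a_mean)
})
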