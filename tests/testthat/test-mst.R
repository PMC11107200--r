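test_that("Fnorm is the hot/cold ratio in per-mil", {
  tm <- seq(-2, 21, 0.05)
  const <- mst_trace(tm, rep(800, length(tm)), 1e-9)
  expect_equal(fnorm(const), 1000)
  stepped <- mst_trace(tm, ifelse(tm < 5, 800, 0.95 * 800), 1e-9)
  expect_equal(fnorm(stepped), 950)
  expect_error(fnorm(const, cold_window = c(-5, 0)), "support")
  expect_error(fnorm(const, cold_window = c(0, 20), hot_window = c(10, 21)),
               "overlap")
  dead <- mst_trace(tm, rep(0, length(tm)), 0)
  expect_error(fnorm(dead), "cold-window")
})

test_that("trace-derived responses match direct arithmetic on the arrays", {
  m <- make_mst(kd = 50e-9, probe = 625e-12, noise = 0)
  got <- vapply(m$traces, fnorm, numeric(1))
  direct <- vapply(m$traces, function(tr) {
    1000 * mean(tr$fluorescence[tr$time >= 19 & tr$time <= 20]) /
      mean(tr$fluorescence[tr$time >= -1 & tr$time <= 0])
  }, numeric(1))
  expect_equal(got, direct, tolerance = 1e-12)
  expect_equal(got, m$delta_fnorm, tolerance = 1e-3)
})

test_that("a noiseless synthetic curve is recovered essentially exactly", {
  m <- make_mst(kd = 50e-9, probe = 625e-12, noise = 0)
  fit <- fit_kd(m$concentrations, m$delta_fnorm, probe_conc = 625e-12)
  expect_equal(fit$kd, 50e-9, tolerance = 1e-6)
  expect_equal(fit$amplitude, -20, tolerance = 1e-6)
  expect_equal(fit$baseline, 940, tolerance = 1e-6)
  expect_false(fit$kd_is_lower_limit)
})

test_that("zero-amplitude data raise a no-binding error", {
  m <- make_mst(kd = 50e-9, probe = 625e-12, amplitude = 0, noise = 0)
  expect_error(fit_kd(m$concentrations, m$delta_fnorm, 625e-12),
               "no binding")
})

test_that("a Kd below the probe concentration is flagged as a lower limit", {
  m <- make_mst(kd = 100e-12, probe = 625e-12, noise = 0)
  fit <- fit_kd(m$concentrations, m$delta_fnorm, probe_conc = 625e-12)
  expect_true(fit$kd_is_lower_limit)
  expect_lte(fit$kd, 625e-12)
})

test_that("the depletion model converges to the hyperbolic isotherm for small probe", {
  kd <- 10e-9
  conc <- 10^seq(-10.5, -6, length.out = 12)
  hyper <- conc / (conc + kd)
  quad <- cblpocket:::.bound_fraction(conc, kd / 1000, kd)
  expect_equal(quad, hyper, tolerance = 0.01)
})

test_that("fit quality degrades gracefully with 5 percent noise", {
  kds <- vapply(1:60, function(seed) {
    m <- make_mst(kd = 50e-9, probe = 625e-12, noise = 0.05, seed = seed)
    fit_kd(m$concentrations, m$delta_fnorm, 625e-12)$kd
  }, numeric(1))
  ratio <- median(kds) / 50e-9
  expect_lt(max(ratio, 1 / ratio), 1.5)
})

test_that("input contracts are enforced", {
  expect_error(fit_kd(c(1e-9, 2e-9, 4e-9, 8e-9, 16e-9), rep(1, 5), 1e-12),
               "at least 6")
  conc <- seq(1e-9, 2e-9, length.out = 8)
  expect_error(fit_kd(conc, rnorm(8), 1e-12), "orders of magnitude")
})

test_that("the fitted model behaves like a classed R model object", {
  m <- make_mst(kd = 20e-9, probe = 625e-12, noise = 0.02, seed = 3)
  fit <- fit_kd(m$concentrations, m$delta_fnorm, 625e-12)
  expect_s3_class(fit, "kd_fit")
  cf <- coef(fit)
  expect_named(cf, c("kd", "amplitude", "baseline"))
  expect_equal(length(fitted(fit)), 16)
  expect_equal(length(residuals(fit)), 16)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-9)
  # predictions at the fitted Kd sit halfway up the saturable part
  # (up to depletion), and extreme dilution returns the baseline
  expect_equal(predict(fit, 1e-15), fit$baseline, tolerance = 1e-3)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(16L, 3L))
  expect_output(print(fit), "binding fit")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("binding_curve composes trace reduction and fitting", {
  m <- make_mst(kd = 5e-9, probe = 625e-12, noise = 0)
  fit <- binding_curve(m$traces, probe_conc = 625e-12)
  expect_equal(fit$kd, 5e-9, tolerance = 1e-2)
})
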