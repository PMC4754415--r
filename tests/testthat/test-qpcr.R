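test_that("noiseless four-parameter logistic is recovered to < 1e-3 relative error", {
  truth <- list(b = 3, L = 95, m = 24.5, k = 0.62)
  cc <- make_logistic_curve(truth$b, truth$L, truth$m, truth$k)
  fit <- fit_amplification(cc)
  expect_true(fit$ok)
  expect_lt(abs(fit$baseline - truth$b) / truth$b, 1e-3)
  expect_lt(abs(fit$amplitude - truth$L) / truth$L, 1e-3)
  expect_lt(abs(fit$midpoint - truth$m) / truth$m, 1e-3)
  expect_lt(abs(fit$rate - truth$k) / truth$k, 1e-3)
  expect_lt(fit$rms_residual, 1e-4)
})

test_that("flat curves are flagged as non-amplifying", {
  cc <- data.frame(cycle = 1:40, fluorescence = rep(5, 40))
  fit <- fit_amplification(cc)
  expect_false(fit$ok)
  expect_true("no_amplification" %in% fit$flags)
  expect_true(is.na(fit$midpoint))
})

test_that("midpoint is recovered within 0.25 cycles under 1% plateau noise", {
  truth <- list(b = 2, L = 100, m = 26, k = 0.66)
  errs <- withr::with_seed(42, vapply(1:100, function(i) {
    cc <- make_logistic_curve(truth$b, truth$L, truth$m, truth$k)
    cc$fluorescence <- cc$fluorescence + stats::rnorm(40, sd = 1)
    fit_amplification(cc)$midpoint - truth$m
  }, numeric(1)))
  expect_lt(max(abs(errs)), 0.25)
})

test_that("efficiency and CT are recovered from noiseless forward curves", {
  for (E in c(0.85, 1.0)) {
    k <- default_kinetics(); k$E_true <- E; k$noise_sd <- 0; k$n_cycles <- 45
    cc <- simulate_amplification_curves(1, k, seed = 1)
    fit <- fit_amplification(cc)
    m <- estimate_efficiency_ct(cc, fit)
    expect_lt(abs(m$E - E), 0.03)
    expect_true(m$CT > min(cc$cycle) && m$CT < max(cc$cycle))
    expect_equal(m$R0, exp(-m$CT * log1p(m$E)))
  }
})

test_that("identical curves give identical measurements", {
  k <- default_kinetics(); k$E_true <- 0.9; k$noise_sd <- 0
  cc <- simulate_amplification_curves(0.5, k, seed = 3)
  m1 <- estimate_efficiency_ct(cc, fit_amplification(cc))
  m2 <- estimate_efficiency_ct(cc, fit_amplification(cc))
  expect_identical(m1$E, m2$E)
  expect_identical(m1$CT, m2$CT)
})

test_that("CT shift between efficiencies matches the exponential closed form", {
  # same template, different efficiency: CT = const - log(F0 k)/log(1+E)
  k <- default_kinetics(); k$noise_sd <- 0; k$n_cycles <- 45
  cts <- vapply(c(0.85, 1.0), function(E) {
    k$E_true <- E
    cc <- simulate_amplification_curves(1, k, seed = 1)
    estimate_efficiency_ct(cc, fit_amplification(cc))$CT
  }, numeric(1))
  # threshold crossing scales as 1/log(1+E) for a fixed F0 fraction:
  # CT_1 * log(1+E_1) = CT_2 * log(1+E_2) up to the fit's shape offset
  expect_equal(cts[1] * log(1.85), cts[2] * log(2), tolerance = 0.01)
})

test_that("relative_quantity matches its closed forms in the log domain", {
  expect_equal(relative_quantity(1, 10), 2^-10, tolerance = 1e-14)
  expect_equal(relative_quantity(0, 30), 1.0, tolerance = 1e-14)
  expect_equal(relative_quantity(0.9, 25), exp(-25 * log(1.9)),
               tolerance = 1e-13)
  # cross-check log form against direct power form to >= 12 digits
  expect_equal(relative_quantity(0.9, 25) / (1.9^-25), 1, tolerance = 1e-12)
  expect_error(relative_quantity(-0.1, 10), "non-negative")
})

test_that("R0 is strictly decreasing in CT and in E", {
  cts <- seq(5, 40, by = 5)
  expect_true(all(diff(relative_quantity(0.9, cts)) < 0))
  es <- seq(0.1, 1.1, by = 0.2)
  expect_true(all(diff(relative_quantity(es, 20)) < 0))
})

test_that("normalization divides by the same-cell reference and drops broken cells", {
  meas <- data.frame(
    fish_id = rep(c("F1", "F2"), each = 3),
    nucleus = "Dm",
    gene = rep(c("a", "b", "ref"), 2),
    E = 1, CT = rep(c(10, 11, 10), 2), ok = TRUE)
  meas$R0 <- relative_quantity(meas$E, meas$CT)
  out <- normalize_expression(meas, "ref")
  expect_equal(nrow(out), 4)
  expect_equal(out$relative_expression[out$fish_id == "F1" & out$gene == "a"],
               1)  # self-ratio: same E, CT as reference
  # missing reference: whole F2 cell dropped with a warning
  meas2 <- meas[!(meas$fish_id == "F2" & meas$gene == "ref"), ]
  expect_warning(out2 <- normalize_expression(meas2, "ref"), "reference")
  expect_equal(sort(unique(out2$fish_id)), "F1")
})

test_that("a 10-fold dilution propagates through quantification end to end", {
  k <- default_kinetics(); k$E_true <- 1; k$noise_sd <- 0; k$n_cycles <- 50
  curves <- simulate_amplification_curves(c(1, 0.1, 1), k,
                                          reaction_id = c("t1", "t2", "ref"),
                                          seed = 1)
  curves$fish_id <- "F1"
  curves$nucleus <- "Dm"
  curves$gene <- c("a", "b", "ref")[match(curves$reaction_id,
                                          c("t1", "t2", "ref"))]
  q <- quantify_curves(curves)
  expect_true(all(q$ok))
  out <- normalize_expression(q, "ref")
  r <- out$relative_expression
  expect_equal(r[out$gene == "a"] / r[out$gene == "b"], 10, tolerance = 0.05)
})
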