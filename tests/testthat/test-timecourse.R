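test_that("fruit volume reproduces the allometric formula", {
  expect_equal(fruit_volume(0, 0), 0.3537)
  expect_equal(fruit_volume(10, 10), 61.9537)
  # quadratic circumference term: doubling C multiplies (V - 0.3537) by 4
  v1 <- fruit_volume(7, 5) - 0.3537
  v2 <- fruit_volume(7, 10) - 0.3537
  expect_equal(v2 / v1, 4)
  expect_error(fruit_volume(-1, 5), class = "fx_negative_biometry")
})

test_that("polynomial fits reproduce exact data and handle degenerate cases", {
  t <- 0:5
  fit <- fit_polynomial(t, t^2, degree = 2)
  expect_equal(coef(fit), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  # noiseless degree-d data reproduces coefficients to 1e-9 relative
  set.seed(1)
  for (d in 1:3) {
    beta <- rnorm(d + 1)
    tt <- seq(2, 12, by = 2)
    yy <- eval_poly(beta, tt)
    f <- fit_polynomial(tt, yy, degree = d)
    expect_equal(coef(f), beta, tolerance = 1e-9)
  }

  # constant data, degree 1: slope 0 and R^2 = 1 by convention
  fc <- fit_polynomial(t, rep(3, 6), degree = 1)
  expect_equal(coef(fc), c(3, 0), tolerance = 1e-12)
  expect_equal(fc$r_squared, 1)

  expect_error(fit_polynomial(c(1, 2), c(1, 2), degree = 2),
               class = "fx_underdetermined")
})

test_that("quadratic fit of the packaged starch means matches the normal-equation oracle", {
  tab <- plantain_pulp_concentrations()
  ag <- tab[tab$cultivar == "AG" & tab$metabolite == "starch", ]
  ag <- ag[order(ag$week), ]
  fit <- fit_polynomial(ag$week, ag$value, degree = 2)
  # frozen from an independent normal-equation solve of the six means
  expect_equal(coef(fit), c(176.75, 44.9633928571, -1.846875),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 0.9772639, tolerance = 1e-6)
  expect_equal(net_breakdown_time(fit), 12.17283, tolerance = 1e-4)

  # analytic derivative matches a central finite difference
  h <- 1e-4
  for (t0 in c(3, 6, 9, 11)) {
    fd <- (predict(fit, t0 + h) - predict(fit, t0 - h)) / (2 * h)
    expect_equal(derivative(fit, t0), fd, tolerance = 1e-6)
  }
})

test_that("degree selection maximizes adjusted R^2 with low-degree tie-break", {
  t <- rep(seq(2, 12, by = 2), each = 3)
  y_cubic <- 1 + 0.5 * t - 0.2 * t^2 + 0.05 * t^3
  expect_equal(select_degree(t, y_cubic, 1:3)$degree, 3L)

  y_lin <- 2 + 3 * t
  expect_equal(select_degree(t, y_lin, 1:3)$degree, 1L)

  # noisy quadratic data: degree 2 recovered in >= 95% of regenerations
  wins <- 0
  set.seed(42)
  for (i in 1:100) {
    y <- 5 + 4 * t - 0.3 * t^2 + rnorm(length(t), sd = 0.5)
    if (select_degree(t, y, 1:3)$degree == 2L) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("derivative is linear and matches analytic forms", {
  t <- seq(0, 4, by = 0.5)
  f <- fit_polynomial(t, t^3, degree = 3)
  g <- fit_polynomial(t, 2 * t^2 - t, degree = 3)
  expect_equal(derivative(f, 2), 12, tolerance = 1e-9)
  # derivative of the sum = sum of derivatives
  s <- fit_polynomial(t, t^3 + 2 * t^2 - t, degree = 3)
  tt <- c(0.5, 1.7, 3.1)
  expect_equal(derivative(s, tt), derivative(f, tt) + derivative(g, tt),
               tolerance = 1e-8)
  # quadratic derivative vanishes at the vertex
  q <- fit_polynomial(t, -(t - 2)^2, degree = 2)
  expect_equal(derivative(q, 2), 0, tolerance = 1e-10)
  expect_warning(derivative(q, 10), "outside")
})

test_that("per-fruit conversion and accumulation flux behave dimensionally", {
  t <- seq(2, 12)
  dw_fit <- fit_polynomial(t, rep(2, length(t)), degree = 1)
  expect_equal(per_fruit_amount(100, dw_fit, 6), 200)
  expect_equal(per_fruit_amount(0, dw_fit, 6), 0)

  amount_fit <- fit_polynomial(t, 10 * t, degree = 1)
  expect_equal(accumulation_flux(amount_fit, dw_fit, c(3, 7, 11)),
               rep(5, 3), tolerance = 1e-10)

  dw_bad <- fit_polynomial(t, 5 - t, degree = 1)  # negative over part of domain
  expect_error(per_fruit_amount(10, dw_bad, 12), class = "fx_negative_dw")
})

test_that("accumulation flux integrates back to the amount difference", {
  t <- seq(2, 12, by = 2)
  amount_fit <- fit_polynomial(t, 3 + 4 * t + 0.5 * t^2, degree = 2)
  dw_fit <- fit_polynomial(t, 1 + 0.3 * t, degree = 1)
  grid <- seq(2, 12, by = 0.005)
  flux <- accumulation_flux(amount_fit, dw_fit, grid)
  dw <- predict(dw_fit, grid)
  integrand <- flux * dw
  trap <- sum((integrand[-1] + integrand[-length(grid)]) / 2 * diff(grid))
  delta <- predict(amount_fit, 12) - predict(amount_fit, 2)
  expect_equal(trap, delta, tolerance = 1e-3 * abs(delta))
})

test_that("R^2 is invariant under affine rescaling of the response", {
  set.seed(3)
  t <- rep(1:6, each = 2)
  y <- 2 + t + rnorm(12, sd = 0.3)
  f1 <- fit_polynomial(t, y, 1)
  f2 <- fit_polynomial(t, 5 * y - 7, 1)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("growth rate of a cubic has one interior minimum (three growth phases)", {
  t <- seq(2, 12, by = 0.5)
  vol <- 5 - 2 * t + 3 * t^2 - 0.15 * t^3
  fit <- fit_polynomial(t, vol, degree = 3)
  expect_equal(growth_rate(fit, 3), derivative(fit, 3), tolerance = 1e-12)
  g <- growth_rate(fit, t)
  # sign of the second difference changes exactly once for a cubic rate? the
  # rate is quadratic, so it has a single interior extremum
  d2 <- diff(sign(diff(g)))
  expect_equal(sum(d2 != 0), 1L)

  f3 <- fit_polynomial(0:4, (0:4)^3, degree = 3)
  expect_equal(growth_rate(f3, 1), 3, tolerance = 1e-9)
})

test_that("net breakdown time is the quadratic vertex", {
  t <- seq(2, 18)
  fit <- fit_polynomial(t, -t^2 + 20 * t, degree = 2)
  expect_equal(net_breakdown_time(fit), 10, tolerance = 1e-9)

  sym <- fit_polynomial(t, 100 - (t - 6)^2, degree = 2)
  expect_equal(net_breakdown_time(sym), 6, tolerance = 1e-9)

  rising <- fit_polynomial(t, t^2, degree = 2)
  expect_error(net_breakdown_time(rising), class = "fx_no_maximum")
})
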