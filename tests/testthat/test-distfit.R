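test_that("normal and exponential fits match their closed forms", {
  fn <- fit_distance_distribution(c(0, 2), "normal")
  expect_equal(unname(coef(fn)), c(1, sqrt(2)), tolerance = 1e-15)
  expect_warning(fit_distance_distribution(rep(3, 5), "normal"),
                 "sigma = 0")
  expect_error(fit_distance_distribution(1, "normal"), "at least 2")
  fe <- fit_distance_distribution(c(2, 4), "exponential")
  expect_identical(unname(coef(fe)["mean"]), 3)
  fe1 <- fit_distance_distribution(1, "exponential")
  expect_identical(unname(coef(fe1)["mean"]), 1)
  expect_error(fit_distance_distribution(c(-1, 2), "exponential"),
               "nonnegative")
  # non-finite values are excluded with a message
  expect_message(fit_distance_distribution(c(0, 2, Inf), "normal"),
                 "non-finite")
})

test_that("the step ECDF counts observations per its definition", {
  fe <- fit_distance_distribution(c(1, 2, 3), "ecdf")
  expect_equal(predict(fe, 2, type = "step"), 2 / 3)
  expect_equal(predict(fe, 0.99, type = "step"), 0)
  expect_equal(predict(fe, 3, type = "step"), 1)
  expect_error(predict(fit_distance_distribution(1:3, "normal"),
                       1, type = "step"), "ecdf")
})

test_that("the smoothed ECDF uses midpoint nodes with hard boundaries", {
  fe <- fit_distance_distribution(c(1, 2), "ecdf")
  expect_equal(predict(fe, 1.5), 0.5)  # midpoint-node interpolation
  expect_equal(predict(fe, 2), 1)      # cdf(x_(n)) = 1
  expect_equal(predict(fe, 1 - 1e-9), 0)  # 0 below the minimum
  # quantile round trip within 1/n
  fx <- fit_distance_distribution(c(0.2, 0.4, 0.4, 0.9, 1.3), "ecdf")
  for (q in seq(0.05, 0.95, by = 0.1))
    expect_lt(abs(predict(fx, quantile(fx, q)) - q), 1 / 5 + 1e-12)
})

test_that("a degenerate one-point ECDF samples its atom", {
  fe <- fit_distance_distribution(5, "ecdf")
  expect_identical(simulate(fe, 3, seed = 1), c(5, 5, 5))
  expect_identical(simulate(fe, 3, seed = 99), c(5, 5, 5))
})

test_that("KDE cdf follows the kernel-mixture closed form", {
  f1 <- fit_distance_distribution(2, "kde", bandwidth = 0.3)
  xs <- c(1.5, 2, 2.7)
  expect_equal(predict(f1, xs), pnorm((xs - 2) / 0.3), tolerance = 1e-12)
  expect_equal(predict(f1, 2), 0.5)
  f2 <- fit_distance_distribution(c(0, 1), "kde", bandwidth = 0.5)
  expect_equal(predict(f2, 0.5), 0.5, tolerance = 1e-12)
  # direct two-term summation oracle at an off-center point
  expect_equal(predict(f2, 0.2),
               mean(pnorm((0.2 - c(0, 1)) / 0.5)), tolerance = 1e-12)
  expect_error(fit_distance_distribution(1:3, "kde", bandwidth = 0),
               "positive")
})

test_that("KDE density integrates to one over its grid", {
  set.seed(4)
  vals <- rexp(200, 1.5)
  fk <- fit_distance_distribution(vals, "kde", bandwidth = "auto")
  h <- unname(coef(fk)["bandwidth"])
  xs <- seq(min(vals) - 6 * h, max(vals) + 6 * h, length.out = 4001)
  dens <- predict(fk, xs, type = "density")
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  expect_equal(integral, 1, tolerance = 1e-6)
})

test_that("grid-mode KDE matches exact summation to 1e-6", {
  set.seed(11)
  vals <- c(rnorm(300, 1, 0.2), rexp(200, 2))
  exact <- fit_distance_distribution(vals, "kde", bandwidth = 0.05,
                                     kde_mode = "exact")
  grid <- fit_distance_distribution(vals, "kde", bandwidth = 0.05,
                                    kde_mode = "grid")
  xs <- seq(min(vals), max(vals), length.out = 200)
  expect_lt(max(abs(predict(exact, xs) - predict(grid, xs))), 1e-6)
})

test_that("KDE converges to the step ECDF as the bandwidth vanishes", {
  set.seed(8)
  vals <- sort(runif(10, 0, 5))
  fk <- fit_distance_distribution(vals, "kde", bandwidth = 1e-6)
  fe <- fit_distance_distribution(vals, "ecdf")
  # at non-data abscissae (midpoints between order statistics)
  mids <- (vals[-1] + vals[-10]) / 2
  expect_lt(max(abs(predict(fk, mids) - predict(fe, mids, type = "step"))),
            1e-6)
})

test_that("every family has a nondecreasing cdf over a wide grid", {
  set.seed(9)
  vals <- c(rexp(150, 2), rnorm(150, 1, 0.3))
  vals <- vals[vals > 0]
  for (fam in c("normal", "exponential", "ecdf", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = "auto")
    pad <- if (fam == "normal") 4 * coef(fit)["sigma"] else 1
    xs <- seq(min(vals) - pad, max(vals) + pad, length.out = 1000)
    expect_true(all(diff(predict(fit, xs)) >= -1e-12), info = fam)
  }
})

test_that("quantile and cdf are inverse on the interior", {
  set.seed(10)
  vals <- rexp(400, 1)
  qs <- seq(0.01, 0.99, by = 0.01)
  for (fam in c("normal", "exponential", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = "auto")
    err <- abs(predict(fit, quantile(fit, qs)) - qs)
    expect_lt(max(err), 1e-6)
  }
  fe <- fit_distance_distribution(vals, "ecdf")
  err_e <- abs(predict(fe, quantile(fe, qs)) - qs)
  expect_lt(max(err_e), 1 / length(vals) + 1e-12)
})

test_that("simulation is seed-reproducible and distributionally sound", {
  set.seed(2)
  vals <- rexp(300, 2)
  for (fam in c("normal", "exponential", "ecdf", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = "auto")
    expect_identical(simulate(fit, 50, seed = 5),
                     simulate(fit, 50, seed = 5))
  }
  # inverse-CDF sampling of a standard normal fit: CLT bound on the mean
  fn <- fit_distance_distribution(c(-1, 1) / sqrt(2), "normal")
  expect_equal(unname(coef(fn)), c(0, 1), tolerance = 1e-15)
  expect_lt(abs(mean(simulate(fn, 1e5, seed = 42))), 0.02)
})

test_that("large samples from a fit agree with its own quantile grid", {
  set.seed(3)
  vals <- c(rexp(200, 3), rnorm(100, 1.2, 0.1))
  vals <- vals[vals > 0]
  n <- 5000
  grid <- (seq_len(n) - 0.5) / n
  for (fam in c("normal", "exponential", "ecdf", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = "auto")
    qgrid <- quantile(fit, grid)
    pass <- vapply(1:10, function(s) {
      ks_two_sample(simulate(fit, n, seed = s), qgrid)$p_value > 0.001
    }, logical(1))
    expect_gte(sum(pass), 9L)
  }
})

test_that("fitted models survive a JSON round trip", {
  set.seed(6)
  vals <- rexp(50, 2)
  for (fam in c("normal", "exponential", "ecdf", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = 0.1)
    f <- tempfile(fileext = ".json")
    write_model(fit, f)
    back <- read_model(f)
    xs <- seq(0, 3, length.out = 50)
    expect_equal(predict(back, xs), predict(fit, xs), tolerance = 1e-12)
    expect_identical(back$family, fit$family)
  }
})
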