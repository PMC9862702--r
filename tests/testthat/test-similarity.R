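test_that("quantile tables have one nondecreasing row per percent", {
  set.seed(20)
  vals <- rexp(300, 1)
  for (fam in c("normal", "exponential", "ecdf", "kde")) {
    fit <- fit_distance_distribution(vals, fam, bandwidth = "auto")
    qt <- quantile_table(fit)
    expect_identical(nrow(qt), 20L)
    expect_identical(qt$q, seq(5, 100, by = 5))
    expect_true(all(diff(qt$value) >= -1e-12), info = fam)
  }
  expect_error(quantile_table(
    fit_distance_distribution(vals, "ecdf"), qs = c(0, 50)), "qs")
})

test_that("the 100th percentile row is the observed maximum", {
  fe <- fit_distance_distribution(c(1, 2, 3, 4), "ecdf")
  qt <- quantile_table(fe, qs = c(50, 100))
  expect_identical(qt$value[qt$q == 100], 4)
  # also for the unbounded-support KDE
  fk <- fit_distance_distribution(c(1, 2, 3, 4), "kde", bandwidth = 0.1)
  expect_identical(quantile_table(fk)$value[20], 4)
})

test_that("the packaged reference percentile table loads correctly", {
  tab <- reference_percentile_table()
  expect_identical(nrow(tab), 20L)
  expect_identical(tab$value[tab$q == 50], 0.9589)
  expect_identical(tab$value[tab$q == 100], 27.0327)
  expect_true(all(diff(tab$value) > 0))
})

test_that("nearest-table lookup reproduces the worked rank example", {
  tab <- reference_percentile_table()
  expect_identical(percentile_of(0.81, mode = "nearest-table",
                                 table = tab), 15)
  # ties go to the smaller percent
  toy <- structure(data.frame(q = c(10, 20), value = c(1, 3)),
                   class = c("quantile_table", "data.frame"))
  expect_identical(percentile_of(2, mode = "nearest-table", table = toy),
                   10)
  expect_error(percentile_of(1, mode = "nearest-table"), "table")
})

test_that("continuous percentiles invert the model quantiles", {
  set.seed(21)
  vals <- rexp(500, 2)
  fit <- fit_distance_distribution(vals, "kde", bandwidth = "auto")
  for (q in seq(5, 95, by = 10)) {
    d <- quantile(fit, q / 100)
    expect_lt(abs(percentile_of(d, model = fit) - q), 0.5)
  }
  # far lower tail maps below the 0.1th percentile
  d_low <- quantile(fit, 0.0005)
  expect_lt(percentile_of(d_low, model = fit), 0.1)
  expect_error(percentile_of(1, mode = "continuous"), "model")
})

test_that("similarity verdicts use a strict threshold", {
  expect_true(is_similar(15, 16))
  expect_false(is_similar(15, 15))
  expect_true(is_similar(27, 30))
  expect_error(is_similar(15, 0), "threshold_p")
})

test_that("panel reports summarize resolved members and distances", {
  cat <- generate_fixture_catalog(30, c(60, 90), seed = 30)
  cd <- pairwise_distances(cat)
  model <- fit_distance_distribution(cd, "kde", bandwidth = "auto")
  nms <- catalog_names(cat)[c(2, 5, 9, 14, 20)]
  rep <- analyze_panel(nms, cat, model, species_prefix = "",
                       threshold_p = 50)
  expect_identical(rep$m, 5L)
  expect_identical(rep$pair_count, pair_count(5))
  expect_identical(length(rep$distances), 10L)
  # independent recomputation of the mean from the distance vector
  expect_equal(rep$mean, mean(rep$distances$values), tolerance = 1e-12)
  expect_true(rep$range[1] <= rep$mean && rep$mean <= rep$range[2])
  expect_identical(rep$similar,
                   is_similar(rep$percentile_of_mean, 50))
})

test_that("identical panel members give a zero-distance similar panel", {
  cat <- hairpin_catalog(data.frame(
    identifier = c("syn-mir-001", "syn-mir-002"),
    sequence = rep("ACGUACGUACGUACGU", 2)))
  vals <- c(0.4, 0.6, 0.8, 1.0, 1.2)
  model <- fit_distance_distribution(vals, "kde", bandwidth = 0.1)
  rep <- analyze_panel(c("syn-mir-001", "syn-mir-002"), cat, model,
                       species_prefix = "", threshold_p = 30)
  expect_identical(rep$mean, 0)
  expect_lt(rep$percentile_of_mean, 1)
  expect_true(rep$similar)
})

test_that("panel means are distribution-consistent with the catalog", {
  cat <- generate_fixture_catalog(100, c(50, 120), seed = 77)
  cd <- pairwise_distances(cat)
  m <- as.matrix(cd)
  overall_mean <- mean(cd$values)
  set.seed(78)
  panel_means <- replicate(200, {
    idx <- sample.int(100, 10)
    sub <- m[idx, idx]
    mean(sub[upper.tri(sub)])
  })
  se <- sd(panel_means) / sqrt(length(panel_means))
  expect_lt(abs(mean(panel_means) - overall_mean), 3 * se)
})
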