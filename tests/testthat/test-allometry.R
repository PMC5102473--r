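test_that("shear transform maps (x, y) to (x, x + y) and inverts bit-exactly", {
  expect_equal(shear_transform(data.frame(x = 2, y = 3))$y, 5)
  expect_equal(shear_transform(data.frame(x = 0, y = -7))$y, -7)
  set.seed(1)
  d <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  round_trip <- shear_transform(shear_transform(d), inverse = TRUE)
  expect_equal(round_trip$y, d$y, tolerance = 1e-15)
  expect_identical(round_trip$x, d$x)
})

test_that("two exact points give slope 1, intercept 1, R2 = 1", {
  pts <- tibble::tibble(
    taxon = c("a", "b", "c"), M_g = c(1, 100, 10),
    kC_per_day = c(10, 1000, 100)
  )
  fit <- fit_loglog(pts, "kC", "M")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("weighted and unweighted fits match the normal-equations oracle to 1e-10", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    x <- runif(n, 0, 5)
    y <- -1 + 0.6 * x + rnorm(n, 0, 0.3)
    w <- runif(n, 0.2, 2)
    d <- tibble::tibble(
      taxon = paste0("t", 1:n), M_g = 10^x, kC_per_day = 10^y, weight = w
    )
    fit_w <- fit_loglog(d, "kC", "M", weighted = TRUE)
    or_w <- ols_oracle(x, y, w)
    expect_equal(fit_w$slope, or_w$slope, tolerance = 1e-10)
    expect_equal(fit_w$intercept, or_w$intercept, tolerance = 1e-10)
    expect_equal(fit_w$ci95_slope, or_w$ci_slope, tolerance = 1e-10)
    expect_equal(fit_w$ci95_intercept, or_w$ci_intercept, tolerance = 1e-10)
    expect_equal(fit_w$r2, or_w$r2, tolerance = 1e-10)
    expect_equal(fit_w$residuals, or_w$residuals, tolerance = 1e-10)
    fit_u <- fit_loglog(d, "kC", "M", weighted = FALSE)
    or_u <- ols_oracle(x, y)
    expect_equal(fit_u$slope, or_u$slope, tolerance = 1e-10)
    # equal weights reproduce the unweighted fit bit-for-bit
    d_eq <- dplyr::mutate(d, weight = 1)
    fit_eq <- fit_loglog(d_eq, "kC", "M", weighted = TRUE)
    expect_identical(fit_eq$slope, fit_u$slope)
    expect_identical(fit_eq$r2, fit_u$r2)
  }
})

test_that("fit_loglog validates its inputs", {
  expect_error(
    fit_loglog(tibble::tibble(M_g = c(1, 2), kC_per_day = c(1, 2)), "kC", "M"),
    "at least 3"
  )
  bad <- tibble::tibble(
    taxon = c("ok1", "bad_taxon", "ok2"),
    M_g = c(1, -5, 10), kC_per_day = c(1, 1, 1)
  )
  expect_error(fit_loglog(bad, "kC", "M"), "bad_taxon")
  expect_error(
    fit_loglog(tibble::tibble(M_g = 1:5), "kC", "M"),
    "rate column missing"
  )
  # excluded rows are dropped before fitting
  d <- exact_power_law_table(6)
  d$excluded[1] <- TRUE
  expect_equal(fit_loglog(d, "kC", "M")$n, 5)
})

test_that("the shear relation links the Gmax and kC regressions exactly", {
  set.seed(11)
  d <- generate_group("g", n = 40, log10_mass_range = c(0, 4), sd = 0.35)
  cmp <- compare_dependent_variables(d, "kC", "M")
  expect_equal(cmp$report$slope_difference, 1, tolerance = 1e-12)
  expect_equal(cmp$report$ci_width_Gmax, cmp$report$ci_width_specific,
    tolerance = 1e-12
  )
  expect_identical(cmp$fit_Gmax$intercept, cmp$report$slope_Gmax * 0 + cmp$fit_Gmax$intercept)
  expect_equal(cmp$fit_Gmax$residuals, cmp$fit_specific$residuals,
    tolerance = 1e-12
  )
  expect_gt(cmp$report$r2_Gmax, cmp$report$r2_specific)
})

test_that("prediction bands contain confidence bands and are narrowest at the weighted mean", {
  set.seed(3)
  d <- generate_group("g", n = 30, sd = 0.3)
  fit <- fit_loglog(d, "kC", "M")
  grid <- seq(0, 6, length.out = 60)
  cb <- confidence_band(fit, grid)
  pb <- prediction_band(fit, grid)
  expect_true(all(pb$lower <= cb$lower))
  expect_true(all(pb$upper >= cb$upper))
  expect_true(all(cb$lower < cb$upper))
  # extrapolation beyond the data is flagged
  expect_true(any(cb$extrapolated))
  expect_false(all(cb$extrapolated))
  # band width is minimal at the weighted mean of x
  w <- fit$data$weight
  xbar <- sum(w * fit$data$x) / sum(w)
  width <- function(x0) {
    b <- confidence_band(fit, x0)
    b$upper - b$lower
  }
  expect_lt(width(xbar), width(xbar - 0.5))
  expect_lt(width(xbar), width(xbar + 0.5))
})

test_that("confidence bands cover the true line at the mean mass at their nominal rate", {
  n <- 25
  x <- runif(n, 0, 4)
  covered <- vapply(1:400, function(seed) {
    set.seed(seed)
    y <- -2 + 0.5 * x + rnorm(n, 0, 0.4)
    d <- tibble::tibble(M_g = 10^x, kC_per_day = 10^y)
    fit <- fit_loglog(d, "kC", "M")
    b <- confidence_band(fit, mean(x))
    truth <- -2 + 0.5 * mean(x)
    b$lower <= truth && truth <= b$upper
  }, logical(1))
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("fixed-slope adjustment reduces rates to 1 g and finds group overlap", {
  d <- tibble::tibble(
    taxon = c("a", "b", "c"), group = "g",
    M_g = c(1, 1e4, 100), Gmax_g_per_day = c(5, 1e3, 10)
  )
  fs <- fixed_slope_adjust(d, b = 0.75, dependent = "Gmax")
  expect_equal(fs$adjusted$adjusted[1], log10(5)) # M = 1 g: untouched
  expect_equal(fs$adjusted$adjusted[2], 3 - 0.75 * 4) # worked arithmetic
  # groups drawn with the same intercept have matching adjusted distributions
  set.seed(5)
  g1 <- generate_group("low", n = 400, log10_mass_range = c(0, 2), intercept = -1, sd = 0.3)
  g2 <- generate_group("high", n = 400, log10_mass_range = c(3, 5), intercept = -1, sd = 0.3)
  fs2 <- fixed_slope_adjust(dplyr::bind_rows(g1, g2), b = 0.75, dependent = "Gmax")
  a1 <- fs2$adjusted$adjusted[fs2$adjusted$group == "low"]
  a2 <- fs2$adjusted$adjusted[fs2$adjusted$group == "high"]
  ks <- suppressWarnings(stats::ks.test(a1, a2))
  expect_lt(unname(ks$statistic), 0.12)
  expect_false(is.null(fs2$overlap))
  # disjoint adjusted ranges give no overlap interval
  g3 <- dplyr::mutate(g1, group = "shifted", Gmax_g_per_day = Gmax_g_per_day * 1e6)
  fs3 <- fixed_slope_adjust(dplyr::bind_rows(g1, g3), b = 0.75, dependent = "Gmax")
  expect_null(fs3$overlap)
})

test_that("loglog_fit tidy and glance expose the estimates", {
  d <- exact_power_law_table(8)
  fit <- fit_loglog(d, "kC", "M")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope_b"], -0.25, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$r2, 1, tolerance = 1e-10)
  expect_equal(gl$n, 8L)
})
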