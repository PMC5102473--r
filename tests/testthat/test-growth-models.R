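test_that("model constants match their closed forms and numerical maximization", {
  closed <- model_constants(c("logistic", "gompertz", "von_bertalanffy"))
  expect_equal(closed$C, c(1 / 4, exp(-1), 4 / 9))
  expect_equal(closed$d, c(1 / 2, exp(-1), 8 / 27))
  expect_equal(closed$D, c(1 / 2, 1, 3 / 2))
  numeric <- model_constants(c("logistic", "gompertz", "von_bertalanffy"),
    method = "numeric"
  )
  expect_equal(numeric$C, closed$C, tolerance = 1e-6)
  expect_equal(numeric$d, closed$d, tolerance = 1e-6)
  expect_equal(numeric$D, closed$D, tolerance = 1e-6)
  # C is the value of df/ds where f = d
  for (m in c("logistic", "gompertz", "von_bertalanffy")) {
    gm <- growth_model(m)
    s_star <- numeric$s_star[numeric$model == m]
    expect_equal(dimensionless_growth(gm, s_star), gm$d, tolerance = 1e-6)
  }
  expect_error(growth_model("richards"), "unknown growth model")
})

test_that("dimensionless growth functions hit their anchor values and are monotone", {
  expect_equal(dimensionless_growth("logistic", 0), 0.5)
  expect_equal(dimensionless_growth("gompertz", 0), exp(-1))
  expect_equal(dimensionless_growth("von_bertalanffy", 50), 1, tolerance = 1e-12)
  s <- seq(-5, 8, length.out = 400) # double-exponential tail underflows below
  for (m in c("logistic", "gompertz")) {
    f <- dimensionless_growth(m, s)
    expect_true(all(diff(f) > 0), info = m)
    expect_true(all(f > 0 & f < 1), info = m)
  }
  s_pos <- seq(0.01, 12, length.out = 400)
  f <- dimensionless_growth("von_bertalanffy", s_pos)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
})

test_that("predict_mass matches a pointwise closed-form oracle and is increasing", {
  p <- growth_params(M = 100, k = 0.2, t_c = 10, model = "logistic")
  expect_equal(predict_mass(p, 10), 50)
  t <- seq(-40, 80, length.out = 100)
  oracle <- 100 / (1 + exp(-0.2 * (t - 10)))
  expect_equal(predict_mass(p, t), oracle, tolerance = 1e-12)
  expect_true(all(diff(predict_mass(p, t)) > 0))
  expect_true(all(predict_mass(p, t) < p$M))
  pg <- growth_params(M = 1, k = 0.1, t_c = 5, model = "gompertz")
  expect_equal(predict_mass(pg, 5), exp(-1))
})

test_that("derived rates obey the closed forms and the numerical peak of dm/dt", {
  p <- growth_params(M = 100, k = 0.2, model = "logistic")
  dr <- derived_rates(p)
  expect_equal(dr$G_max, 100 * 0.2 * 0.25)
  expect_equal(dr$kC, dr$G_max / p$M)
  expect_equal(dr$t_M, 1 / dr$kC)
  # Gompertz inflection sits at ~37% of asymptotic mass
  expect_equal(derived_rates(growth_params(M = 1000, k = 0.1, model = "gompertz"))$BMatMG / 1000,
    exp(-1),
    tolerance = 1e-12
  )
  set.seed(42)
  for (i in 1:12) {
    m <- sample(c("logistic", "gompertz", "von_bertalanffy"), 1)
    p <- growth_params(
      M = 10^runif(1, 1, 5), k = 10^runif(1, -3, -0.5),
      t_c = runif(1, 0, 200), model = m
    )
    dr <- derived_rates(p)
    # kD = kC / d exactly
    expect_equal(dr$kD, dr$kC / growth_model(m)$d, tolerance = 1e-12)
    expect_equal(dr$BMatMG, p$M * growth_model(m)$d, tolerance = 1e-12)
    # numerical max of dm/dt on a fine grid around the inflection age
    # grid over the growth domain (s >= 0 for von Bertalanffy, whose cubic
    # form is only a mass trajectory above t_c)
    tg <- if (m == "von_bertalanffy") {
      seq(p$t_c, p$t_c + 4 / p$k, length.out = 4001)
    } else {
      seq(p$t_c - 2 / p$k, p$t_c + 2 / p$k, length.out = 4001)
    }
    dt <- diff(tg)[1]
    g_num <- max(diff(predict_mass(p, tg)) / dt)
    expect_equal(g_num, dr$G_max, tolerance = 1e-3)
  }
})

test_that("time_to_fraction inverts the sigmoids and brackets the growth-time rule of thumb", {
  p <- growth_params(M = 1, k = 1, model = "logistic")
  expect_equal(
    time_to_fraction(p, 0.01, 0.9),
    log(0.9 / 0.1) - log(0.01 / 0.99),
    tolerance = 1e-9
  )
  # near the inflection, duration ~ (mass change) / G_max
  eps <- 1e-6
  expect_equal(time_to_fraction(p, 0.5 - eps, 0.5 + eps), 2 * eps / 0.25,
    tolerance = 1e-4
  )
  # time from 1% to 90% of M is within the 1.5-2x t_M band for the logistic
  dr <- derived_rates(p)
  ratio <- time_to_fraction(p, 0.01, 0.9) / dr$t_M
  expect_equal(ratio, 1.70, tolerance = 0.01)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2)
  # von Bertalanffy bisection agrees with the analytic inverse
  pv <- growth_params(M = 1, k = 0.3, model = "von_bertalanffy")
  for (q in c(0.05, 0.3, 0.8, 0.99)) {
    expect_equal(
      time_to_fraction(pv, 0.01, q),
      (-log(1 - q^(1 / 3)) + log(1 - 0.01^(1 / 3))) / 0.3,
      tolerance = 1e-7
    )
  }
  expect_error(time_to_fraction(p, 0.9, 0.5), "fractions")
  expect_error(time_to_fraction(p, 0, 0.5), "fractions")
})

test_that("growth-curve fitting recovers noise-free parameters for all three models", {
  truths <- list(
    logistic = growth_params(M = 5000, k = 0.05, t_c = 40, model = "logistic"),
    gompertz = growth_params(M = 800, k = 0.02, t_c = 100, model = "gompertz"),
    von_bertalanffy = growth_params(
      M = 1200, k = 0.01, t_c = 30,
      model = "von_bertalanffy"
    )
  )
  spans <- list(
    logistic = seq(0, 120, length.out = 7),
    gompertz = seq(0, 500, length.out = 7),
    von_bertalanffy = seq(40, 800, length.out = 7) # masses positive above t_c
  )
  for (m in names(truths)) {
    tr <- truths[[m]]
    d <- tibble::tibble(age_days = spans[[m]], mass_g = predict_mass(tr, spans[[m]]))
    fit <- fit_growth_curve(d, m)
    expect_equal(fit$params$M, tr$M, tolerance = 1e-6)
    expect_equal(fit$params$k, tr$k, tolerance = 1e-6)
    expect_equal(fit$params$t_c, tr$t_c, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
    expect_equal(fit$derived$G_max, derived_rates(tr)$G_max, tolerance = 1e-6)
  }
})

test_that("fixing the asymptote removes one free parameter without changing the optimum", {
  tr <- growth_params(M = 5000, k = 0.05, t_c = 40, model = "logistic")
  ages <- seq(0, 120, length.out = 7)
  d <- tibble::tibble(age_days = ages, mass_g = predict_mass(tr, ages))
  free <- fit_growth_curve(d, "logistic")
  fixed <- fit_growth_curve(d, "logistic", fix_asymptote = 5000)
  expect_true(fixed$asymptote_fixed)
  expect_false(free$asymptote_fixed)
  expect_equal(fixed$params$M, 5000)
  expect_equal(fixed$params$k, free$params$k, tolerance = 1e-6)
  expect_equal(fixed$params$t_c, free$params$t_c, tolerance = 1e-6)
  # a 3-point series supports the 2-parameter fit but not the 3-parameter one
  d3 <- d[c(1, 4, 7), ]
  expect_error(fit_growth_curve(d3, "logistic"), "free parameters")
  expect_s3_class(fit_growth_curve(d3, "logistic", fix_asymptote = 5000), "growth_fit")
})

test_that("neonate augmentation appends a flagged point and feeds the fit", {
  tr <- growth_params(M = 5000, k = 0.05, t_c = 40, model = "logistic")
  ages <- seq(30, 120, length.out = 5)
  d <- tibble::tibble(age_days = ages, mass_g = predict_mass(tr, ages))
  fit <- fit_growth_curve(d, "logistic", add_neonate = c(0, predict_mass(tr, 0)))
  expect_true(fit$neonate_added)
  expect_equal(fit$n, 6)
  expect_identical(fit$data$provenance[6], "neonate")
  expect_equal(fit$params$M, 5000, tolerance = 1e-6)
})

test_that("noisy Gompertz series recover the growth constant within 10% (median over seeds)", {
  tr <- growth_params(M = 2000, k = 0.03, t_c = 80, model = "gompertz")
  ages <- seq(0, 400, length.out = 10)
  m_true <- predict_mass(tr, ages)
  rel_err <- vapply(1:50, function(seed) {
    set.seed(seed)
    d <- tibble::tibble(
      age_days = ages,
      mass_g = pmax(m_true + rnorm(10, 0, 0.02 * tr$M), 1e-3)
    )
    fit <- fit_growth_curve(d, "gompertz")
    abs(fit$params$k - tr$k) / tr$k
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("growth_fit accessors expose tidy, glance and predictions", {
  tr <- growth_params(M = 5000, k = 0.05, t_c = 40, model = "logistic")
  ages <- seq(0, 120, length.out = 7)
  d <- tibble::tibble(age_days = ages, mass_g = predict_mass(tr, ages))
  fit <- fit_growth_curve(d, "logistic")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "fixed"))
  expect_equal(td$estimate[td$term == "M"], 5000, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$G_max, derived_rates(tr)$G_max, tolerance = 1e-6)
  expect_equal(predict(fit), d$mass_g, tolerance = 1e-6)
})
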