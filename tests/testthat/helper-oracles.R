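# Independent oracles used across the suite. Each is deliberately written
# from first principles (normal equations, brute-force geometry, closed-form
# probability) so it shares no code path with the implementation it checks.

# Weighted OLS via the normal equations, with t-based confidence intervals.
ols_oracle <- function(x, y, w = rep(1, length(x)), level = 0.95) {
  X <- cbind(1, x)
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% beta
  df <- length(x) - 2
  sigma2 <- sum(w * res^2) / df
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  tq <- qt(1 - (1 - level) / 2, df)
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  list(
    intercept = beta[1], slope = beta[2],
    ci_intercept = beta[1] + c(-1, 1) * tq * se[1],
    ci_slope = beta[2] + c(-1, 1) * tq * se[2],
    residuals = drop(res),
    r2 = 1 - sum(w * res^2) / tss
  )
}

# Brute-force convex-hull membership: a point is inside the hull of S iff it
# lies on the inner side of every supporting line through a pair of points of
# S (a line with all of S on one side). O(n^3) precompute, independent of
# grDevices::chull and of the package's ray/half-plane code.
brute_force_membership <- function(sx, sy, qx, qy, tol = 1e-9) {
  n <- length(sx)
  if (n == 1) {
    return(sqrt((qx - sx)^2 + (qy - sy)^2) <= tol)
  }
  inside <- rep(TRUE, length(qx))
  any_edge <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ex <- sx[j] - sx[i]
      ey <- sy[j] - sy[i]
      len <- sqrt(ex^2 + ey^2)
      if (len == 0) next
      cr <- (ex * (sy - sy[i]) - ey * (sx - sx[i])) / len
      if (all(cr >= -tol)) {
        any_edge <- TRUE
        qcr <- (ex * (qy - sy[i]) - ey * (qx - sx[i])) / len
        inside <- inside & (qcr >= -tol)
      } else if (all(cr <= tol)) {
        any_edge <- TRUE
        qcr <- (ex * (qy - sy[i]) - ey * (qx - sx[i])) / len
        inside <- inside & (qcr <= tol)
      }
    }
  }
  if (!any_edge) {
    # all points coincide up to pairs with zero length: fall back to distance
    return(sqrt((qx - mean(sx))^2 + (qy - mean(sy))^2) <= tol)
  }
  inside
}

# AICc arithmetic, written out independently of the package function.
aicc_oracle <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + (2 * k * (k + 1)) / (n - k - 1)
}

# Closed-form R^2 values implied by the metabolic generator: masses uniform
# on [0, decades] in log10, log-BMR = b1*x + N(0, sB), log-kC = (b2-1)*x +
# N(0, sG), independent noises. Pairwise squared correlations follow from the
# shared regressor.
metab_r2_oracle <- function(decades, b1, b2, sd_bmr, sd_growth) {
  vx <- decades^2 / 12
  c2 <- (b2 - 1)^2
  r2_bmr_m <- b1^2 * vx / (b1^2 * vx + sd_bmr^2)
  r2_kc_m <- c2 * vx / (c2 * vx + sd_growth^2)
  list(
    r2_bmr_m = r2_bmr_m,
    r2_kc_m = r2_kc_m,
    r2_bmr_kc = r2_bmr_m * r2_kc_m
  )
}

# Normal-theory accuracy of nearest-mean classification between two normals
# with common sd: the sample mean falls on the correct side of the midpoint.
nearest_mean_accuracy_oracle <- function(delta, sigma, n) {
  pnorm(abs(delta) * sqrt(n) / (2 * sigma))
}

# Smallest n with oracle accuracy >= conf.
minimal_n_oracle <- function(delta, sigma, conf = 0.95) {
  ceiling((2 * sigma * qnorm(conf) / abs(delta))^2)
}

# A small noise-free rate table lying exactly on a power law.
exact_power_law_table <- function(n = 8, intercept = -1, slope = 0.75,
                                  group = "g", model = "gompertz") {
  log_m <- seq(0, 4, length.out = n)
  kc <- 10^(intercept + (slope - 1) * log_m)
  gm <- allomax::growth_model(model)
  tibble::tibble(
    taxon = paste0(group, seq_len(n)), group = group, thermo = "endotherm",
    M_g = 10^log_m, BMatMG_g = gm$d * 10^log_m,
    Gmax_g_per_day = kc * 10^log_m, kC_per_day = kc,
    kD_per_day = kc / gm$d, weight = 1, excluded = FALSE
  )
}

# Containment test for a residual parallelogram, written from its published
# fields (slope, intercept range, x range) rather than package internals.
point_in_parallelogram_test <- function(par, x, y, tol = 1e-9) {
  in_x <- x >= par$x_range[1] - tol & x <= par$x_range[2] + tol
  lo <- par$intercept_range[1] + par$slope * x
  hi <- par$intercept_range[2] + par$slope * x
  in_x & y >= lo - tol & y <= hi + tol
}
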