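# Column naming shared by the rate-table schema
rate_column <- c(
  Gmax = "Gmax_g_per_day", kC = "kC_per_day", kD = "kD_per_day"
)
mass_column <- c(M = "M_g", BMatMG = "BMatMG_g")

#' Shear transformation on log-log coordinates
#'
#' Applies the map `(x, y) -> (x, x + y)` (or its inverse) to a table of
#' log-log coordinates. This is the geometric transformation induced by
#' regressing `G_max = M * kC` rather than `kC` on mass `M`: on logarithmic
#' axes the dependent variable gains the independent one additively, which
#' compresses scatter along the line `y = x`, adds exactly 1 to the fitted
#' slope, and leaves residuals untouched while inflating R-squared.
#'
#' @param data Data frame with the two coordinate columns.
#' @param x,y Column names (strings) of the coordinates; defaults `"x"`, `"y"`.
#' @param inverse If `TRUE`, applies `(x, y) -> (x, y - x)`.
#' @return A tibble with the same columns, `y` replaced by `x + y`
#'   (or `y - x`).
#' @examples
#' shear_transform(data.frame(x = 2, y = 3)) # y becomes 5
#' @export
shear_transform <- function(data, x = "x", y = "y", inverse = FALSE) {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  out <- tibble::as_tibble(data)
  stopifnot(all(is.finite(out[[x]])), all(is.finite(out[[y]])))
  out[[y]] <- if (inverse) out[[y]] - out[[x]] else out[[y]] + out[[x]]
  out
}

#' Log-log allometric regression
#'
#' Weighted ordinary least squares of `log10(rate)` on `log10(mass)`,
#' the workhorse of growth-rate allometry: `rate = a * mass^b` becomes
#' `log10(rate) = log10(a) + b * log10(mass)`. Excluded rows (`excluded ==
#' TRUE`) are dropped before fitting; 95% intervals use the t distribution
#' with `n - 2` degrees of freedom; for weighted fits R-squared is
#' `1 - wRSS / wTSS` about the weighted mean.
#'
#' @param data A rate table (see [read_rate_table()]): needs the mass column
#'   for `independent`, the rate column for `dependent`, and optionally
#'   `taxon`, `group`, `weight`, `excluded`.
#' @param dependent `"Gmax"`, `"kC"` or `"kD"`.
#' @param independent `"M"` or `"BMatMG"`.
#' @param weighted Use the `weight` column (default `TRUE` when present).
#' @param level Confidence level for parameter intervals.
#' @return An object of class `loglog_fit` with elements `intercept`
#'   (log10 a), `slope` (b), `ci95_intercept`, `ci95_slope`, `r2`, `n`,
#'   `residuals` (per point), `data` (the fitted log10 coordinates), `lm`
#'   (the underlying [stats::lm()] fit), `dependent`, `independent`,
#'   `weighted`.
#' @examples
#' pts <- data.frame(M_g = c(1, 100), kC_per_day = c(10, 1000))
#' fit_loglog(pts, "kC", "M") # slope 1, intercept 1, R2 = 1
#' @export
fit_loglog <- function(data, dependent = c("Gmax", "kC", "kD"),
                       independent = c("M", "BMatMG"),
                       weighted = TRUE, level = 0.95) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  ycol <- rate_column[[dependent]]
  xcol <- mass_column[[independent]]
  stopifnot(is.data.frame(data))
  if (!ycol %in% names(data)) {
    stop("rate column missing: ", ycol, call. = FALSE)
  }
  if (!xcol %in% names(data)) {
    stop("mass column missing: ", xcol, call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  if (!"taxon" %in% names(d)) d$taxon <- paste0("pt", seq_len(nrow(d)))
  if (!"group" %in% names(d)) d$group <- "all"
  if (!"weight" %in% names(d)) d$weight <- 1
  if (!"excluded" %in% names(d)) d$excluded <- FALSE
  d <- d[!isTRUE_vec(d$excluded), , drop = FALSE]
  mass <- d[[xcol]]
  rate <- d[[ycol]]
  bad <- !is.finite(mass) | !is.finite(rate) | mass <= 0 | rate <= 0
  if (any(bad)) {
    stop(
      "non-positive or missing mass/rate for: ",
      paste(utils::head(d$taxon[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(d) < 3) {
    stop("need at least 3 non-excluded points to fit", call. = FALSE)
  }
  w <- if (weighted) as.numeric(d$weight) else rep(1, nrow(d))
  if (any(!is.finite(w) | w < 0)) stop("weights must be nonnegative", call. = FALSE)
  fd <- tibble::tibble(
    taxon = d$taxon, group = d$group,
    x = log10(mass), y = log10(rate), weight = w
  )
  lmfit <- stats::lm(y ~ x, data = fd, weights = weight)
  cf <- stats::coef(lmfit)
  # noise-free power laws are legitimate inputs (synthetic checks): silence
  # summary.lm's perfect-fit chatter only
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  ci <- quiet_perfect(stats::confint(lmfit, level = level))
  s <- quiet_perfect(summary(lmfit))
  structure(
    list(
      dependent = dependent, independent = independent,
      intercept = unname(cf[[1]]), slope = unname(cf[[2]]),
      ci95_intercept = unname(ci[1, ]), ci95_slope = unname(ci[2, ]),
      r2 = s$r.squared, n = nrow(fd),
      residuals = unname(stats::residuals(lmfit)),
      sigma = s$sigma,
      data = fd, lm = lmfit, weighted = weighted, level = level
    ),
    class = "loglog_fit"
  )
}

# coerce possibly-character/logical/NA excluded column to logical TRUE mask
isTRUE_vec <- function(x) {
  if (is.logical(x)) {
    !is.na(x) & x
  } else {
    tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  }
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit> log10(%s) ~ log10(%s), n = %d%s\n  slope b = %.4f [%.4f, %.4f]\n  intercept log10(a) = %.4f [%.4f, %.4f]\n  R^2 = %.4f\n",
    x$dependent, x$independent, x$n,
    if (x$weighted) " (weighted)" else "",
    x$slope, x$ci95_slope[1], x$ci95_slope[2],
    x$intercept, x$ci95_intercept[1], x$ci95_intercept[2], x$r2
  ))
  invisible(x)
}

#' @rdname fit_loglog
#' @param x A `loglog_fit` object.
#' @param ... Unused.
#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept_log10a", "slope_b"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$ci95_intercept[1], x$ci95_slope[1]),
    conf.high = c(x$ci95_intercept[2], x$ci95_slope[2])
  )
}

#' @rdname fit_loglog
#' @export
glance.loglog_fit <- function(x, ...) {
  tibble::tibble(
    dependent = x$dependent, independent = x$independent,
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    sigma = x$sigma, n = x$n, weighted = x$weighted
  )
}

#' Compare peak-rate and mass-specific-rate regressions
#'
#' Fits the same points twice, once with the peak growth rate (`Gmax`) and
#' once with the mass-specific rate (`kC`, or `kD`) as the dependent
#' variable, and reports the two fits side by side. Because the dependent
#' variables differ by the factor `M` — the independent variable — the two
#' regressions are related by the shear transformation: identical residuals,
#' identical interval widths, slopes differing by exactly 1; only R-squared
#' changes.
#'
#' @inheritParams fit_loglog
#' @param specific `"kC"` or `"kD"` — the mass-specific dependent variable
#'   compared against `"Gmax"`.
#' @return A list with `fit_Gmax`, `fit_specific`, and `report`, a one-row
#'   tibble: `slope_Gmax`, `slope_specific`, `slope_difference`,
#'   `ci_width_Gmax`, `ci_width_specific`, `r2_Gmax`, `r2_specific`.
#' @export
compare_dependent_variables <- function(data, specific = c("kC", "kD"),
                                        independent = c("M", "BMatMG"),
                                        weighted = TRUE) {
  specific <- match.arg(specific)
  independent <- match.arg(independent)
  f1 <- fit_loglog(data, "Gmax", independent, weighted = weighted)
  f2 <- fit_loglog(data, specific, independent, weighted = weighted)
  list(
    fit_Gmax = f1,
    fit_specific = f2,
    report = tibble::tibble(
      slope_Gmax = f1$slope, slope_specific = f2$slope,
      slope_difference = f1$slope - f2$slope,
      ci_width_Gmax = diff(f1$ci95_slope),
      ci_width_specific = diff(f2$ci95_slope),
      r2_Gmax = f1$r2, r2_specific = f2$r2
    )
  )
}

band_grid <- function(fit, grid, n = 100) {
  if (is.null(grid)) {
    seq(min(fit$data$x), max(fit$data$x), length.out = n)
  } else {
    as.numeric(grid)
  }
}

#' Confidence and single-prediction bands for a log-log fit
#'
#' `confidence_band()` gives the pointwise 95% band for the mean response
#' (the constraint on the group's central tendency); `prediction_band()`
#' gives the 95% band for a single new observation (the constraint relevant
#' to classifying an individual species). The prediction band contains the
#' confidence band everywhere; the distinction between the two is the
#' statistical face of the ecological fallacy. Grid points outside the fitted
#' mass range are computed but flagged `extrapolated`.
#'
#' @param fit A [fit_loglog()] object.
#' @param grid Optional numeric vector of log10-mass values; defaults to 100
#'   points spanning the data.
#' @param level Band level.
#' @return A tibble of class `allometry_band` with columns `kind`, `x`,
#'   `fit`, `lower`, `upper`, `level`, `extrapolated`.
#' @export
confidence_band <- function(fit, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "loglog_fit"))
  x <- band_grid(fit, grid)
  pr <- stats::predict(fit$lm,
    newdata = data.frame(x = x),
    interval = "confidence", level = level
  )
  extrap <- x < min(fit$data$x) | x > max(fit$data$x)
  tibble::new_tibble(
    tibble::tibble(
      kind = "confidence", x = x, fit = pr[, "fit"],
      lower = pr[, "lwr"], upper = pr[, "upr"], level = level,
      extrapolated = extrap
    ),
    class = "allometry_band"
  )
}

#' @rdname confidence_band
#' @export
prediction_band <- function(fit, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "loglog_fit"))
  x <- band_grid(fit, grid)
  pr <- suppressWarnings(stats::predict(fit$lm,
    newdata = data.frame(x = x),
    interval = "prediction", level = level, weights = 1
  ))
  extrap <- x < min(fit$data$x) | x > max(fit$data$x)
  tibble::new_tibble(
    tibble::tibble(
      kind = "prediction", x = x, fit = pr[, "fit"],
      lower = pr[, "lwr"], upper = pr[, "upr"], level = level,
      extrapolated = extrap
    ),
    class = "allometry_band"
  )
}

#' Mass-adjusted growth rates under a fixed allometric slope
#'
#' Reduces the two-dimensional (mass, rate) comparison to one dimension by
#' adjusting every rate to the value it would take at a body mass of 1 g,
#' assuming a fixed scaling exponent `b`:
#' `adjusted = log10(rate) - b * log10(mass)`. Group distributions of the
#' adjusted rates can then be compared directly; the `overlap` interval is
#' the intersection of the per-group `[min, max]` ranges (empty when some
#' group separates cleanly).
#'
#' @inheritParams fit_loglog
#' @param b Fixed slope; 0.75 (metabolic-theory value) and 0.66 are the two
#'   conventional choices.
#' @param groups Optional character vector: restrict the overlap interval to
#'   these groups (all groups by default).
#' @return A list of class `fixed_slope_adjust`: `adjusted` (per-point
#'   tibble), `group_summary` (per-group min/median/max), `overlap`
#'   (named numeric `c(lower, upper)` or `NULL` when empty), `b`.
#' @export
fixed_slope_adjust <- function(data, b = 0.75,
                               dependent = c("Gmax", "kC", "kD"),
                               independent = c("M", "BMatMG"),
                               groups = NULL) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  stopifnot(is.numeric(b), length(b) == 1, is.finite(b))
  ycol <- rate_column[[dependent]]
  xcol <- mass_column[[independent]]
  d <- tibble::as_tibble(data)
  if (!"group" %in% names(d)) d$group <- "all"
  if (!"taxon" %in% names(d)) d$taxon <- paste0("pt", seq_len(nrow(d)))
  adj <- tibble::tibble(
    taxon = d$taxon, group = d$group,
    thermo = if ("thermo" %in% names(d)) d$thermo else NA_character_,
    adjusted = log10(d[[ycol]]) - b * log10(d[[xcol]])
  )
  gs <- adj |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$adjusted), median = stats::median(.data$adjusted),
      max = max(.data$adjusted), .groups = "drop"
    )
  use <- if (is.null(groups)) gs else gs[gs$group %in% groups, , drop = FALSE]
  lo <- max(use$min)
  hi <- min(use$max)
  structure(
    list(
      adjusted = adj, group_summary = gs,
      overlap = if (lo <= hi) c(lower = lo, upper = hi) else NULL,
      b = b, dependent = dependent, independent = independent
    ),
    class = "fixed_slope_adjust"
  )
}

#' @export
print.fixed_slope_adjust <- function(x, ...) {
  cat(sprintf(
    "<fixed_slope_adjust> log10(%s) - %.2f log10(%s), %d groups\n",
    x$dependent, x$b, x$independent, nrow(x$group_summary)
  ))
  if (is.null(x$overlap)) {
    cat("  no common overlap interval across groups\n")
  } else {
    cat(sprintf(
      "  overlap interval across groups: [%.3f, %.3f]\n",
      x$overlap[["lower"]], x$overlap[["upper"]]
    ))
  }
  invisible(x)
}
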