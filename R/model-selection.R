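#' Polynomial model family for curvature analysis
#'
#' The candidate family used to test whether log-log growth-rate allometry is
#' genuinely linear (a pure power law) or curved. Each member is a linear
#' model in powers of `x = log10(mass)` with the intercept always included;
#' the seven default members are the seven nonempty subsets of
#' `{x, x^2, x^3}`:
#' linear `{1}`, quadratic1 `{1,2}`, quadratic2 `{2}`, cubic1 `{1,2,3}`,
#' cubic2 `{1,3}`, cubic3 `{2,3}`, cubic4 `{3}`. The mapping is overridable
#' by supplying a named list of integer power vectors.
#'
#' @param family Optional named list of integer vectors (subsets of 1:3 and
#'   beyond) to override the default labels.
#' @return A named list of integer vectors of class `poly_family`.
#' @examples
#' names(poly_family())
#' @export
poly_family <- function(family = NULL) {
  if (is.null(family)) {
    family <- list(
      linear = 1L,
      quadratic1 = c(1L, 2L),
      quadratic2 = 2L,
      cubic1 = c(1L, 2L, 3L),
      cubic2 = c(1L, 3L),
      cubic3 = c(2L, 3L),
      cubic4 = 3L
    )
  }
  stopifnot(is.list(family), !is.null(names(family)), all(nzchar(names(family))))
  if (anyDuplicated(purrr::map_chr(family, paste, collapse = ","))) {
    stop("duplicated power sets in model family (labels must map to distinct powers)",
      call. = FALSE
    )
  }
  structure(purrr::map(family, as.integer), class = "poly_family")
}

#' Fit one polynomial model on log-log coordinates
#'
#' Least squares for `y = b0 + sum_i b_i x^i` over the included powers,
#' optionally weighted.
#'
#' @param x,y Numeric vectors (log10 mass, log10 rate).
#' @param powers Integer vector of included powers (intercept implicit).
#' @param weights Optional nonnegative weights.
#' @return A list with `coefficients` (named, intercept first), `rss`
#'   (weighted when weights given), `fitted`, `residuals`, `n_coef`.
#' @export
fit_poly <- function(x, y, powers, weights = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  powers <- sort(unique(as.integer(powers)))
  stopifnot(length(powers) >= 1, all(powers >= 1))
  n <- length(x)
  if (n <= length(powers) + 1) {
    stop("need more points than coefficients", call. = FALSE)
  }
  X <- cbind(1, vapply(powers, function(p) x^p, numeric(n)))
  colnames(X) <- c("(Intercept)", paste0("x^", powers))
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(all(is.finite(w)), all(w >= 0))
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design (degenerate x values)", call. = FALSE)
  }
  fit <- stats::lm.wfit(X, y, w)
  fitted <- drop(X %*% fit$coefficients)
  res <- y - fitted
  list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    rss = sum(w * res^2),
    fitted = fitted,
    residuals = res,
    n_coef = ncol(X)
  )
}

#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-likelihood form:
#' `AICc = n * log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)`, with `k` counting
#' the regression coefficients plus one for the residual variance. Returns
#' `NA` (inadmissible) when `n <= k + 1`, where the correction term blows up.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Parameter count (coefficients + 1).
#' @return The AICc value, or `NA_real_` for inadmissible `n`, `k`.
#' @examples
#' aicc(rss = 20, n = 20, k = 2) # 0 + 4 + 12/17
#' @export
aicc <- function(rss, n, k) {
  stopifnot(is.numeric(rss), is.numeric(n), is.numeric(k), rss >= 0)
  if (n <= k + 1) {
    return(NA_real_)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Per-group model-selection table
#'
#' Fits every member of a polynomial family to each group's log-log
#' (mass, rate) data and ranks them by AICc. The best model in each group has
#' `delta_aicc = 0`; models with `delta_aicc < 2` carry strong statistical
#' support. Any group whose best-supported model includes a power above 1
#' shows curvature, contradicting a simple power law. Exact AICc ties are
#' broken in favour of the model with fewer parameters (recorded in `tie`).
#'
#' @param data A rate table with a `group` column.
#' @param dependent,independent Coordinate choice, as in [fit_loglog()].
#' @param family A [poly_family()] (or named list of power vectors).
#' @param weighted Use per-taxon weights (weighted RSS in the likelihood).
#' @param include_excluded Keep rows flagged `excluded`.
#' @return A tibble of class `selection_table`: one row per group x model
#'   with `group`, `model`, `rss`, `k`, `n`, `aicc`, `delta_aicc`,
#'   `strong_support`, `best`, `admissible`, `tie`.
#' @export
selection_table <- function(data, dependent = c("kC", "kD", "Gmax"),
                            independent = c("M", "BMatMG"),
                            family = poly_family(), weighted = TRUE,
                            include_excluded = FALSE) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  family <- poly_family(if (inherits(family, "poly_family")) unclass(family) else family)
  d <- tibble::as_tibble(data)
  if (!"group" %in% names(d)) d$group <- "all"
  if (!include_excluded && "excluded" %in% names(d)) {
    d <- d[!isTRUE_vec(d$excluded), , drop = FALSE]
  }
  if (!"weight" %in% names(d)) d$weight <- 1
  co <- loglog_coords(d, dependent, independent)
  co$group <- as.character(d$group)
  co$weight <- if (weighted) as.numeric(d$weight) else 1
  rows <- purrr::map(unique(co$group), function(g) {
    sub <- co[co$group == g, , drop = FALSE]
    per_model <- purrr::imap(family, function(powers, label) {
      k <- length(powers) + 2L # coefficients (incl. intercept) + variance
      fit <- tryCatch(
        fit_poly(sub$x, sub$y, powers, weights = sub$weight),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        tibble::tibble(
          group = g, model = label, rss = NA_real_, k = k,
          n = nrow(sub), aicc = NA_real_
        )
      } else {
        tibble::tibble(
          group = g, model = label, rss = fit$rss, k = k,
          n = nrow(sub), aicc = aicc(fit$rss, nrow(sub), k)
        )
      }
    })
    tab <- dplyr::bind_rows(per_model)
    tab$admissible <- is.finite(tab$aicc)
    best_aicc <- min(tab$aicc[tab$admissible])
    tab$delta_aicc <- tab$aicc - best_aicc
    # break exact ties by smaller k: only the winner keeps delta 0 flag 'best'
    at_min <- which(tab$admissible & tab$delta_aicc <= 1e-12)
    winner <- at_min[which.min(tab$k[at_min])]
    tab$best <- seq_len(nrow(tab)) == winner
    tab$tie <- length(at_min) > 1
    tab$strong_support <- tab$admissible & tab$delta_aicc < 2
    tab
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "selection_table")
}

#' Wide Delta-AICc view of a selection table
#'
#' @param table A [selection_table()] result.
#' @param digits Decimals for the Delta-AICc values.
#' @return A tibble, rows = groups, columns = model labels.
#' @export
selection_wide <- function(table, digits = 3) {
  stopifnot(is.data.frame(table), all(c("group", "model", "delta_aicc") %in% names(table)))
  table |>
    dplyr::mutate(delta_aicc = round(.data$delta_aicc, digits)) |>
    dplyr::select("group", "model", "delta_aicc") |>
    tidyr::pivot_wider(names_from = "model", values_from = "delta_aicc")
}
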