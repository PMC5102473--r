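#' Ontogenetic adjustment of basal metabolic rate
#'
#' BMR compilations measure animals at whatever body mass they had on the
#' respirometry bench (`M_met_g`), often well below adult mass. Assuming the
#' interspecific scaling `BMR ~ M^b` also holds through ontogeny, the
#' measured value can be projected to adult mass:
#' `BMR_adj = BMR * (M / M_met)^b`.
#'
#' @param data Metabolic table with columns `BMR_W`, `M_met_g`, `M_g`.
#' @param b Ontogenetic scaling exponent (0.75, the Kleiber value, by
#'   default).
#' @return The input as a tibble with a `BMR_adj_W` column appended. Records
#'   with `M_met_g > M_g` are retained with a warning (juvenile/adult mass
#'   inconsistencies occur in real compilations); `M_met_g <= 0` is an error.
#' @examples
#' bmr_adjust(data.frame(BMR_W = 1, M_met_g = 10, M_g = 160))$BMR_adj_W # 8
#' @export
bmr_adjust <- function(data, b = 0.75) {
  stopifnot(is.data.frame(data))
  stopifnot(all(c("BMR_W", "M_met_g", "M_g") %in% names(data)))
  d <- tibble::as_tibble(data)
  if (any(!is.finite(d$M_met_g) | d$M_met_g <= 0)) {
    stop("M_met_g must be positive", call. = FALSE)
  }
  if (any(d$M_met_g > d$M_g)) {
    warning("some records have measurement mass above adult mass; retained")
  }
  d$BMR_adj_W <- d$BMR_W * (d$M_g / d$M_met_g)^b
  d
}

#' Direct test of a proportional BMR-growth-rate link
#'
#' Tests the claim `BMR = c * G_max` record by record: the predicted BMR is
#' `c * G_max` and the report gives the worst over-prediction factor
#' (`max(predicted / observed)`), the worst under-prediction factor
#' (`max(observed / predicted)`), and their product, the total spread a
#' single proportionality constant would have to cover. The constant `c`
#' absorbs the unit bridge between watts and g/day as used by the source
#' compilation; 0.6 is the published value.
#'
#' @param data Metabolic table with `BMR_W` (or `BMR_adj_W`) and
#'   `Gmax_g_per_day`.
#' @param c Proportionality constant.
#' @param use_adjusted Test against `BMR_adj_W` (computing it via
#'   [bmr_adjust()] if absent) instead of raw `BMR_W`.
#' @param b Exponent passed to [bmr_adjust()] when needed.
#' @return A list of class `direct_test`: `over_factor`, `under_factor`,
#'   `total_range`, `n`, `records` (per-record tibble with `predicted`,
#'   `observed`, `ratio`), `c`, `use_adjusted`. Records without a positive
#'   `Gmax_g_per_day` are skipped with a warning.
#' @export
direct_test <- function(data, c = 0.6, use_adjusted = FALSE, b = 0.75) {
  stopifnot(is.data.frame(data), "Gmax_g_per_day" %in% names(data))
  stopifnot(is.numeric(c), length(c) == 1, c > 0)
  d <- tibble::as_tibble(data)
  if (use_adjusted && !"BMR_adj_W" %in% names(d)) d <- bmr_adjust(d, b = b)
  obs_col <- if (use_adjusted) "BMR_adj_W" else "BMR_W"
  stopifnot(obs_col %in% names(d))
  ok <- is.finite(d$Gmax_g_per_day) & d$Gmax_g_per_day > 0
  if (any(!ok)) {
    warning(sum(!ok), " record(s) without positive G_max skipped")
    d <- d[ok, , drop = FALSE]
  }
  stopifnot(nrow(d) >= 1, all(d[[obs_col]] > 0))
  predicted <- c * d$Gmax_g_per_day
  observed <- d[[obs_col]]
  ratio <- predicted / observed
  records <- tibble::tibble(
    taxon = if ("taxon" %in% names(d)) d$taxon else paste0("rec", seq_len(nrow(d))),
    predicted = predicted, observed = observed, ratio = ratio
  )
  structure(
    list(
      over_factor = max(ratio),
      under_factor = max(1 / ratio),
      total_range = max(ratio) * max(1 / ratio),
      n = nrow(d), records = records, c = c, use_adjusted = use_adjusted
    ),
    class = "direct_test"
  )
}

#' @export
print.direct_test <- function(x, ...) {
  cat(sprintf(
    "<direct_test> BMR%s = %.3g * G_max on %d records\n  worst over-prediction: factor %.3g; worst under-prediction: factor %.3g\n  total spread: factor %.3g\n",
    if (x$use_adjusted) "_adj" else "", x$c, x$n,
    x$over_factor, x$under_factor, x$total_range
  ))
  invisible(x)
}

#' Pairwise-correlation transitivity report
#'
#' Fits the three pairwise log-log regressions among mass-specific growth
#' rate, BMR and body mass — `kC ~ M`, `BMR ~ M`, `BMR ~ kC` — and reports
#' their slopes and R-squared side by side. Correlation is not transitive:
#' both rates can scale with mass while being essentially uncorrelated with
#' each other, which is exactly what composing two allometric regressions
#' into a growth-metabolism law (the fallacy of averages) overlooks. When
#' the two log-scale noises are independent, the implied cross R-squared is
#' the product of the two marginal R-squared values.
#'
#' @param data Metabolic table with `M_g`, `BMR_W` (or `BMR_adj_W`) and
#'   `kC_per_day`.
#' @param use_adjusted Regress `BMR_adj_W` instead of `BMR_W`.
#' @param b Exponent passed to [bmr_adjust()] when the adjusted column must
#'   be computed.
#' @param weighted Use per-taxon weights if a `weight` column is present.
#' @return A list of class `transitivity_report`: `fits` (named list of
#'   [fit_loglog()]-style fits for `kC_vs_M`, `BMR_vs_M`, `BMR_vs_kC`) and
#'   `report` (tibble with `pair`, `slope`, `r2`, `n`).
#' @export
transitivity_report <- function(data, use_adjusted = FALSE, b = 0.75,
                                weighted = TRUE) {
  stopifnot(is.data.frame(data))
  stopifnot(all(c("M_g", "kC_per_day") %in% names(data)))
  d <- tibble::as_tibble(data)
  if (use_adjusted && !"BMR_adj_W" %in% names(d)) d <- bmr_adjust(d, b = b)
  bmr_col <- if (use_adjusted) "BMR_adj_W" else "BMR_W"
  stopifnot(bmr_col %in% names(d))
  # reuse the allometry machinery by renaming into the rate-table schema:
  # BMR plays the role of a "rate" with M or kC as the independent variable
  d_kC_M <- d
  fit_kC_M <- fit_loglog(d_kC_M, "kC", "M", weighted = weighted)
  d_BMR_M <- d
  d_BMR_M$Gmax_g_per_day <- d[[bmr_col]]
  fit_BMR_M <- fit_loglog(d_BMR_M, "Gmax", "M", weighted = weighted)
  d_BMR_kC <- d
  d_BMR_kC$Gmax_g_per_day <- d[[bmr_col]]
  d_BMR_kC$M_g <- d$kC_per_day
  fit_BMR_kC <- fit_loglog(d_BMR_kC, "Gmax", "M", weighted = weighted)
  fits <- list(kC_vs_M = fit_kC_M, BMR_vs_M = fit_BMR_M, BMR_vs_kC = fit_BMR_kC)
  report <- tibble::tibble(
    pair = names(fits),
    slope = unname(purrr::map_dbl(fits, "slope")),
    r2 = unname(purrr::map_dbl(fits, "r2")),
    n = unname(purrr::map_int(fits, "n")),
    bmr = ifelse(grepl("BMR", names(fits)), bmr_col, NA_character_)
  )
  structure(
    list(fits = fits, report = report, use_adjusted = use_adjusted),
    class = "transitivity_report"
  )
}

#' @export
print.transitivity_report <- function(x, ...) {
  cat("<transitivity_report>\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      "  %-10s slope = %8.4f  R^2 = %.4f  (n = %d)\n",
      r$pair[i], r$slope[i], r$r2[i], r$n[i]
    ))
  }
  invisible(x)
}
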