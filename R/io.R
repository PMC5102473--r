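rate_table_cols <- c(
  "taxon", "group", "thermo", "M_g", "BMatMG_g", "Gmax_g_per_day",
  "kC_per_day", "kD_per_day", "weight", "excluded"
)

#' Read and validate a species-level rate table
#'
#' Reads the rate-table CSV schema (`taxon, group, thermo, M_g, BMatMG_g,
#' Gmax_g_per_day, kC_per_day, kD_per_day, weight, excluded`, with an
#' optional `model` column; missing optional columns get defaults). Blank
#' rate cells are filled from the algebraic identities where derivable:
#' `kC = Gmax / M`, `Gmax = kC * M`, and — when a growth model is named —
#' `BMatMG = d * M` and `kD = kC / d`. Weights are normalised so each taxon
#' carries total weight 1, split equally across its rows (the convention for
#' compilations with multiple series per taxon).
#'
#' @param path CSV path (or anything [readr::read_csv()] accepts).
#' @param default_model Model assumed for rows lacking a `model` entry when
#'   model constants are needed (`NULL` leaves underivable cells `NA`).
#' @return A validated rate-table tibble.
#' @export
read_rate_table <- function(path, default_model = "gompertz") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("taxon", "group", "M_g")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("rate table missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  d <- tibble::as_tibble(raw)
  if (!"thermo" %in% names(d)) d$thermo <- "unknown"
  if (!"weight" %in% names(d)) d$weight <- NA_real_
  if (!"excluded" %in% names(d)) d$excluded <- FALSE
  d$excluded <- isTRUE_vec(d$excluded)
  for (col in c("BMatMG_g", "Gmax_g_per_day", "kC_per_day", "kD_per_day")) {
    if (!col %in% names(d)) d[[col]] <- NA_real_
  }
  bad <- !is.finite(d$M_g) | d$M_g <= 0
  if (any(bad)) {
    stop(
      "non-positive mass for taxon: ",
      paste(utils::head(d$taxon[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  # fill the shear identity both ways
  i <- is.na(d$kC_per_day) & !is.na(d$Gmax_g_per_day)
  d$kC_per_day[i] <- d$Gmax_g_per_day[i] / d$M_g[i]
  i <- is.na(d$Gmax_g_per_day) & !is.na(d$kC_per_day)
  d$Gmax_g_per_day[i] <- d$kC_per_day[i] * d$M_g[i]
  # model-dependent fills
  model <- if ("model" %in% names(d)) d$model else rep(NA_character_, nrow(d))
  model[is.na(model) | !nzchar(model)] <- default_model %||% NA_character_
  dconst <- vapply(model, function(m) {
    if (is.na(m)) NA_real_ else growth_model(m)$d
  }, numeric(1))
  i <- is.na(d$BMatMG_g) & !is.na(dconst)
  d$BMatMG_g[i] <- dconst[i] * d$M_g[i]
  i <- is.na(d$kD_per_day) & !is.na(d$kC_per_day) & !is.na(dconst)
  d$kD_per_day[i] <- d$kC_per_day[i] / dconst[i]
  d$model <- model
  # per-taxon weight normalisation: each taxon's rows share total weight 1
  d <- d |>
    dplyr::group_by(.data$taxon) |>
    dplyr::mutate(weight = ifelse(is.na(.data$weight), 1 / dplyr::n(), .data$weight)) |>
    dplyr::ungroup()
  neg_rate <- (!is.na(d$kC_per_day) & d$kC_per_day <= 0) |
    (!is.na(d$Gmax_g_per_day) & d$Gmax_g_per_day <= 0)
  if (any(neg_rate)) {
    stop(
      "non-positive rate for taxon: ",
      paste(utils::head(d$taxon[neg_rate], 5), collapse = ", "),
      call. = FALSE
    )
  }
  d[, c(rate_table_cols[rate_table_cols %in% names(d)],
        setdiff(names(d), rate_table_cols))]
}

#' Write a rate table to CSV
#'
#' @param data Rate-table tibble.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_rate_table <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, na = "NA")
  invisible(data)
}

#' Read an age-mass series table
#'
#' Schema: `taxon, age_days, mass_g, provenance` (provenance `observed` or
#' `neonate`; missing defaults to `observed`).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_age_mass <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("taxon", "age_days", "mass_g"), names(d))
  if (length(missing) > 0) {
    stop("age-mass table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"provenance" %in% names(d)) d$provenance <- "observed"
  d$provenance[is.na(d$provenance)] <- "observed"
  stopifnot(all(is.finite(d$age_days)), all(d$mass_g > 0))
  tibble::as_tibble(d)
}

#' Read a metabolic table
#'
#' Schema: `taxon, group, thermo, BMR_W, M_met_g, M_g, Gmax_g_per_day,
#' kC_per_day` (the last two optional; `kC` is filled from `Gmax / M` when
#' absent).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_metabolic <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("taxon", "BMR_W", "M_met_g", "M_g"), names(d))
  if (length(missing) > 0) {
    stop("metabolic table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  d <- tibble::as_tibble(d)
  if (!"group" %in% names(d)) d$group <- "all"
  if (!"kC_per_day" %in% names(d) && "Gmax_g_per_day" %in% names(d)) {
    d$kC_per_day <- d$Gmax_g_per_day / d$M_g
  }
  stopifnot(all(d$BMR_W > 0), all(d$M_g > 0))
  d
}

#' Run the full reanalysis pipeline
#'
#' Executes every analysis stage on a rate table (and optionally a metabolic
#' table): both dependent-variable regressions per group with the shear
#' comparison, confidence/prediction bands, hull-membership and
#' nearest-line matrices, residual parallelograms, fixed-slope adjusted
#' rates at each requested slope, the polynomial selection table, pooled
#' endotherm/ectotherm overlap, and — when metabolic data are present — the
#' direct proportionality test and the transitivity report. Stages whose
#' inputs are missing are skipped with a notice in `$log`.
#'
#' @param rates Rate-table tibble (from [read_rate_table()] or a generator).
#' @param metabolic Optional metabolic tibble.
#' @param dependent,independent Coordinate choice for the specific-rate
#'   analyses.
#' @param fixed_slopes Slopes for [fixed_slope_adjust()].
#' @param weighted Use per-taxon weights.
#' @param seed Seed recorded in the bundle and set before any stochastic
#'   stage.
#' @return A list of class `report_bundle` with one element per stage plus
#'   `config` (including a reproducibility hash of the inputs) and `log`.
#' @export
run_pipeline <- function(rates, metabolic = NULL,
                         dependent = c("kC", "kD"),
                         independent = c("M", "BMatMG"),
                         fixed_slopes = c(0.75, 0.66),
                         weighted = TRUE, seed = 1) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  set.seed(seed)
  rates <- tibble::as_tibble(rates)
  log <- character()
  note <- function(msg) log <<- c(log, msg)
  groups <- unique(as.character(rates$group))
  safe <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      note(sprintf("stage '%s' skipped: %s", label, conditionMessage(e)))
      NULL
    })
  }
  fits <- purrr::map(groups, function(g) {
    safe(
      paste0("fit:", g),
      compare_dependent_variables(rates[rates$group == g, , drop = FALSE],
        specific = dependent, independent = independent, weighted = weighted
      )
    )
  })
  names(fits) <- groups
  fits <- purrr::compact(fits)
  regression_report <- dplyr::bind_rows(purrr::imap(fits, function(f, g) {
    dplyr::mutate(f$report, group = g, .before = 1)
  }))
  bands <- purrr::map(fits, function(f) {
    list(
      confidence = confidence_band(f$fit_specific),
      prediction = prediction_band(f$fit_specific)
    )
  })
  hulls <- safe("hulls", hull_membership_matrix(rates, dependent, independent))
  nearest <- safe(
    "nearest_line",
    nearest_line_classification(rates, dependent, independent, weighted = weighted)
  )
  parallelograms <- purrr::map(fits, function(f) residual_parallelogram(f$fit_specific))
  fixed <- purrr::map(fixed_slopes, function(b) {
    safe(
      paste0("fixed_slope:", b),
      fixed_slope_adjust(rates, b = b, dependent = "Gmax", independent = independent)
    )
  })
  names(fixed) <- paste0("b_", fixed_slopes)
  selection <- safe(
    "selection",
    selection_table(rates, dependent, independent, weighted = weighted)
  )
  pooled <- safe("pooled", pooled_overlap(rates, dependent, independent, weighted = weighted))
  metabolic_stage <- NULL
  if (!is.null(metabolic)) {
    metabolic_stage <- list(
      direct = safe("direct_test", direct_test(metabolic)),
      direct_adjusted = safe("direct_test_adj", direct_test(metabolic, use_adjusted = TRUE)),
      transitivity = safe("transitivity", transitivity_report(metabolic))
    )
  } else {
    note("metabolic stages skipped: no metabolic table supplied")
  }
  config <- list(
    dependent = dependent, independent = independent,
    fixed_slopes = fixed_slopes, weighted = weighted, seed = seed,
    n_points = nrow(rates), groups = groups,
    hash = rlang::hash(list(rates, metabolic, dependent, independent,
                            fixed_slopes, weighted, seed)),
    package_version = as.character(utils::packageVersion("allomax"))
  )
  structure(
    list(
      regressions = fits, regression_report = regression_report,
      bands = bands, hulls = hulls, nearest_line = nearest,
      parallelograms = parallelograms, fixed_slope = fixed,
      selection = selection, pooled = pooled, metabolic = metabolic_stage,
      config = config, log = log
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> %d groups, %d points; stages: %s\n",
    length(x$config$groups), x$config$n_points,
    paste(names(Filter(Negate(is.null), x[1:10])), collapse = ", ")
  ))
  if (length(x$log) > 0) cat("  notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the tabular stages as CSV, the scalar/nested results plus config
#' (with its hash and seed) as JSON, and a manifest listing the files.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p)
    files <<- c(files, name)
  }
  put_csv(bundle$regression_report, "regressions.csv")
  if (!is.null(bundle$hulls)) {
    put_csv(
      tibble::as_tibble(bundle$hulls$counts, rownames = "points"),
      "hull_membership.csv"
    )
  }
  if (!is.null(bundle$nearest_line)) {
    put_csv(
      tibble::as_tibble(bundle$nearest_line$counts, rownames = "points"),
      "nearest_line.csv"
    )
    put_csv(bundle$nearest_line$assignments, "nearest_line_assignments.csv")
  }
  if (!is.null(bundle$selection)) {
    put_csv(selection_wide(bundle$selection), "selection_delta_aicc.csv")
    put_csv(tibble::as_tibble(bundle$selection), "selection_full.csv")
  }
  for (nm in names(bundle$fixed_slope)) {
    fs <- bundle$fixed_slope[[nm]]
    if (!is.null(fs)) put_csv(fs$adjusted, paste0("fixed_slope_", nm, ".csv"))
  }
  meta <- list(config = bundle$config, log = bundle$log)
  if (!is.null(bundle$metabolic)) {
    meta$metabolic <- list(
      direct = bundle$metabolic$direct[c("over_factor", "under_factor", "total_range", "n")],
      direct_adjusted = bundle$metabolic$direct_adjusted[
        c("over_factor", "under_factor", "total_range", "n")
      ],
      transitivity = bundle$metabolic$transitivity$report
    )
  }
  if (!is.null(bundle$pooled)) {
    meta$pooled_overlap_fraction <- bundle$pooled$overlap_fraction
  }
  jsonlite::write_json(meta, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, "report.json")
  manifest <- tibble::tibble(file = files)
  jsonlite::write_json(
    list(files = files, hash = bundle$config$hash, seed = bundle$config$seed),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
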