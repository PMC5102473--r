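#' Trait distributions for the classification bootstrap
#'
#' Hypothesis distributions for a scalar trait (such as adult body mass in
#' kg). `trait_normal()` is a parametric stand-in specified by mean and sd;
#' `trait_empirical()` wraps an observed sample and resamples it with
#' replacement.
#'
#' @param label Hypothesis label.
#' @param mean,sd Normal parameters (sd > 0).
#' @param values Nonempty numeric sample for the empirical form.
#' @return An object of class `trait_distribution` with a `mean`, a `draw(n)`
#'   sampler, and the defining parameters.
#' @export
trait_normal <- function(label, mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(
    list(
      label = label, form = "normal", mean = mean, sd = sd,
      draw = function(n) stats::rnorm(n, mean, sd)
    ),
    class = "trait_distribution"
  )
}

#' @rdname trait_normal
#' @export
trait_empirical <- function(label, values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  structure(
    list(
      label = label, form = "empirical", mean = mean(values), values = values,
      draw = function(n) sample(values, n, replace = TRUE)
    ),
    class = "trait_distribution"
  )
}

#' @export
print.trait_distribution <- function(x, ...) {
  cat(sprintf(
    "<trait_distribution> %s (%s), mean = %.3f\n", x$label, x$form, x$mean
  ))
  invisible(x)
}

# equal-weight mixture of two trait distributions (each draw picks its source
# group independently with probability 1/2)
trait_mixture <- function(label, dist_a, dist_b) {
  structure(
    list(
      label = label, form = "mixture",
      mean = (dist_a$mean + dist_b$mean) / 2,
      components = list(dist_a, dist_b),
      draw = function(n) {
        pick <- stats::runif(n) < 0.5
        out <- numeric(n)
        out[pick] <- dist_a$draw(sum(pick))
        out[!pick] <- dist_b$draw(sum(!pick))
        out
      }
    ),
    class = "trait_distribution"
  )
}

#' Classify an all-one-group sample among trait hypotheses
#'
#' Given a sample assumed to come entirely from one of the hypothesised
#' distributions, assigns the hypothesis whose mean lies nearest the observed
#' sample mean (default), or the maximum-likelihood hypothesis under normal
#' likelihoods (`rule = "likelihood"`, normal hypotheses only). Ties go to
#' the lowest-index hypothesis and are flagged.
#'
#' @param sample Nonempty numeric vector of trait values.
#' @param hypotheses List of [trait_normal()]/[trait_empirical()] objects.
#' @param rule `"nearest_mean"` or `"likelihood"`.
#' @return A list with `label`, `index`, `tie`.
#' @export
classify_sample <- function(sample, hypotheses,
                            rule = c("nearest_mean", "likelihood")) {
  rule <- match.arg(rule)
  stopifnot(length(sample) >= 1, is.list(hypotheses), length(hypotheses) >= 2)
  score <- switch(rule,
    nearest_mean = {
      m <- mean(sample)
      -abs(m - purrr::map_dbl(hypotheses, "mean"))
    },
    likelihood = purrr::map_dbl(hypotheses, function(h) {
      if (h$form != "normal") {
        stop("likelihood rule requires normal hypotheses", call. = FALSE)
      }
      sum(stats::dnorm(sample, h$mean, h$sd, log = TRUE))
    })
  )
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  list(
    label = hypotheses[[cand[[1]]]]$label,
    index = cand[[1]],
    tie = length(cand) > 1
  )
}

# correct-classification rate for each hypothesis at group size n
classification_accuracy <- function(hypotheses, n, replicates, rule) {
  vapply(seq_along(hypotheses), function(i) {
    h <- hypotheses[[i]]
    draws <- matrix(h$draw(n * replicates), nrow = replicates)
    if (rule == "nearest_mean") {
      means <- rowMeans(draws)
      hyp_means <- purrr::map_dbl(hypotheses, "mean")
      # nearest mean; ties resolve to lowest index, matching classify_sample
      idx <- apply(abs(outer(means, hyp_means, "-")), 1, which.min)
      mean(idx == i)
    } else {
      mean(vapply(seq_len(replicates), function(r) {
        classify_sample(draws[r, ], hypotheses, rule = rule)$index == i
      }, logical(1)))
    }
  }, numeric(1))
}

#' Minimal group size for confident classification
#'
#' Smallest group size `N` such that a sample of `N` values, all drawn from
#' one (unknown) hypothesis, is classified correctly with frequency at least
#' `confidence` for *every* hypothesis, estimated by bootstrap simulation.
#' Two scenarios mirror the strength of the prior constraint:
#' `"two_pure_groups"` allows only the two pure hypotheses; `"pure_or_mixed"`
#' adds an equal-probability mixture as a third hypothesis, which always
#' demands a larger `N` — relaxing the constraint on group composition makes
#' classification harder, and with unknown composition it becomes impossible.
#' The search doubles `N` until the requirement holds, then bisects.
#'
#' @param dist_a,dist_b Trait distributions ([trait_normal()] /
#'   [trait_empirical()]).
#' @param scenario `"two_pure_groups"` or `"pure_or_mixed"`.
#' @param confidence Required per-hypothesis correct-classification rate
#'   (in (0.5, 1)).
#' @param replicates Bootstrap replicates per evaluation (>= 1000 for
#'   reported results).
#' @param rule Classification rule, see [classify_sample()].
#' @param n_max Give up above this `N` (accuracy plateau below `confidence`
#'   is reported as unattainable).
#' @param seed Optional seed for reproducibility.
#' @return A list of class `minimal_group_size`: `N` (`NA` when
#'   unattainable), `attained` (logical), `curve` (tibble of evaluated `N`
#'   with min/per-hypothesis accuracy), `scenario`, `confidence`.
#' @export
minimal_group_size <- function(dist_a, dist_b,
                               scenario = c("two_pure_groups", "pure_or_mixed"),
                               confidence = 0.95, replicates = 10000,
                               rule = c("nearest_mean", "likelihood"),
                               n_max = 100000, seed = NULL) {
  scenario <- match.arg(scenario)
  rule <- match.arg(rule)
  stopifnot(confidence > 0.5, confidence < 1, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  hypotheses <- list(dist_a, dist_b)
  if (scenario == "pure_or_mixed") {
    hypotheses <- c(hypotheses, list(trait_mixture(
      paste0(dist_a$label, "+", dist_b$label), dist_a, dist_b
    )))
  }
  labels <- purrr::map_chr(hypotheses, "label")
  evals <- list()
  eval_n <- function(n) {
    acc <- classification_accuracy(hypotheses, n, replicates, rule)
    evals[[length(evals) + 1]] <<- tibble::tibble(
      N = n, hypothesis = labels, accuracy = acc
    )
    min(acc)
  }
  # doubling phase
  n <- 1L
  ok_n <- NA_integer_
  while (n <= n_max) {
    if (eval_n(n) >= confidence) {
      ok_n <- n
      break
    }
    n <- n * 2L
  }
  if (is.na(ok_n)) {
    return(structure(
      list(
        N = NA_integer_, attained = FALSE,
        curve = dplyr::bind_rows(evals), scenario = scenario,
        confidence = confidence
      ),
      class = "minimal_group_size"
    ))
  }
  lo <- max(1L, ok_n %/% 2L) # largest failing power of two (or 1)
  hi <- ok_n
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2L)
    if (eval_n(mid) >= confidence) hi <- mid else lo <- mid
  }
  structure(
    list(
      N = as.integer(hi), attained = TRUE,
      curve = dplyr::bind_rows(evals), scenario = scenario,
      confidence = confidence
    ),
    class = "minimal_group_size"
  )
}

#' @export
print.minimal_group_size <- function(x, ...) {
  if (x$attained) {
    cat(sprintf(
      "<minimal_group_size> %s: N >= %d at %.0f%% confidence\n",
      x$scenario, x$N, 100 * x$confidence
    ))
  } else {
    cat(sprintf(
      "<minimal_group_size> %s: unattainable within search range\n", x$scenario
    ))
  }
  invisible(x)
}
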