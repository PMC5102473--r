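test_that("convex hull handles simple, random and degenerate point sets", {
  h3 <- convex_hull(c(0, 1, 0), c(0, 0, 1))
  expect_equal(nrow(h3$vertices), 3)
  expect_false(h3$degenerate)
  # hull of the hull's vertices equals itself (idempotence)
  set.seed(2)
  x <- rnorm(25)
  y <- rnorm(25)
  h <- convex_hull(x, y)
  h2 <- convex_hull(h$vertices[, 1], h$vertices[, 2])
  expect_equal(
    h$vertices[order(h$vertices[, 1], h$vertices[, 2]), ],
    h2$vertices[order(h2$vertices[, 1], h2$vertices[, 2]), ]
  )
  # vertices agree with the brute-force extreme-point oracle: hull vertices
  # are exactly the points whose removal changes membership of some extreme
  inside_all <- brute_force_membership(x, y, x, y)
  expect_true(all(inside_all))
  # every hull vertex is a point of the set, and non-vertices are strictly
  # inside the hull of the remaining points only if not extreme
  expect_true(all(h$vertices[, 1] %in% x))
  # collinear points degrade to their extreme segment
  hc <- convex_hull(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_true(hc$degenerate)
  expect_equal(nrow(hc$vertices), 2)
  expect_equal(unname(hc$vertices[, 1]), c(0, 3))
  h1 <- convex_hull(1, 1)
  expect_true(h1$degenerate)
})

test_that("point-in-hull agrees with the brute-force supporting-line oracle", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    sx <- runif(n, 0, 3)
    sy <- runif(n, -2, 2)
    h <- convex_hull(sx, sy)
    qx <- runif(40, -0.5, 3.5)
    qy <- runif(40, -2.5, 2.5)
    expect_equal(
      point_in_hull(h, qx, qy),
      brute_force_membership(sx, sy, qx, qy)
    )
    # boundary points (the defining set itself) count as inside
    expect_true(all(point_in_hull(h, sx, sy)))
  }
})

test_that("hull-membership diagonals equal group sizes and disjoint clusters do not mix", {
  set.seed(4)
  d <- default_scenario(n = 25)
  mm <- hull_membership_matrix(d, "kC", "M")
  expect_equal(unname(diag(mm$counts)), rep(25L, 4))
  expect_true(all(mm$counts <= 25L))
  # two clusters separated by more than their diameters cannot overlap
  far <- dplyr::bind_rows(
    generate_group("a", n = 10, log10_mass_range = c(0, 1), intercept = 0, sd = 0.05),
    generate_group("b", n = 10, log10_mass_range = c(6, 7), intercept = -20, sd = 0.05)
  )
  mm_far <- hull_membership_matrix(far, "kC", "M")
  expect_equal(unname(mm_far$counts["a", "b"]), 0L)
  expect_equal(unname(mm_far$counts["b", "a"]), 0L)
  # membership matches the brute-force oracle group by group
  co <- mm$coords
  for (g in rownames(mm$counts)) {
    for (hgrp in colnames(mm$counts)) {
      sel <- co$group == g
      hul <- co$group == hgrp
      expect_equal(
        unname(mm$counts[g, hgrp]),
        sum(brute_force_membership(co$x[hul], co$y[hul], co$x[sel], co$y[sel]))
      )
    }
  }
})

test_that("adding a point to a group never decreases its hull's column counts", {
  set.seed(21)
  d <- default_scenario(n = 15)
  before <- hull_membership_matrix(d, "kC", "M")$counts
  extra <- generate_group("mammals",
    n = 3, log10_mass_range = c(2, 3),
    intercept = -1.3, sd = 0.8
  )
  after <- hull_membership_matrix(dplyr::bind_rows(d, extra), "kC", "M")$counts
  grps <- rownames(before)
  expect_true(all(after[grps, "mammals"] >= before[grps, "mammals"]))
})

test_that("residual parallelograms contain the hull and never lose members to it", {
  set.seed(6)
  d <- generate_group("g", n = 30, sd = 0.4)
  fit <- fit_loglog(d, "kC", "M")
  par <- residual_parallelogram(fit)
  h <- convex_hull(fit$data$x, fit$data$y)
  expect_true(all(point_in_parallelogram_test(par, h$vertices[, 1], h$vertices[, 2])))
  # all fitted points inside the parallelogram, and counts dominate hull counts
  expect_true(all(point_in_parallelogram_test(par, fit$data$x, fit$data$y)))
  other <- generate_group("h", n = 30, intercept = -1.8, sd = 0.4)
  of <- fit_loglog(other, "kC", "M")
  in_par <- sum(point_in_parallelogram_test(par, of$data$x, of$data$y))
  in_hull <- sum(point_in_hull(h, of$data$x, of$data$y))
  expect_gte(in_par, in_hull)
  # exact line collapses to a zero-height parallelogram
  exact <- exact_power_law_table(6)
  pf <- residual_parallelogram(fit_loglog(exact, "kC", "M"))
  expect_lt(diff(pf$intercept_range), 1e-10)
})

test_that("nearest-line classification is exhaustive and prefers the nearer line", {
  # a single group sends every point to its own line
  one <- generate_group("solo", n = 10, seed = 8)
  nl1 <- nearest_line_classification(one, "kC", "M")
  expect_equal(unname(nl1$counts["solo", "solo"]), 10L)
  # two flat groups at log-rate 0 and 10; a stray point at 2 goes to the lower
  mk_flat <- function(g, level, xs) {
    tibble::tibble(
      taxon = paste0(g, seq_along(xs)), group = g, M_g = 10^xs,
      kC_per_day = 10^level
    )
  }
  d <- dplyr::bind_rows(
    mk_flat("low", 0, c(0, 1, 2, 3)),
    mk_flat("high", 10, c(0, 1, 2, 3)),
    tibble::tibble(taxon = "stray", group = "high", M_g = 10^1.5, kC_per_day = 10^2)
  )
  nl <- nearest_line_classification(d, "kC", "M")
  stray <- nl$assignments[nl$assignments$taxon == "stray", ]
  expect_equal(stray$nearest, "low")
  # row sums equal group sizes (each point assigned exactly once)
  expect_equal(unname(rowSums(nl$counts)), c(4L, 5L))
  # identical groups tie everywhere; ties stay with the owner and are logged
  dup <- dplyr::bind_rows(
    mk_flat("a", 0, c(0, 1, 2)),
    mk_flat("b", 0, c(0, 1, 2))
  )
  nld <- nearest_line_classification(dup, "kC", "M")
  expect_equal(nrow(nld$ties), 6)
  expect_equal(unname(diag(nld$counts)), c(3L, 3L))
  # vertical distance mode runs and differs only in metric, not exhaustiveness
  nlv <- nearest_line_classification(d, "kC", "M", distance = "vertical")
  expect_equal(unname(rowSums(nlv$counts)), c(4L, 5L))
})

test_that("pooled endotherm/ectotherm overlap spans the disjoint and coincident extremes", {
  far <- dplyr::bind_rows(
    generate_group("a",
      n = 10, log10_mass_range = c(0, 1), intercept = 0,
      sd = 0.05, thermo = "endotherm"
    ),
    generate_group("b",
      n = 10, log10_mass_range = c(6, 7), intercept = -20,
      sd = 0.05, thermo = "ectotherm"
    )
  )
  po_far <- pooled_overlap(far, "kC", "M")
  expect_equal(po_far$overlap_fraction, 0)
  # identical point clouds under the two labels overlap (fraction ~ 1)
  base <- generate_group("x", n = 20, seed = 3, thermo = "endotherm")
  twin <- dplyr::mutate(base,
    thermo = "ectotherm",
    taxon = paste0(taxon, "_t")
  )
  po_same <- pooled_overlap(dplyr::bind_rows(base, twin), "kC", "M")
  expect_gt(po_same$overlap_fraction, 0.98)
  # the default scenario shows hull overlap while pooled regressions separate
  d <- default_scenario(n = 30, seed = 2)
  po <- pooled_overlap(d, "kC", "M")
  expect_gt(po$overlap_fraction, 0)
  ints <- purrr::map_dbl(po$fits, "intercept")
  expect_gt(ints[["endotherm"]], ints[["ectotherm"]])
  expect_error(pooled_overlap(dplyr::select(d, -thermo), "kC", "M"), "thermo")
})
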