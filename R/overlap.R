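# log10 coordinates used by the overlap machinery
loglog_coords <- function(data, dependent, independent) {
  ycol <- rate_column[[dependent]]
  xcol <- mass_column[[independent]]
  stopifnot(ycol %in% names(data), xcol %in% names(data))
  tibble::tibble(
    x = log10(as.numeric(data[[xcol]])),
    y = log10(as.numeric(data[[ycol]]))
  )
}

#' Convex hull of a planar point set
#'
#' Smallest enclosing convex polygon of points on the (log10 mass, log10
#' rate) plane, the region a group's species actually occupy — as opposed to
#' the narrow confidence band around the group's regression line. Vertices
#' are returned counter-clockwise. Sets with fewer than 3 distinct
#' non-collinear points are flagged `degenerate` and represented by their
#' extreme points (a segment or single point).
#'
#' @param x,y Numeric coordinate vectors (or `x` a data frame with columns
#'   `x` and `y`).
#' @param group Optional label stored on the result.
#' @return An object of class `hull_polygon`: list with `group`, `vertices`
#'   (matrix, columns `x`, `y`, counter-clockwise), `degenerate`, `n_points`.
#' @export
convex_hull <- function(x, y = NULL, group = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y), length(x) >= 1)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  pts <- cbind(x = x, y = y)
  uniq <- unique(pts)
  degenerate <- FALSE
  if (nrow(uniq) == 1) {
    verts <- uniq
    degenerate <- TRUE
  } else {
    idx <- grDevices::chull(pts[, 1], pts[, 2])
    verts <- pts[rev(idx), , drop = FALSE] # chull is clockwise; reverse to CCW
    if (nrow(verts) < 3 || polygon_area(verts) <= 0) {
      # collinear: keep the two extremes of the segment
      o <- order(pts[, 1], pts[, 2])
      verts <- pts[c(o[1], o[length(o)]), , drop = FALSE]
      degenerate <- TRUE
    }
  }
  structure(
    list(
      group = group, vertices = verts, degenerate = degenerate,
      n_points = length(x)
    ),
    class = "hull_polygon"
  )
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat(sprintf(
    "<hull_polygon>%s %d vertices from %d points%s\n",
    if (is.null(x$group)) "" else paste0(" ", x$group),
    nrow(x$vertices), x$n_points,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

# signed area of a CCW polygon (shoelace)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) {
    return(0)
  }
  i2 <- c(2:n, 1)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

# distance from point to segment ab
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax
  aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
  sqrt((ax + t * abx - px)^2 + (ay + t * aby - py)^2)
}

#' Point-in-hull test
#'
#' Tests whether points lie inside (or within `tol` of the boundary of) a
#' convex hull. Boundary points count as inside. Degenerate hulls (segment
#' or single point) use distance to the segment/point.
#'
#' @param hull A [convex_hull()] object.
#' @param x,y Numeric coordinate vectors (or `x` a data frame with `x`, `y`).
#' @param tol Boundary tolerance in coordinate (log10) units.
#' @return Logical vector.
#' @export
point_in_hull <- function(hull, x, y = NULL, tol = 1e-9) {
  stopifnot(inherits(hull, "hull_polygon"))
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  v <- hull$vertices
  n <- nrow(v)
  if (hull$degenerate) {
    if (n == 1) {
      return(sqrt((x - v[1, 1])^2 + (y - v[1, 2])^2) <= tol)
    }
    return(point_segment_distance(x, y, v[1, 1], v[1, 2], v[2, 1], v[2, 2]) <= tol)
  }
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # CCW orientation: interior has nonnegative cross product for every edge
    cross <- (v[j, 1] - v[i, 1]) * (y - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (x - v[i, 1])
    edge_len <- sqrt((v[j, 1] - v[i, 1])^2 + (v[j, 2] - v[i, 2])^2)
    inside <- inside & (cross >= -tol * max(edge_len, 1))
  }
  inside
}

#' Hull-membership overlap matrix
#'
#' For each pair of groups, counts how many of one group's points fall inside
#' the convex hull of the other, in (log10 mass, log10 rate) coordinates.
#' Substantial off-diagonal counts mean the groups' species-level ranges
#' overlap even when their regression lines separate cleanly. Rows index the
#' group the points belong to; columns index the group whose hull is tested;
#' the diagonal necessarily equals the group sizes.
#'
#' @param data A rate table with a `group` column.
#' @param dependent,independent Coordinate choice, as in [fit_loglog()]
#'   (`kC` vs `M` for compilations built on a common model, `kD` vs `BMatMG`
#'   for model-heterogeneous ones, `Gmax` vs `M` for the sheared view).
#' @param include_excluded Keep rows flagged `excluded` (default `FALSE`).
#' @param tol Boundary tolerance passed to [point_in_hull()].
#' @return A list of class `overlap_matrix`: `counts` (integer matrix),
#'   `hulls` (named list of [convex_hull()] objects), `coords` (the points
#'   used, with group labels).
#' @export
hull_membership_matrix <- function(data, dependent = c("kC", "kD", "Gmax"),
                                   independent = c("M", "BMatMG"),
                                   include_excluded = FALSE, tol = 1e-9) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  d <- tibble::as_tibble(data)
  stopifnot("group" %in% names(d))
  if (!include_excluded && "excluded" %in% names(d)) {
    d <- d[!isTRUE_vec(d$excluded), , drop = FALSE]
  }
  co <- loglog_coords(d, dependent, independent)
  co$group <- as.character(d$group)
  groups <- unique(co$group)
  hulls <- purrr::map(groups, function(g) {
    convex_hull(co$x[co$group == g], co$y[co$group == g], group = g)
  })
  names(hulls) <- groups
  counts <- matrix(0L,
    nrow = length(groups), ncol = length(groups),
    dimnames = list(points = groups, hull = groups)
  )
  for (g in groups) {
    sel <- co$group == g
    for (h in groups) {
      counts[g, h] <- sum(point_in_hull(hulls[[h]], co$x[sel], co$y[sel], tol = tol))
    }
  }
  structure(
    list(counts = counts, hulls = hulls, coords = co,
         dependent = dependent, independent = independent),
    class = "overlap_matrix"
  )
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf(
    "<overlap_matrix> points (rows) inside hulls (columns), log10(%s) vs log10(%s)\n",
    x$dependent, x$independent
  ))
  print(x$counts)
  invisible(x)
}

#' Residual parallelogram of a log-log fit
#'
#' The region bounded by the group's regression line shifted vertically to
#' pass through its most positive and most negative residuals, over the
#' group's mass range — an alternative, looser overlap region that always
#' contains the group's convex hull.
#'
#' @param fit A [fit_loglog()] object.
#' @return A list of class `residual_parallelogram`: `slope`,
#'   `intercept_range` (intercept + min/max residual), `x_range`, and
#'   `vertices` (4 x 2 matrix, counter-clockwise).
#' @export
residual_parallelogram <- function(fit) {
  stopifnot(inherits(fit, "loglog_fit"))
  r <- range(fit$residuals)
  xr <- range(fit$data$x)
  ic <- fit$intercept + r
  v <- rbind(
    c(xr[1], ic[1] + fit$slope * xr[1]),
    c(xr[2], ic[1] + fit$slope * xr[2]),
    c(xr[2], ic[2] + fit$slope * xr[2]),
    c(xr[1], ic[2] + fit$slope * xr[1])
  )
  colnames(v) <- c("x", "y")
  structure(
    list(
      slope = fit$slope, intercept_range = ic, x_range = xr, vertices = v
    ),
    class = "residual_parallelogram"
  )
}

# membership under a parallelogram: within x-range and between the two lines
point_in_parallelogram <- function(par, x, y, tol = 1e-9) {
  within_x <- x >= par$x_range[1] - tol & x <= par$x_range[2] + tol
  yhat_lo <- par$intercept_range[1] + par$slope * x
  yhat_hi <- par$intercept_range[2] + par$slope * x
  within_x & y >= yhat_lo - tol & y <= yhat_hi + tol
}

#' Nearest-regression-line classification
#'
#' Assigns every point to the group whose regression line lies nearest (the
#' most restrictive of the overlap criteria). Group regressions are fitted
#' internally with [fit_loglog()]; distance is perpendicular Euclidean
#' distance in the log-log plane by default, with vertical (residual)
#' distance as an option. Ties go to the point's own group when it is among
#' the tied groups, otherwise to the first tied group in group order; ties
#' are recorded.
#'
#' @inheritParams hull_membership_matrix
#' @param weighted Use per-taxon weights in the group fits.
#' @param distance `"perpendicular"` or `"vertical"`.
#' @return A list of class `nearest_line_classification`: `counts` (matrix,
#'   rows = point group, columns = nearest-line group), `assignments`
#'   (per-point tibble), `ties` (tibble of tied points), `fits`.
#' @export
nearest_line_classification <- function(data, dependent = c("kC", "kD", "Gmax"),
                                        independent = c("M", "BMatMG"),
                                        weighted = TRUE,
                                        include_excluded = FALSE,
                                        distance = c("perpendicular", "vertical"),
                                        tol = 1e-12) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  distance <- match.arg(distance)
  d <- tibble::as_tibble(data)
  stopifnot("group" %in% names(d))
  if (!include_excluded && "excluded" %in% names(d)) {
    d <- d[!isTRUE_vec(d$excluded), , drop = FALSE]
  }
  groups <- unique(as.character(d$group))
  fits <- purrr::map(groups, function(g) {
    fit_loglog(d[d$group == g, , drop = FALSE], dependent, independent,
      weighted = weighted
    )
  })
  names(fits) <- groups
  co <- loglog_coords(d, dependent, independent)
  co$group <- as.character(d$group)
  co$taxon <- if ("taxon" %in% names(d)) d$taxon else paste0("pt", seq_len(nrow(d)))
  dist_mat <- vapply(groups, function(g) {
    f <- fits[[g]]
    resid <- abs(co$y - (f$intercept + f$slope * co$x))
    if (distance == "perpendicular") resid / sqrt(1 + f$slope^2) else resid
  }, numeric(nrow(co)))
  dist_mat <- matrix(dist_mat, nrow = nrow(co), dimnames = list(NULL, groups))
  assigned <- character(nrow(co))
  tied <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    dmin <- min(dist_mat[i, ])
    cand <- groups[dist_mat[i, ] <= dmin + tol]
    tied[i] <- length(cand) > 1
    assigned[i] <- if (co$group[i] %in% cand) co$group[i] else cand[[1]]
  }
  counts <- table(
    factor(co$group, levels = groups),
    factor(assigned, levels = groups)
  )
  counts <- matrix(as.integer(counts),
    nrow = length(groups),
    dimnames = list(points = groups, nearest_line = groups)
  )
  assignments <- tibble::tibble(
    taxon = co$taxon, group = co$group, nearest = assigned,
    distance = dist_mat[cbind(seq_len(nrow(co)), match(assigned, groups))],
    tie = tied
  )
  structure(
    list(
      counts = counts, assignments = assignments,
      ties = assignments[assignments$tie, , drop = FALSE], fits = fits,
      distance = distance
    ),
    class = "nearest_line_classification"
  )
}

#' @export
print.nearest_line_classification <- function(x, ...) {
  cat(sprintf(
    "<nearest_line_classification> %s distance; %d ties\n",
    x$distance, nrow(x$ties)
  ))
  print(x$counts)
  invisible(x)
}

# grid-rasterized area of hull intersection and union over a joint bbox
hull_overlap_fraction <- function(hull_a, hull_b, resolution = 512) {
  va <- hull_a$vertices
  vb <- hull_b$vertices
  xr <- range(va[, 1], vb[, 1])
  yr <- range(va[, 2], vb[, 2])
  # pad degenerate extents so the grid is well defined
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  gx <- seq(xr[1], xr[2], length.out = resolution)
  gy <- seq(yr[1], yr[2], length.out = resolution)
  gridpts <- expand.grid(x = gx, y = gy)
  in_a <- point_in_hull(hull_a, gridpts$x, gridpts$y)
  in_b <- point_in_hull(hull_b, gridpts$x, gridpts$y)
  union <- sum(in_a | in_b)
  if (union == 0) {
    return(0)
  }
  sum(in_a & in_b) / union
}

#' Pooled endotherm/ectotherm overlap
#'
#' Pools all points by thermoregulation label into two groups and applies the
#' hull and prediction-band machinery to the pooled groups. The overlap
#' fraction is the grid-approximated area of the hull intersection divided by
#' the area of the hull union (0 for disjoint hulls, approaching 1 for
#' coincident ones).
#'
#' @inheritParams hull_membership_matrix
#' @param weighted Use per-taxon weights in the pooled fits.
#' @param resolution Rasterization grid resolution per axis.
#' @return A list of class `pooled_overlap`: `hulls`, `fits`, `bands`
#'   (prediction bands per pooled group), `overlap_fraction`, `counts`
#'   (pooled hull-membership matrix).
#' @export
pooled_overlap <- function(data, dependent = c("kC", "kD", "Gmax"),
                           independent = c("M", "BMatMG"), weighted = TRUE,
                           include_excluded = FALSE, resolution = 512) {
  dependent <- match.arg(dependent)
  independent <- match.arg(independent)
  d <- tibble::as_tibble(data)
  if (!"thermo" %in% names(d) || any(is.na(d$thermo))) {
    stop("pooled_overlap requires a complete 'thermo' column", call. = FALSE)
  }
  d$group <- as.character(d$thermo)
  mm <- hull_membership_matrix(d, dependent, independent,
    include_excluded = include_excluded
  )
  pools <- names(mm$hulls)
  fits <- purrr::map(pools, function(g) {
    fit_loglog(d[d$group == g, , drop = FALSE], dependent, independent,
      weighted = weighted
    )
  })
  names(fits) <- pools
  bands <- purrr::map(fits, prediction_band)
  ov <- if (length(pools) >= 2) {
    hull_overlap_fraction(mm$hulls[[1]], mm$hulls[[2]], resolution)
  } else {
    NA_real_
  }
  structure(
    list(
      hulls = mm$hulls, fits = fits, bands = bands,
      overlap_fraction = ov, counts = mm$counts
    ),
    class = "pooled_overlap"
  )
}

#' @export
print.pooled_overlap <- function(x, ...) {
  cat(sprintf(
    "<pooled_overlap> groups: %s; hull overlap fraction = %.3f\n",
    paste(names(x$hulls), collapse = ", "), x$overlap_fraction
  ))
  invisible(x)
}
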