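# Shape descriptors for digitized crystal outlines: roundness
# (4*area / (pi * major_axis^2) of the moment-equivalent ellipse) and
# solidity (area / convex-hull area), plus a descriptive two-group
# comparison. Outlines are simple polygons delineated on micrographs.

# Shoelace area (positive after orientation normalization) and the second
# central moments of the filled polygon.
polygon_moments <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  xi <- x; yi <- y
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  cross <- xi * yj - xj * yi
  a <- sum(cross) / 2
  if (a < 0) {                       # normalize to counter-clockwise
    return(polygon_moments(rev(x), rev(y)))
  }
  if (a == 0) stop("degenerate (zero-area) polygon", call. = FALSE)
  cx <- sum((xi + xj) * cross) / (6 * a)
  cy <- sum((yi + yj) * cross) / (6 * a)
  ixx <- sum(cross * (yi^2 + yi * yj + yj^2)) / 12
  iyy <- sum(cross * (xi^2 + xi * xj + xj^2)) / 12
  ixy <- sum(cross * (xi * yj + 2 * xi * yi + 2 * xj * yj + xj * yi)) / 24
  # central second moments per unit area (covariance of the filled shape)
  list(area = a,
       cov = matrix(c(iyy / a - cx^2, ixy / a - cx * cy,
                      ixy / a - cx * cy, ixx / a - cy^2), 2L))
}

#' Roundness of a polygon outline
#'
#' `4 * area / (pi * major_axis^2)`, where the major axis is that of the
#' ellipse sharing the polygon's second central moments (the fitted
#' ellipse). Equals 1 for a circle and b/a for an ellipse with semi-axes
#' a >= b.
#'
#' @param x,y Vertex coordinates of a simple polygon (any consistent unit).
#' @return Roundness in (0, 1].
#' @export
roundness <- function(x, y) {
  m <- polygon_moments(x, y)
  lambda1 <- max(eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values)
  major <- 4 * sqrt(lambda1)         # full major-axis length of the ellipse
  4 * m$area / (pi * major^2)
}

#' Solidity of a polygon outline
#'
#' Polygon area divided by the area of its convex hull; 1 iff the polygon
#' is convex.
#'
#' @inheritParams roundness
#' @return Solidity in (0, 1].
#' @export
solidity <- function(x, y) {
  m <- polygon_moments(x, y)
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  hull_area <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  m$area / hull_area
}

#' Shape metrics for a table of outlines
#'
#' @param outlines Tibble with columns `shape_id`, `x`, `y` (vertices in
#'   order within each shape), e.g. from [read_outlines()].
#' @return Tibble with one row per shape: `shape_id`, `area`, `roundness`,
#'   `solidity`.
#' @export
shape_metrics <- function(outlines) {
  outlines %>%
    group_by(.data$shape_id) %>%
    summarise(area = polygon_moments(.data$x, .data$y)$area,
              roundness = roundness(.data$x, .data$y),
              solidity = solidity(.data$x, .data$y),
              .groups = "drop")
}

#' Read outlines from CSV
#'
#' @param path CSV with columns `shape_id`, `vertex_index`, `x`, `y`.
#' @return Tibble sorted by shape and vertex order.
#' @export
read_outlines <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    arrange(.data$shape_id, .data$vertex_index)
}

#' Compare shape metrics between two groups
#'
#' Descriptive two-sample comparison: per-group medians plus a rank-based
#' (Hodges-Lehmann) shift estimate and Wilcoxon rank-sum statistic. The
#' shift is the location of `values_b` relative to `values_a`.
#'
#' @param values_a,values_b Non-empty numeric samples (e.g. wild-type and
#'   mutant roundness values).
#' @param metric Optional label carried through to [generics::tidy()].
#' @return An object of class `shape_comparison`.
#' @export
compare_shape_groups <- function(values_a, values_b, metric = "metric") {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(
    wilcox.test(values_b, values_a, conf.int = TRUE, exact = FALSE))
  # Hodges-Lehmann shift: median of all pairwise differences b_j - a_i
  hl <- median(outer(values_b, values_a, "-"))
  structure(
    list(metric = metric,
         values_a = values_a, values_b = values_b,
         n_a = length(values_a), n_b = length(values_b),
         median_a = median(values_a), median_b = median(values_b),
         shift = hl,
         conf_low = wt$conf.int[1], conf_high = wt$conf.int[2],
         statistic = unname(wt$statistic), p_value = wt$p.value),
    class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat("<shape_comparison>", x$metric, "\n")
  cat(sprintf("  group A: n = %d, median = %.4f\n", x$n_a, x$median_a))
  cat(sprintf("  group B: n = %d, median = %.4f\n", x$n_b, x$median_b))
  cat(sprintf("  rank-based shift (B - A): %.4f [%.4f, %.4f]\n",
              x$shift, x$conf_low, x$conf_high))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shape_comparison <- function(x, ...) {
  tibble(metric = x$metric, group = c("a", "b"), n = c(x$n_a, x$n_b),
         median = c(x$median_a, x$median_b))
}

#' @export
glance.shape_comparison <- function(x, ...) {
  tibble(metric = x$metric, shift = x$shift, conf_low = x$conf_low,
         conf_high = x$conf_high, statistic = x$statistic,
         p_value = x$p_value)
}

#' Simulate crystal outline fixtures
#'
#' Generates polygon outlines emulating the two morphologies seen in
#' iridophore crystals: `"parallelepiped"` (elongated, convex, wild-type
#' analog) and `"irregular"` (rounder, ragged-contour, mutant analog).
#'
#' @param n Number of shapes.
#' @param type `"parallelepiped"` or `"irregular"`.
#' @param seed Integer seed.
#' @return Outline tibble (`shape_id`, `vertex_index`, `x`, `y`).
#' @export
simulate_crystal_outlines <- function(n = 30L,
                                      type = c("parallelepiped", "irregular"),
                                      seed = 1L) {
  type <- match.arg(type)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      theta <- runif(1, 0, pi)
      if (type == "parallelepiped") {
        len <- runif(1, 2, 4); wid <- len * runif(1, 0.2, 0.4)
        shear <- runif(1, -0.3, 0.3)
        px <- c(0, len, len + shear, shear) - len / 2
        py <- c(0, 0, wid, wid) - wid / 2
      } else {
        k <- 14L
        ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
        r <- runif(1, 0.8, 1.6) * (1 + runif(k, -0.35, 0.35))
        px <- r * cos(ang); py <- 0.8 * r * sin(ang)
      }
      rx <- px * cos(theta) - py * sin(theta)
      ry <- px * sin(theta) + py * cos(theta)
      tibble(shape_id = paste0(type, "_", i),
             vertex_index = seq_along(rx),
             x = rx + runif(1, -5, 5), y = ry + runif(1, -5, 5))
    })
  })
}
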