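# Exact 2-D geometry of the Thales construction: the inscribed angle beta at an
# observed intake point, the circle whose diameter joins the origin and the
# intake target, perpendicular-foot projections onto nutritional rails, and
# inside/on/outside classification.

## Coerce points to an n x 2 matrix. Accepts a length-2 numeric, an n x 2
## matrix, or a data frame carrying nutrient_a/nutrient_b columns.
as_point_matrix <- function(x, arg = "point") {
  if (is.data.frame(x)) {
    if (all(c("nutrient_a", "nutrient_b") %in% names(x))) {
      x <- cbind(x$nutrient_a, x$nutrient_b)
    } else {
      x <- as.matrix(x[, 1:2])
    }
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 2L) {
      nutri_stop(sprintf("`%s` must have two coordinates, got %d.", arg, length(x)))
    }
    x <- matrix(x, ncol = 2L)
  } else {
    x <- as.matrix(x)
  }
  if (ncol(x) != 2L) {
    nutri_stop(sprintf("`%s` must be a 2-column point matrix.", arg))
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    nutri_stop(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  x
}

validate_target <- function(target) {
  target <- as_point_matrix(target, "target")
  if (nrow(target) != 1L) {
    nutri_stop("`target` must be a single coordinate pair.")
  }
  target <- drop(target)
  if (sqrt(sum(target^2)) <= 0) {
    nutri_stop("invalid intake target: zero norm.")
  }
  target
}

#' Thales angle at an observed intake point
#'
#' Computes the inscribed angle \eqn{\beta} at the observed intake point `B`
#' of the triangle formed by the origin `A = (0, 0)`, the point `B`, and the
#' intake target `C`. By Thales' theorem \eqn{\beta = 90} degrees exactly when
#' `B` lies on the circle whose diameter is the segment from the origin to the
#' target -- the configuration predicted by the closest-distance-optimisation
#' (CDO) rule of compromise. Angles above 90 place the point inside that
#' circle (under-consumption), below 90 outside it (tolerated surplus).
#'
#' The angle is computed from the normalised dot product of the directions
#' `B -> A` and `B -> C`, with the cosine clamped to `[-1, 1]` to guard
#' against floating-point overshoot. A point collinear with and strictly
#' between origin and target returns 180 degrees (limit case); a point on the
#' ray beyond the target returns 0.
#'
#' @param point Intake coordinates: a length-2 numeric `(nutrient_a,
#'   nutrient_b)`, an `n x 2` matrix, or a data frame with `nutrient_a` and
#'   `nutrient_b` columns.
#' @param target Intake target coordinate (length-2 positive numeric).
#' @param tol Relative tolerance used to flag points coinciding with the
#'   origin or the target (degenerate triangle vertices).
#'
#' @return Numeric vector of angles in degrees, one per point, in `[0, 180]`.
#' @examples
#' thales_angle(c(1, 1), target = c(0, 2)) # on the circle: 90
#' thales_angle(c(1, 1), target = c(4, 0)) # inside: 116.565
#' @seealso [beta_deviation()], [circle_position()], [cdo_projection()]
#' @export
thales_angle <- function(point, target, tol = 1e-12) {
  target <- validate_target(target)
  p <- as_point_matrix(point)
  scale <- max(1, sqrt(sum(target^2)))

  d_origin <- sqrt(rowSums(p^2))
  d_target <- sqrt(rowSums(sweep(p, 2L, target)^2))
  bad <- d_origin <= tol * scale | d_target <= tol * scale
  if (any(bad)) {
    nutri_stop_numeric(sprintf(
      "degenerate vertex: point(s) %s coincide with the origin or the intake target.",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }

  # u = B -> A, v = B -> C. The angle is the arccos of the normalised dot
  # product; it is evaluated as atan2(|u x v|, u . v), which is algebraically
  # identical but numerically stable near 0 and 180 degrees, where arccos of
  # a clamped cosine loses up to ~1e-8 degrees.
  u <- -p
  v <- sweep(-p, 2L, target, "+")
  cross <- abs(u[, 1] * v[, 2] - u[, 2] * v[, 1])
  dot <- rowSums(u * v)
  atan2(cross, dot) * 180 / pi
}

#' Deviation of the Thales angle from the CDO prediction
#'
#' Returns [thales_angle()] minus 90 degrees. Positive deviations mean the
#' intake point lies inside the Thales circle (under-consumption relative to
#' the perpendicular CDO foot); negative deviations mean it lies outside
#' (the nutrient surplus is tolerated). Rails whose confidence interval for
#' this deviation covers zero are consistent with CDO.
#'
#' @inheritParams thales_angle
#' @return Numeric vector of deviations in degrees.
#' @examples
#' beta_deviation(c(1, 1), target = c(0, 2)) # 0: on the circle
#' beta_deviation(c(1, 1), target = c(4, 0)) # +26.565: inside
#' @export
beta_deviation <- function(point, target, tol = 1e-12) {
  thales_angle(point, target, tol = tol) - 90
}

#' Thales circle of an intake target
#'
#' The circle whose diameter is the segment from the origin to the intake
#' target. Under the CDO rule of compromise every rail's intake falls on this
#' circle (on the arc in the positive quadrant).
#'
#' @inheritParams thales_angle
#' @return An object of class `thales_circle`: a list with `center`
#'   (`target / 2`) and `radius` (`|target| / 2`).
#' @examples
#' thales_circle(c(10, 40))
#' @export
thales_circle <- function(target) {
  target <- validate_target(target)
  structure(
    list(center = target / 2, radius = sqrt(sum(target^2)) / 2),
    class = "thales_circle"
  )
}

#' @export
print.thales_circle <- function(x, ...) {
  cat(sprintf(
    "Thales circle: center (%.4g, %.4g), radius %.4g\n",
    x$center[1], x$center[2], x$radius
  ))
  invisible(x)
}

#' Classify intake points relative to the Thales circle
#'
#' Classifies each point as `inside`, `on`, or `outside` the circle whose
#' diameter joins the origin and the intake target, using the sign of the
#' angle deviation against a tolerance. By Thales' theorem this agrees with
#' the metric criterion (distance to the circle center versus radius).
#'
#' @inheritParams thales_angle
#' @param tol_deg Angular tolerance in degrees for the `on` classification.
#'   The exact-geometry default (`1e-8`) suits constructed data; raise it to
#'   describe noisy intake data.
#' @return Factor with levels `inside`, `on`, `outside`.
#' @examples
#' circle_position(rbind(c(1, 1), c(0.5, 1), c(2, 1)), target = c(0, 2))
#' @export
circle_position <- function(point, target, tol_deg = 1e-8) {
  dev <- beta_deviation(point, target)
  out <- ifelse(dev > tol_deg, "inside", ifelse(dev < -tol_deg, "outside", "on"))
  factor(out, levels = c("inside", "on", "outside"))
}

#' Parse a nutritional-rail ratio label
#'
#' A nutritional rail is the ray from the origin whose direction is a diet's
#' fixed nutrient ratio, written `"a:b"` (e.g. `"1:4"` for P:C 1:4). Labels
#' that differ only by a common factor (`"7:35"`, `"1:5"`) describe the same
#' rail direction.
#'
#' @param label Ratio label of the form `"a:b"` with non-negative numbers,
#'   not both zero.
#' @return An object of class `rail`: list with `ratio_a`, `ratio_b`,
#'   `label`, and the unit `direction` vector.
#' @examples
#' parse_rail("1:4")
#' parse_rail("7:35")$direction # same direction as "1:5"
#' @export
parse_rail <- function(label) {
  if (inherits(label, "rail")) {
    return(label)
  }
  if (!is.character(label) || length(label) != 1L) {
    nutri_stop("rail label must be a single character string like \"1:4\".")
  }
  m <- regmatches(
    label,
    regexec("^\\s*([0-9]*\\.?[0-9]+)\\s*:\\s*([0-9]*\\.?[0-9]+)\\s*$", label)
  )[[1]]
  if (length(m) != 3L) {
    nutri_stop(sprintf("malformed rail label '%s': expected \"a:b\".", label))
  }
  a <- as.numeric(m[2])
  b <- as.numeric(m[3])
  if (a + b <= 0) {
    nutri_stop(sprintf("rail '%s' has zero direction (0:0 is not a rail).", label))
  }
  structure(
    list(
      ratio_a = a, ratio_b = b, label = trimws(label),
      direction = c(a, b) / sqrt(a^2 + b^2)
    ),
    class = "rail"
  )
}

#' @export
print.rail <- function(x, ...) {
  cat(sprintf(
    "rail %s: direction (%.4f, %.4f)\n",
    x$label, x$direction[1], x$direction[2]
  ))
  invisible(x)
}

#' Perpendicular (CDO) foot of the intake target on a rail
#'
#' Orthogonally projects the intake target onto the ray from the origin along
#' the rail direction. Under the closest-distance-optimisation rule the
#' intake on each rail falls at this foot, where the segment to the target
#' meets the rail at 90 degrees; consequently `thales_angle(foot, target)`
#' is 90 whenever the foot is distinct from both origin and target.
#'
#' @param rail A [parse_rail()] object or a ratio label such as `"1:4"`.
#' @inheritParams thales_angle
#' @return Named numeric `(nutrient_a, nutrient_b)`: the foot on the rail ray.
#' @examples
#' cdo_projection("1:1", target = c(10, 40)) # (25, 25)
#' cdo_projection("1:4", target = c(10, 40)) # the target itself
#' @export
cdo_projection <- function(rail, target) {
  rail <- parse_rail(rail)
  target <- validate_target(target)
  u <- rail$direction
  t_foot <- sum(target * u) # >= 0: target and rail both in the positive quadrant
  setNames(t_foot * u, c("nutrient_a", "nutrient_b"))
}

## Key used to order rail labels by increasing nutrient_a : nutrient_b ratio
## (0:1 first, 1:0 last), matching the customary table layout.
rail_sort_key <- function(labels) {
  vapply(labels, function(l) {
    r <- parse_rail(l)
    atan2(r$ratio_a, r$ratio_b)
  }, numeric(1))
}

## Reorder a rail factor by ratio.
rail_factor <- function(labels) {
  lev <- unique(labels)
  factor(labels, levels = lev[order(rail_sort_key(lev))])
}
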