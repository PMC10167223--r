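# Synthetic nutrient-array generators (archetypal rules of compromise) and
# the noise-stability simulation for the Thales-angle estimator.

#' Noise model for synthetic intake arrays
#'
#' Additive per-coordinate error drawn from one of three families. The
#' `scale` parameter is the family's natural dispersion parameter: `sd` for
#' Gaussian, `lambda` for Poisson, `shape` (rate 1) for gamma. Gaussian draws
#' have mean zero; Poisson and gamma draws have mean `scale`, so by default
#' they both disperse and translate the array -- exactly how raw `rpois()` /
#' `rgamma()` errors behave. With `centered = TRUE` the theoretical mean is
#' subtracted so increasing `scale` increases dispersion without translation.
#'
#' @param family `"gaussian"`, `"poisson"`, or `"gamma"`.
#' @param scale Positive dispersion parameter (sd / lambda / shape).
#' @param centered Subtract the distribution's theoretical mean.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(family = c("gaussian", "poisson", "gamma"),
                        scale = 1, centered = FALSE) {
  family <- match.arg(family)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    nutri_stop("noise `scale` must be a single positive finite number.")
  }
  structure(
    list(family = family, scale = scale, centered = isTRUE(centered)),
    class = "noise_model"
  )
}

draw_noise <- function(model, n) {
  s <- model$scale
  switch(model$family,
    gaussian = rnorm(n, mean = 0, sd = s),
    poisson = rpois(n, lambda = s) - if (model$centered) s else 0,
    gamma = rgamma(n, shape = s, rate = 1) - if (model$centered) s else 0
  )
}

## Resolve a rails argument (character labels or rail objects) to a list of
## parsed rails.
resolve_rails <- function(rails) {
  if (inherits(rails, "rail")) {
    rails <- list(rails)
  }
  rails <- lapply(rails, parse_rail)
  if (length(rails) == 0L) {
    nutri_stop("at least one rail is required.")
  }
  rails
}

## Assemble generator output as an intake_dataset without re-validating
## non-negativity (additive noise may dip below zero; documented as synthetic).
build_synthetic_dataset <- function(species, rail_labels, a, b) {
  out <- tibble::tibble(
    species = species,
    group = NA_character_,
    treatment = "rail",
    rail = rail_labels,
    nutrient_a = a,
    nutrient_b = b
  )
  structure(
    out,
    load_report = dplyr::count(out, .data$species, .data$treatment, .data$rail,
      name = "n_records"
    ),
    class = c("intake_dataset", class(tibble::tibble()))
  )
}

#' Generate a synthetic CDO nutrient array
#'
#' Places `n_per_rail` points at the perpendicular (CDO) foot of the intake
#' target on each rail and adds per-coordinate noise. With vanishing noise
#' every generated point satisfies \eqn{\beta = 90} degrees exactly.
#'
#' @param target Intake target `(nutrient_a, nutrient_b)`.
#' @param rails Character vector of ratio labels (or [parse_rail()] objects).
#' @param n_per_rail Number of points per rail.
#' @param noise A [noise_model()], or `NULL` for noiseless feet.
#' @param seed Optional integer seed for reproducibility.
#' @param species Species label attached to the records.
#' @return An `intake_dataset` of `length(rails) * n_per_rail` rail records,
#'   with the generating `target` as an attribute.
#' @export
generate_cdo_array <- function(target, rails, n_per_rail = 1, noise = NULL,
                               seed = NULL, species = "cdo") {
  generate_archetype_array("cdo", target, rails,
    n_per_rail = n_per_rail,
    noise = noise, seed = seed, species = species
  )
}

#' Generate an archetypal nutrient array
#'
#' Synthetic fixtures for the classic nutrient-array shapes used to
#' fingerprint rules of compromise:
#'
#' * `cdo` -- points at the perpendicular foot of the target on each rail
#'   (the closest-distance-optimisation array; all angles 90 degrees).
#' * `equal_distance` -- points at a common Euclidean distance from the
#'   origin (`distance`, default `|target|`, i.e. the arc through the
#'   target). On the target's own rail the point is the target itself; at
#'   more imbalanced rails the points fall progressively further outside the
#'   Thales circle, giving the parabola-shaped angle profile of a
#'   surplus-tolerant generalist. `from = "target"` instead intersects each
#'   rail with the circle of radius `distance` centred on the target
#'   (`branch` selects the intersection beyond or before the foot); rails
#'   whose foot lies further than `distance` from the target have no
#'   intersection and raise an error.
#' * `square` -- nutrient A held at the target's A-coordinate.
#' * `inverted_square` -- nutrient B held at the target's B-coordinate.
#' * `linear` -- total intake `a + b` held at the target's total.
#' * `concave` -- interpolates between the square and inverted-square points
#'   along each rail and shrinks the array toward the origin, maximally at
#'   the rails most distant in angle from the target (under-consumption of
#'   strongly imbalanced diets).
#'
#' @param kind Archetype name (see above).
#' @inheritParams generate_cdo_array
#' @param distance Radius for `equal_distance` (from the origin by default).
#' @param from For `equal_distance`: measure the common distance from the
#'   `"origin"` (default) or from the `"target"`.
#' @param branch For `from = "target"`: `"outer"` (beyond the CDO foot) or
#'   `"inner"` intersection.
#' @param shrink For `concave`: maximal proportional shrinkage toward the
#'   origin at the most imbalanced rail, in `[0, 1)`.
#' @return An `intake_dataset` with attribute `target`.
#' @export
generate_archetype_array <- function(kind = c(
                                       "cdo", "equal_distance", "square",
                                       "inverted_square", "linear", "concave"
                                     ),
                                     target, rails, n_per_rail = 1,
                                     noise = NULL, seed = NULL, species = kind,
                                     distance = NULL,
                                     from = c("origin", "target"),
                                     branch = c("outer", "inner"),
                                     shrink = 0.5) {
  kind <- match.arg(kind)
  from <- match.arg(from)
  branch <- match.arg(branch)
  species <- species[[1]]
  target <- validate_target(target)
  rails <- resolve_rails(rails)
  if (!is.numeric(n_per_rail) || n_per_rail < 1) {
    nutri_stop("`n_per_rail` must be >= 1.")
  }
  n_per_rail <- as.integer(n_per_rail)
  if (!is.null(noise) && !inherits(noise, "noise_model")) {
    nutri_stop("`noise` must be a noise_model() or NULL.")
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }

  base_point <- function(rail) {
    u <- rail$direction
    switch(kind,
      cdo = sum(target * u) * u,
      equal_distance = {
        if (from == "origin") {
          L <- distance %||% sqrt(sum(target^2))
          L * u
        } else {
          r <- distance %||% max(vapply(rails, function(rr) {
            ft <- sum(target * rr$direction) * rr$direction
            sqrt(sum((ft - target)^2))
          }, numeric(1)))
          t_foot <- sum(target * u)
          d <- sqrt(sum((t_foot * u - target)^2))
          if (d > r) {
            nutri_stop_numeric(sprintf(
              "rail %s does not intersect the circle of radius %.4g around the target (foot distance %.4g).",
              rail$label, r, d
            ))
          }
          s <- sqrt(r^2 - d^2)
          tt <- if (branch == "outer") t_foot + s else t_foot - s
          if (tt < 0) {
            nutri_stop_numeric(sprintf(
              "inner intersection for rail %s lies behind the origin.", rail$label
            ))
          }
          tt * u
        }
      },
      square = {
        if (rail$ratio_a <= 0) {
          nutri_stop_numeric(sprintf(
            "square array undefined for rail %s: nutrient A is always zero on it.",
            rail$label
          ))
        }
        (target[1] / u[1]) * u
      },
      inverted_square = {
        if (rail$ratio_b <= 0) {
          nutri_stop_numeric(sprintf(
            "inverted-square array undefined for rail %s: nutrient B is always zero on it.",
            rail$label
          ))
        }
        (target[2] / u[2]) * u
      },
      linear = (sum(target) / sum(u)) * u,
      concave = {
        theta <- atan2(u[2], u[1]) # 0 = pure nutrient A, pi/2 = pure B
        w <- theta / (pi / 2)
        t_sq <- if (u[1] > 0) target[1] / u[1] else NA_real_
        t_inv <- if (u[2] > 0) target[2] / u[2] else NA_real_
        tt <- if (is.na(t_sq)) {
          t_inv
        } else if (is.na(t_inv)) {
          t_sq
        } else {
          (1 - w) * t_sq + w * t_inv
        }
        theta_t <- atan2(target[2], target[1])
        dmax <- max(vapply(rails, function(rr) {
          abs(atan2(rr$direction[2], rr$direction[1]) - theta_t)
        }, numeric(1)))
        g <- if (dmax > 0) abs(theta - theta_t) / dmax else 0
        tt * (1 - shrink * g) * u
      }
    )
  }

  feet <- lapply(rails, base_point)
  labels <- vapply(rails, function(r) r$label, character(1))
  a <- rep(vapply(feet, `[`, numeric(1), 1L), each = n_per_rail)
  b <- rep(vapply(feet, `[`, numeric(1), 2L), each = n_per_rail)
  if (!is.null(noise)) {
    a <- a + draw_noise(noise, length(a))
    b <- b + draw_noise(noise, length(b))
  }
  out <- build_synthetic_dataset(
    species, rep(labels, each = n_per_rail), a, b
  )
  attr(out, "target") <- setNames(target, c("nutrient_a", "nutrient_b"))
  out
}

#' Noise-stability simulation of the Thales-angle estimator
#'
#' Characterises how the estimated angle of a known-90-degree (CDO) array
#' behaves as additive error grows, for Gaussian, Poisson and gamma error
#' families. For each (family, scale) cell, `reps` synthetic arrays of `n`
#' points (cycled across the rails, noise per coordinate) are generated, the
#' mean angle of each array is estimated, and the mean and the 2.5/97.5
#' percentile band of those estimates are recorded. `noise_proportion` is
#' `scale / |target|`, the error magnitude relative to the intake target.
#'
#' A single root `seed` spawns an independent, fixed substream per
#' (family, scale) cell, so any grid row is reproducible in isolation.
#'
#' @param families Subset of `c("gaussian", "poisson", "gamma")`.
#' @param scale_grid Increasing vector of positive dispersion parameters.
#' @param n Points per simulated array.
#' @param reps Simulated arrays per grid cell.
#' @param target Intake target of the generating CDO array.
#' @param rails Rails of the generating CDO array.
#' @param seed Optional integer root seed.
#' @param centered Use mean-centred noise (see [noise_model()]).
#' @return Tibble of class `stability_simulation`, one row per
#'   (family, scale): `family`, `scale`, `noise_proportion`, `mean_beta`,
#'   `lwr95`, `upr95`, `n`, `reps`. Attributes: `seed`, `target`.
#' @export
noise_stability_simulation <- function(families = c("gaussian", "poisson", "gamma"),
                                       scale_grid = seq(0.01, 100, by = 0.5),
                                       n = 100, reps = 100,
                                       target = c(100, 100),
                                       rails = c("1:5", "1:2", "2:1", "5:1"),
                                       seed = NULL, centered = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  if (length(scale_grid) == 0L || any(!is.finite(scale_grid)) ||
    any(scale_grid <= 0) || is.unsorted(scale_grid, strictly = TRUE)) {
    nutri_stop("`scale_grid` must be a strictly increasing vector of positive values.")
  }
  if (reps < 1) {
    nutri_stop("`reps` must be >= 1.")
  }
  target <- validate_target(target)
  rails <- resolve_rails(rails)
  feet <- t(vapply(rails, function(r) sum(target * r$direction) * r$direction,
    numeric(2)
  ))
  tnorm <- sqrt(sum(target^2))
  scale_ref <- max(1, tnorm)

  rows <- vector("list", length(families) * length(scale_grid))
  k <- 0L
  for (fi in seq_along(families)) {
    for (si in seq_along(scale_grid)) {
      if (!is.null(seed)) {
        ## independent, reproducible substream per grid cell
        set.seed((as.integer(seed) + 1000003L * (fi - 1L) + 101L * (si - 1L)) %%
          2147483647L)
      }
      model <- noise_model(families[fi], scale_grid[si], centered = centered)
      idx <- rep_len(seq_len(nrow(feet)), n)
      ests <- vapply(seq_len(reps), function(r) {
        pa <- feet[idx, 1] + draw_noise(model, n)
        pb <- feet[idx, 2] + draw_noise(model, n)
        ok <- (pa^2 + pb^2) > (1e-9 * scale_ref)^2 &
          ((pa - target[1])^2 + (pb - target[2])^2) > (1e-9 * scale_ref)^2
        mean(thales_angle(cbind(pa[ok], pb[ok]), target))
      }, numeric(1))
      q <- quantile(ests, c(0.025, 0.975), names = FALSE)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        family = families[fi], scale = scale_grid[si],
        noise_proportion = scale_grid[si] / tnorm,
        mean_beta = mean(ests), lwr95 = q[1], upr95 = q[2],
        n = as.integer(n), reps = as.integer(reps)
      )
    }
  }
  structure(
    dplyr::bind_rows(rows),
    seed = seed, target = setNames(target, c("nutrient_a", "nutrient_b")),
    class = c("stability_simulation", class(tibble::tibble()))
  )
}
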