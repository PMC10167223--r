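# Independent oracles and fixture builders shared across the suite.

# Law-of-cosines oracle for the angle at B of triangle A=(0,0), B, C: computed
# purely from the three side lengths, independent of the dot-product route.
# The sine of the angle comes from Kahan's numerically stable Heron area so
# the oracle keeps full precision near collinear configurations; vectorised
# over rows of `point`.
law_of_cosines_angle <- function(point, target) {
  p <- if (is.null(dim(point))) matrix(point, ncol = 2) else point
  ab <- sqrt(p[, 1]^2 + p[, 2]^2)
  bc <- sqrt((target[1] - p[, 1])^2 + (target[2] - p[, 2])^2)
  ac <- sqrt(sum(target^2))
  cosb <- (ab^2 + bc^2 - ac^2) / (2 * ab * bc)
  # stable Heron: sort sides descending as x >= y >= z
  x <- pmax(ab, bc, ac)
  z <- pmin(ab, bc, ac)
  y <- ab + bc + ac - x - z
  area4 <- sqrt(pmax(0, (x + (y + z)) * (z - (x - y)) * (z + (x - y)) * (x + (y - z))))
  sinb <- area4 / (2 * ab * bc)
  atan2(sinb, cosb) * 180 / pi
}

# Random non-degenerate (point, target) pairs in the positive quadrant.
random_triangles <- function(n, seed = 1) {
  set.seed(seed)
  list(
    px = runif(n, 0.05, 200), py = runif(n, 0.05, 200),
    tx = runif(n, 0.5, 200), ty = runif(n, 0.5, 200)
  )
}

# A point on the Thales circle of `target` at polar angle `theta` from the
# circle center (constructed metrically, independent of any angle code).
on_circle_point <- function(target, theta) {
  target / 2 + sqrt(sum(target^2)) / 2 * c(cos(theta), sin(theta))
}

# Minimal intake data frame in the default CSV layout.
make_intake_df <- function(species, treatment, rail, protein, carbohydrate) {
  data.frame(
    species = species, treatment = treatment, rail = rail,
    protein = protein, carbohydrate = carbohydrate,
    stringsAsFactors = FALSE
  )
}

# Angle-records-shaped tibble for driving the inference functions directly
# with known deviations.
make_records <- function(species, rail, deviation) {
  tibble::tibble(
    species = species, group = NA_character_, rail = rail,
    nutrient_a = NA_real_, nutrient_b = NA_real_,
    beta_deg = 90 + deviation, deviation_deg = deviation,
    position = factor(
      ifelse(deviation > 0, "inside", ifelse(deviation < 0, "outside", "on")),
      levels = c("inside", "on", "outside")
    )
  )
}
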