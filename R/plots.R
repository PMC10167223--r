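# Nutrient-space and angle-summary figures.

circle_path <- function(target, n = 200) {
  circ <- thales_circle(target)
  th <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(
    nutrient_a = circ$center[1] + circ$radius * cos(th),
    nutrient_b = circ$center[2] + circ$radius * sin(th)
  )
}

#' Nutrient-space panel: array, rails, target and Thales circle
#'
#' Plots the individual intake points and per-rail mean intakes of each
#' species in nutrient space, with the nutritional rails as rays from the
#' origin, the intake target, and (in red) the Thales circle whose diameter
#' joins the origin and the target. Intakes falling on that circle are
#' consistent with the closest-distance-optimisation rule.
#'
#' @param records An [angle_records()] tibble (carries the per-species
#'   targets), or an [intake_dataset()] together with an explicit `target`.
#' @param target Explicit intake target, required when `records` is a plain
#'   dataset without choice rows.
#' @return A `ggplot` object; the data behind it are in
#'   `attr(, "plot_data")`.
#' @export
plot_nutrient_array <- function(records, target = NULL) {
  if (!inherits(records, "angle_records")) {
    records <- angle_records(records, target = target)
  }
  targets <- attr(records, "targets")
  tg_df <- dplyr::bind_rows(lapply(names(targets), function(sp) {
    tibble::tibble(
      species = sp,
      nutrient_a = targets[[sp]][1], nutrient_b = targets[[sp]][2]
    )
  }))
  circ_df <- dplyr::bind_rows(lapply(names(targets), function(sp) {
    dplyr::mutate(circle_path(targets[[sp]]), species = sp)
  }))
  means <- dplyr::summarise(
    dplyr::group_by(records, .data$species, .data$rail),
    nutrient_a = mean(.data$nutrient_a),
    nutrient_b = mean(.data$nutrient_b),
    .groups = "drop"
  )
  lim <- 1.05 * max(records$nutrient_a, records$nutrient_b,
    circ_df$nutrient_a, circ_df$nutrient_b, 0
  )
  rails_df <- dplyr::bind_rows(lapply(unique(records$rail), function(l) {
    u <- parse_rail(l)$direction
    t_end <- lim / max(u)
    tibble::tibble(rail = l, xend = t_end * u[1], yend = t_end * u[2])
  }))

  p <- ggplot2::ggplot(records, ggplot2::aes(.data$nutrient_a, .data$nutrient_b)) +
    ggplot2::geom_segment(
      data = rails_df,
      ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = circ_df, colour = "red", linewidth = 0.4
    ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = means, shape = 21, fill = "white", size = 2.2) +
    ggplot2::geom_point(
      data = tg_df, colour = "red", shape = 4, size = 3, stroke = 1.2
    ) +
    ggplot2::facet_wrap(~species) +
    ggplot2::coord_cartesian(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(
      x = "nutrient A intake", y = "nutrient B intake",
      title = "Nutrient array and Thales circle"
    ) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- list(
    points = records, means = means, target = tg_df, circle = circ_df
  )
  p
}

#' Angle-summary panel: per-rail deviation from 90 degrees
#'
#' Plots the estimated mean angle deviation of each rail with its confidence
#' interval, against the rails ordered by nutrient ratio, with a reference
#' line at zero deviation (an angle of 90 degrees, the CDO prediction).
#'
#' @param estimates A [estimate_rail_deviations()] tibble or an
#'   `array_summary`.
#' @param raw_beta Plot the raw angle (reference line at 90) instead of the
#'   deviation (reference line at 0).
#' @return A `ggplot` object with the plotted table in `attr(, "plot_data")`.
#' @export
plot_beta_summary <- function(estimates, raw_beta = FALSE) {
  if (inherits(estimates, "array_summary")) {
    estimates <- estimates$estimates
  }
  df <- tibble::as_tibble(estimates)
  offset <- if (raw_beta) 90 else 0
  df$y <- df$mean_dev + offset
  df$ymin <- df$lwr95 + offset
  df$ymax <- df$upr95 + offset
  df$rail <- rail_factor(df$rail)

  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rail, .data$y, colour = .data$species)) +
    ggplot2::geom_hline(yintercept = offset, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(
      x = "nutritional rail (A:B ratio)",
      y = if (raw_beta) "angle beta (deg)" else "deviation beta - 90 (deg)",
      title = "Per-rail deviation from the CDO prediction"
    ) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- df
  p
}

#' Noise-stability panel
#'
#' Plots the simulated mean angle against the noise proportion for each error
#' family, with the 95 percent simulation band as a ribbon and the true
#' 90-degree angle as a reference line.
#'
#' @param sim A [noise_stability_simulation()] result.
#' @return A `ggplot` object with the plotted table in `attr(, "plot_data")`.
#' @export
plot_noise_stability <- function(sim) {
  df <- tibble::as_tibble(sim)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$noise_proportion, .data$mean_beta,
    colour = .data$family, fill = .data$family
  )) +
    ggplot2::geom_hline(yintercept = 90, linetype = 2, colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lwr95, ymax = .data$upr95),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "noise proportion (scale / |target|)",
      y = "estimated angle beta (deg)",
      title = "Stability of the angle estimate under increasing error"
    ) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- df
  p
}
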