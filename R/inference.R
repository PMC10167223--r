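# Per-rail deviation inference: angle records per observation, pooled-variance
# confidence intervals in the cell-means parameterisation, and the omnibus and
# species-by-rail ANOVA tests.

#' Compute per-observation Thales angles for a dataset
#'
#' Computes the angle \eqn{\beta} and its deviation from 90 degrees for every
#' rail-treatment record, against the (per-species) intake target. Choice
#' records define the target and never enter the angle computation. Records
#' coinciding with the origin or the target (degenerate triangle vertices)
#' are dropped with a warning and counted in the `dropped` attribute.
#'
#' @param dataset An [intake_dataset()].
#' @param target Optional explicit target `(nutrient_a, nutrient_b)` applied
#'   to every species; otherwise the target is estimated per species from its
#'   choice records via [estimate_intake_target()].
#' @param species Optional species filter.
#' @param tol_deg Angular tolerance for the `on`-circle classification.
#' @return Tibble of class `angle_records` with one row per rail record:
#'   `species`, `group`, `rail`, `nutrient_a`, `nutrient_b`, `beta_deg`,
#'   `deviation_deg`, `position`. Attributes: `targets` (named list of the
#'   target used per species), `dropped` (number of degenerate rows).
#' @export
angle_records <- function(dataset, target = NULL, species = NULL, tol_deg = 1e-8) {
  if (!is.null(species)) {
    dataset <- dataset[dataset$species %in% species, , drop = FALSE]
  }
  rails <- dataset[dataset$treatment == "rail", , drop = FALSE]
  if (nrow(rails) == 0L) {
    nutri_stop("no rail-treatment records to compute angles for.")
  }

  targets <- list()
  pieces <- lapply(split(rails, rails$species), function(df) {
    sp <- df$species[[1]]
    tg <- estimate_intake_target(dataset, species = sp, target = target)
    targets[[sp]] <<- tg

    p <- cbind(df$nutrient_a, df$nutrient_b)
    scale <- max(1, sqrt(sum(tg^2)))
    d_origin <- sqrt(rowSums(p^2))
    d_target <- sqrt(rowSums(sweep(p, 2L, tg)^2))
    keep <- d_origin > 1e-9 * scale & d_target > 1e-9 * scale
    df <- df[keep, , drop = FALSE]
    attr(df, "n_dropped") <- sum(!keep)
    if (nrow(df) > 0L) {
      df$beta_deg <- thales_angle(cbind(df$nutrient_a, df$nutrient_b), tg)
      df$deviation_deg <- df$beta_deg - 90
      df$position <- factor(
        ifelse(df$deviation_deg > tol_deg, "inside",
          ifelse(df$deviation_deg < -tol_deg, "outside", "on")
        ),
        levels = c("inside", "on", "outside")
      )
    }
    df
  })

  dropped <- sum(vapply(pieces, function(d) attr(d, "n_dropped"), numeric(1)))
  out <- dplyr::bind_rows(pieces[vapply(pieces, nrow, integer(1)) > 0])
  if (dropped > 0) {
    warning(sprintf(
      "%d record(s) coincided with the origin or the intake target and were dropped.",
      dropped
    ), call. = FALSE)
  }
  if (nrow(out) == 0L) {
    nutri_stop("all rail records were degenerate; no angles computed.")
  }
  out <- out[, c(
    "species", "group", "rail", "nutrient_a", "nutrient_b",
    "beta_deg", "deviation_deg", "position"
  )]
  structure(
    tibble::as_tibble(out),
    targets = targets, dropped = dropped,
    class = c("angle_records", class(tibble::tibble()))
  )
}

## Shared residual-df guard for the linear models below.
check_residual_df <- function(n, k, what) {
  if (n - k < 1L) {
    nutri_stop(sprintf(
      "%s needs at least one residual degree of freedom (n = %d observations, %d parameters); add replicate observations.",
      what, n, k
    ))
  }
}

#' Per-rail deviation estimates with confidence intervals
#'
#' Estimates the mean angle deviation (\eqn{\beta - 90}) of every rail, with
#' confidence intervals, per species. The default is a cell-means linear
#' model (`deviation ~ rail - 1`) with pooled residual variance, so each
#' coefficient is a rail mean and its `confint()` bound is the interval
#' reported; `pooled = FALSE` gives independent per-rail t-intervals instead.
#' A rail whose interval covers zero is consistent with the CDO rule.
#'
#' @param records An [angle_records()] tibble (any data frame with `species`,
#'   `rail`, `deviation_deg` columns works).
#' @param species Optional species filter.
#' @param conf_level Confidence level, default `0.95`.
#' @param pooled Pool residual variance across rails within a species
#'   (cell-means model, the default) or use independent per-rail intervals.
#' @return Tibble of class `rail_estimates`: `species`, `rail`, `n`,
#'   `mean_dev`, `lwr95`, `upr95`, `cdo_consistent`, with rails ordered by
#'   increasing nutrient ratio.
#' @export
estimate_rail_deviations <- function(records, species = NULL, conf_level = 0.95,
                                     pooled = TRUE) {
  if (conf_level <= 0 || conf_level >= 1) {
    nutri_stop("`conf_level` must lie strictly between 0 and 1.")
  }
  if (!is.null(species)) {
    records <- records[records$species %in% species, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    nutri_stop("no angle records to estimate from.")
  }

  one_species <- function(df) {
    sp <- df$species[[1]]
    f <- droplevels(rail_factor(df$rail))
    if (pooled) {
      check_residual_df(nrow(df), nlevels(f),
        sprintf("pooled deviation model for species '%s'", sp)
      )
      fit <- if (nlevels(f) == 1L) {
        lm(df$deviation_deg ~ 1)
      } else {
        lm(df$deviation_deg ~ 0 + f)
      }
      ci <- confint(fit, level = conf_level)
      lev <- levels(f)
      tibble::tibble(
        species = sp,
        rail = lev,
        n = as.integer(table(droplevels(f))[lev]),
        mean_dev = unname(coef(fit)),
        lwr95 = unname(ci[, 1]),
        upr95 = unname(ci[, 2])
      )
    } else {
      alpha <- 1 - conf_level
      dplyr::summarise(
        dplyr::group_by(
          tibble::tibble(rail = f, dev = df$deviation_deg), .data$rail
        ),
        species = sp,
        n = dplyr::n(),
        mean_dev = mean(.data$dev),
        half = if (dplyr::n() >= 2) {
          qt(1 - alpha / 2, dplyr::n() - 1) * stats::sd(.data$dev) / sqrt(dplyr::n())
        } else {
          NA_real_
        },
        .groups = "drop"
      ) |>
        dplyr::mutate(
          lwr95 = .data$mean_dev - .data$half,
          upr95 = .data$mean_dev + .data$half,
          rail = as.character(.data$rail)
        ) |>
        dplyr::select("species", "rail", "n", "mean_dev", "lwr95", "upr95")
    }
  }

  out <- dplyr::bind_rows(lapply(split(records, records$species), one_species))
  out$cdo_consistent <- out$lwr95 <= 0 & out$upr95 >= 0
  out <- out[order(out$species, rail_sort_key(out$rail)), , drop = FALSE]
  structure(
    tibble::as_tibble(out),
    conf_level = conf_level,
    class = c("rail_estimates", class(tibble::tibble()))
  )
}

new_beta_ftest <- function(term, F, df1, df2, p) {
  structure(
    list(term = term, F = F, df1 = df1, df2 = df2, p = p),
    class = "beta_ftest"
  )
}

#' @export
print.beta_ftest <- function(x, ...) {
  cat(sprintf(
    "%s: F(%d, %d) = %.3f, p %s\n",
    x$term, x$df1, x$df2, x$F,
    if (x$p < 0.001) "< 0.001" else sprintf("= %.4g", x$p)
  ))
  invisible(x)
}

#' Omnibus rail effect on angle deviations
#'
#' One-way ANOVA F-test for the rail factor on per-observation angle
#' deviations: do the mean deviations differ across nutritional rails?
#'
#' @inheritParams estimate_rail_deviations
#' @return A `beta_ftest`: list with `term`, `F`, `df1`, `df2`, `p`.
#' @export
omnibus_rail_test <- function(records, species = NULL) {
  if (!is.null(species)) {
    records <- records[records$species %in% species, , drop = FALSE]
  }
  f <- droplevels(rail_factor(records$rail))
  if (nlevels(f) < 2L) {
    nutri_stop("omnibus rail test needs at least two rail levels.")
  }
  check_residual_df(nrow(records), nlevels(f), "omnibus rail test")
  tab <- anova(lm(records$deviation_deg ~ f))
  new_beta_ftest(
    "rail", tab$`F value`[1], tab$Df[1], tab$Df[2], tab$`Pr(>F)`[1]
  )
}

#' Species-by-rail interaction on angle deviations
#'
#' Two-way ANOVA of the angle deviations on species, rail, and their
#' interaction, restricted to the rails both species share. The interaction F
#' uses sequential (fit-order) sums of squares with the main effects entered
#' first; a significant interaction means the shape of the nutrient array --
#' the rule of compromise -- differs between the species.
#'
#' @inheritParams estimate_rail_deviations
#' @param species_pair Optional character vector of exactly two species
#'   labels; defaults to the two species present in `records`.
#' @return A `beta_ftest` for the `species:rail` term.
#' @export
interaction_test <- function(records, species_pair = NULL) {
  if (!is.null(species_pair)) {
    if (length(species_pair) != 2L) {
      nutri_stop("`species_pair` must name exactly two species.")
    }
    records <- records[records$species %in% species_pair, , drop = FALSE]
  }
  sps <- unique(records$species)
  if (length(sps) != 2L) {
    nutri_stop(sprintf(
      "interaction test needs exactly two species, found %d.", length(sps)
    ))
  }
  shared <- intersect(
    unique(records$rail[records$species == sps[1]]),
    unique(records$rail[records$species == sps[2]])
  )
  if (length(shared) < 2L) {
    nutri_stop("the two species share fewer than two rail levels.")
  }
  records <- records[records$rail %in% shared, , drop = FALSE]

  sp <- factor(records$species)
  rl <- droplevels(rail_factor(records$rail))
  check_residual_df(nrow(records), nlevels(sp) * nlevels(rl), "interaction test")
  tab <- anova(lm(records$deviation_deg ~ sp + rl + sp:rl))
  i <- which(rownames(tab) == "sp:rl")
  new_beta_ftest(
    "species:rail", tab$`F value`[i], tab$Df[i], tab$Df[nrow(tab)], tab$`Pr(>F)`[i]
  )
}

#' Full array summary: estimates plus hypothesis tests
#'
#' Convenience wrapper producing, from a set of angle records, the per-rail
#' deviation estimates for every species, the omnibus rail test per species,
#' and (when exactly two species share at least two rails) the species-by-
#' rail interaction test.
#'
#' @inheritParams estimate_rail_deviations
#' @return An `array_summary`: list with `estimates` (tibble), `omnibus`
#'   (named list of `beta_ftest` per species) and `interaction`
#'   (`beta_ftest` or `NULL`).
#' @export
summarize_array <- function(records, conf_level = 0.95, pooled = TRUE) {
  estimates <- estimate_rail_deviations(records,
    conf_level = conf_level, pooled = pooled
  )
  sps <- unique(records$species)
  omnibus <- lapply(setNames(sps, sps), function(sp) {
    tryCatch(omnibus_rail_test(records, species = sp),
      nutriangle_error = function(e) NULL
    )
  })
  interaction <- if (length(sps) == 2L) {
    tryCatch(interaction_test(records), nutriangle_error = function(e) NULL)
  } else {
    NULL
  }
  structure(
    list(estimates = estimates, omnibus = omnibus, interaction = interaction),
    class = "array_summary"
  )
}

#' @export
print.array_summary <- function(x, ...) {
  cat("Per-rail deviation of the Thales angle from 90 deg\n")
  print(x$estimates, n = nrow(x$estimates))
  for (sp in names(x$omnibus)) {
    if (!is.null(x$omnibus[[sp]])) {
      cat(sprintf("%s ", sp))
      print(x$omnibus[[sp]])
    }
  }
  if (!is.null(x$interaction)) {
    print(x$interaction)
  }
  invisible(x)
}
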