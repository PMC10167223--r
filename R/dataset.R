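# Reading, validating and modelling intake datasets, and estimating the
# intake target from choice treatments.

default_column_map <- function() {
  c(
    species = "species", treatment = "treatment", rail = "rail",
    nutrient_a = "protein", nutrient_b = "carbohydrate", group = "group"
  )
}

#' Validate and construct an intake dataset
#'
#' Canonicalises a data frame of individual intake records. Each row is one
#' animal's cumulative intake of two nutrients, under either a fixed-ratio
#' `rail` treatment (the rail label is required) or a free `choice` treatment
#' (used to estimate the intake target). By default nutrient A is protein and
#' nutrient B carbohydrate, with rail labels read as P:C ratios.
#'
#' @param x Data frame of intake records.
#' @param column_map Named character vector mapping the canonical fields
#'   `species`, `treatment`, `rail`, `nutrient_a`, `nutrient_b` (and
#'   optionally `group`) to the columns of `x`. Defaults to
#'   `c(species = "species", treatment = "treatment", rail = "rail",
#'   nutrient_a = "protein", nutrient_b = "carbohydrate")`. Only the fields
#'   you want to remap need to be supplied.
#' @param allow_negative Permit negative intakes. Observed data must be
#'   non-negative (the default); synthetic arrays with additive centred noise
#'   may legitimately dip below zero.
#'
#' @return A tibble of class `intake_dataset` with columns `species`,
#'   `group`, `treatment`, `rail`, `nutrient_a`, `nutrient_b`, carrying a
#'   `load_report` attribute of per-species, per-rail record counts (see
#'   [load_report()]).
#' @export
intake_dataset <- function(x, column_map = NULL, allow_negative = FALSE) {
  map <- default_column_map()
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown) > 0) {
      nutri_stop(sprintf(
        "unknown column_map field(s): %s.", paste(unknown, collapse = ", ")
      ))
    }
    map[names(column_map)] <- column_map
  }

  required <- c("species", "treatment", "rail", "nutrient_a", "nutrient_b")
  missing_cols <- setdiff(map[required], names(x))
  if (length(missing_cols) > 0) {
    nutri_stop(sprintf(
      "missing column(s): %s.", paste(missing_cols, collapse = ", ")
    ))
  }

  out <- tibble::tibble(
    species = as.character(x[[map[["species"]]]]),
    group = if (map[["group"]] %in% names(x)) {
      as.character(x[[map[["group"]]]])
    } else {
      NA_character_
    },
    treatment = as.character(x[[map[["treatment"]]]]),
    rail = if (map[["rail"]] %in% names(x)) {
      as.character(x[[map[["rail"]]]])
    } else {
      NA_character_
    },
    nutrient_a = as.numeric(x[[map[["nutrient_a"]]]]),
    nutrient_b = as.numeric(x[[map[["nutrient_b"]]]])
  )
  if (nrow(out) == 0L) {
    nutri_stop("empty dataset: no intake records.")
  }

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      sprintf("%s (row %s)", what, paste(head(rows, 8L), collapse = ", "))
    } else {
      character(0)
    }
  }

  bad_treat <- which(!out$treatment %in% c("rail", "choice"))
  problems <- c(problems, note(bad_treat, "treatment must be 'rail' or 'choice'"))

  bad_nut <- which(!is.finite(out$nutrient_a) | !is.finite(out$nutrient_b))
  problems <- c(problems, note(bad_nut, "non-finite nutrient intake"))
  if (!allow_negative) {
    neg <- which(out$nutrient_a < 0 | out$nutrient_b < 0)
    problems <- c(problems, note(neg, "negative nutrient intake"))
  }

  is_rail <- out$treatment == "rail"
  rail_ok <- vapply(seq_len(nrow(out)), function(i) {
    if (!isTRUE(is_rail[i])) {
      return(TRUE)
    }
    if (is.na(out$rail[i])) {
      return(FALSE)
    }
    !inherits(try(parse_rail(out$rail[i]), silent = TRUE), "try-error")
  }, logical(1))
  problems <- c(problems, note(which(!rail_ok), "missing or malformed rail label"))

  if (length(problems) > 0) {
    nutri_stop(paste0(
      "invalid intake record(s):\n  - ", paste(problems, collapse = "\n  - ")
    ))
  }

  report <- dplyr::count(out, .data$species, .data$treatment, .data$rail,
    name = "n_records"
  )
  structure(
    out,
    load_report = report,
    class = c("intake_dataset", class(tibble::tibble()))
  )
}

#' Per-species, per-rail record counts of a dataset
#'
#' @param x An [intake_dataset()].
#' @return Tibble with columns `species`, `treatment`, `rail`, `n_records`.
#' @export
load_report <- function(x) {
  attr(x, "load_report")
}

#' Read an intake dataset from CSV
#'
#' Reads a UTF-8 CSV (header row required) of individual intake records and
#' validates it via [intake_dataset()]. Rows failing validation abort the
#' read with row-indexed messages.
#'
#' @param path Path to the CSV file.
#' @inheritParams intake_dataset
#' @return A validated `intake_dataset`.
#' @export
read_intake_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    nutri_stop(sprintf("input file not found: '%s'.", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) nutri_stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0L) {
    nutri_stop(sprintf("empty input file: '%s'.", path))
  }
  intake_dataset(raw, column_map = column_map)
}

#' Estimate the intake target
#'
#' The intake target is the nutrient coordinate animals defend when allowed
#' to feed freely. With an explicit `target` it is returned unchanged;
#' otherwise it is estimated as the arithmetic mean of the choice-treatment
#' records (optionally restricted to one species).
#'
#' @param dataset An [intake_dataset()].
#' @param species Optional species label to restrict the choice records.
#' @param target Optional explicit target coordinate `(nutrient_a,
#'   nutrient_b)`; when supplied, choice records are ignored.
#' @return Named numeric `(nutrient_a, nutrient_b)`.
#' @export
estimate_intake_target <- function(dataset, species = NULL, target = NULL) {
  if (!is.null(target)) {
    target <- validate_target(target)
    if (any(target <= 0)) {
      nutri_stop("explicit intake target must be strictly positive in both nutrients.")
    }
    return(setNames(target, c("nutrient_a", "nutrient_b")))
  }
  rows <- dataset[dataset$treatment == "choice", , drop = FALSE]
  if (!is.null(species)) {
    rows <- rows[rows$species %in% species, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    nutri_stop(sprintf(
      "no choice-treatment records%s to estimate the intake target from; supply `target` explicitly.",
      if (is.null(species)) "" else sprintf(" for species '%s'", paste(species, collapse = ", "))
    ))
  }
  setNames(
    c(mean(rows$nutrient_a), mean(rows$nutrient_b)),
    c("nutrient_a", "nutrient_b")
  )
}

#' Write a per-rail deviation summary to CSV
#'
#' Serialises the output of [estimate_rail_deviations()] (or the `estimates`
#' element of [summarize_array()]) in the customary table layout: one row per
#' species and ratio with the mean angle deviation and its confidence bounds.
#' Values round-trip at full precision.
#'
#' @param x Tibble of rail estimates, or an `array_summary`.
#' @param path Output CSV path.
#' @return Invisibly, the written path.
#' @export
write_summary_csv <- function(x, path) {
  if (inherits(x, "array_summary")) {
    x <- x$estimates
  }
  if (!is.data.frame(x) || nrow(x) == 0L) {
    nutri_stop("empty summary: nothing to write.")
  }
  out <- tibble::tibble(
    species = x$species,
    ratio = as.character(x$rail),
    n = x$n,
    mean_beta_dev = x$mean_dev,
    lwr95 = x$lwr95,
    upr95 = x$upr95,
    cdo_consistent = x$cdo_consistent
  )
  tryCatch(
    readr::write_csv(out, path),
    error = function(e) nutri_stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}
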