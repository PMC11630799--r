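#' Published inactivation thresholds for reference organisms
#'
#' Accumulated doses at which a 10^-6 fraction of a dormant population
#' remains viable, extrapolated from published culture dosage experiments:
#' 1000 Gy for *Escherichia coli*, 8400 Gy for *Bacillus subtilis* and
#' 15 000 Gy for *Deinococcus radiodurans*. These three organisms span the
#' radio-sensitive to highly radio-resistant range and are the packaged
#' defaults for [survival_table()]; users may instead fit their own curves
#' with [fit_loglinear()] and convert via [dose_to_fraction()].
#'
#' @return Tibble with columns `organism`, `threshold_dose_gy`, `source`.
#' @examples
#' reference_thresholds()
#' @export
reference_thresholds <- function() {
  tibble(
    organism = c("E. coli", "B. subtilis", "D. radiodurans"),
    threshold_dose_gy = c(1000, 8400, 15000),
    source = "published"
  )
}

check_survival_curve <- function(curve) {
  check_columns(curve, c("dose_gy", "surviving_fraction"), "curve")
  if (nrow(curve) < 2L) {
    abort("A survival curve needs at least 2 points.",
          class = "radhab_data_error")
  }
  check_number(curve$dose_gy, "dose_gy", min = 0)
  check_number(curve$surviving_fraction, "surviving_fraction",
               min = 0, max = 1, allow_min = FALSE)
  if (any(diff(curve$dose_gy) <= 0)) {
    abort("Curve doses must be strictly increasing.",
          class = "radhab_data_error")
  }
  invisible(curve)
}

#' Fit a log-linear (single-hit) inactivation curve
#'
#' Least-squares fit of `log10(S)` against dose. The decimal-reduction dose
#' D10 (the dose cutting survival tenfold) is `-1/slope`. When the curve
#' contains an exact unirradiated control point `(0, 1)` the intercept is
#' fixed at zero (the curve is assumed normalised to that control);
#' otherwise the intercept is free. Shouldered (linear-quadratic) curves are
#' outside this model; the fit's R-squared is reported so poor log-linear
#' fits are visible, and a curve whose fitted slope is non-negative is
#' rejected as non-inactivating.
#'
#' @param curve Tibble with columns `dose_gy`, `surviving_fraction`
#'   (fractions in (0, 1], doses strictly increasing) and optionally
#'   `organism`.
#' @param organism Label for the fitted organism; defaults to the curve's
#'   `organism` column if present.
#' @return An object of class `"survival_fit"` with elements `organism`,
#'   `d10_gy`, `slope`, `intercept`, `r_squared`, `n_points`, `data`.
#'   [tidy()] and [glance()] methods return tibbles.
#' @examples
#' curve <- tibble::tibble(dose_gy = c(0, 2500), surviving_fraction = c(1, 0.1))
#' fit_loglinear(curve)$d10_gy  # 2500
#' @export
fit_loglinear <- function(curve, organism = NULL) {
  check_survival_curve(curve)
  organism <- organism %||%
    (if ("organism" %in% names(curve)) unique(curve$organism)[1] else NA_character_)
  if (all(curve$surviving_fraction >= 1)) {
    abort("Curve has no point with surviving fraction < 1; cannot fit.",
          class = "radhab_data_error")
  }

  d <- curve$dose_gy
  y <- log10(curve$surviving_fraction)
  fixed <- any(d == 0 & curve$surviving_fraction == 1)

  if (fixed) {
    usable <- d > 0
    if (sum(usable) < 1L) {
      abort("Fewer than 2 usable points for a fixed-intercept fit.",
            class = "radhab_data_error")
    }
    slope <- sum(d * y) / sum(d^2)
    intercept <- 0
    fitted <- slope * d
    # uncentred R^2: the model is constrained through the origin
    r2 <- if (sum(y^2) > 0) 1 - sum((y - fitted)^2) / sum(y^2) else 1
  } else {
    sxx <- sum((d - mean(d))^2)
    if (sxx == 0) {
      abort("Fewer than 2 distinct doses; cannot fit.",
            class = "radhab_data_error")
    }
    slope <- sum((d - mean(d)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(d)
    fitted <- intercept + slope * d
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else 1
  }

  if (slope >= 0) {
    abort("Non-inactivating curve: fitted log10-survival slope is >= 0.",
          class = "radhab_fit_error")
  }

  structure(
    list(organism = organism, d10_gy = -1 / slope, slope = slope,
         intercept = intercept, r_squared = r2, n_points = nrow(curve),
         intercept_fixed = fixed, data = as_tibble(curve)),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Log-linear inactivation fit",
      if (!is.na(x$organism)) paste0("for ", x$organism) else "", "\n")
  cat(sprintf("  D10: %.6g Gy  (slope %.4g per Gy, intercept %s)\n",
              x$d10_gy, x$slope,
              if (x$intercept_fixed) "fixed at 0" else format(x$intercept, digits = 4)))
  cat(sprintf("  R-squared: %.4f over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_loglinear
#' @param x A `survival_fit` object.
#' @param ... Unused.
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble(organism = x$organism,
         d10_gy = x$d10_gy,
         slope_per_gy = x$slope,
         intercept_log10 = x$intercept,
         source = "fitted")
}

#' @rdname fit_loglinear
#' @export
glance.survival_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared,
         n_points = x$n_points,
         intercept_fixed = x$intercept_fixed)
}

#' Dose at which survival falls to a target fraction
#'
#' Under log-linear inactivation the accumulated dose leaving a surviving
#' fraction `f` is `D10 * log10(1/f)`; for the one-in-a-million threshold
#' (`f = 1e-6`) this is six decimal reductions, `6 * D10`.
#'
#' @param d10_gy Decimal-reduction dose in Gy; > 0. Vectorised.
#' @param target_fraction Surviving fraction in (0, 1]; default 1e-6.
#' @return Dose in Gy.
#' @examples
#' dose_to_fraction(2500)          # 15 000 Gy
#' dose_to_fraction(1400, 1e-6)    # 8400 Gy
#' @export
dose_to_fraction <- function(d10_gy, target_fraction = 1e-6) {
  check_number(d10_gy, "d10_gy", min = 0, allow_min = FALSE)
  check_number(target_fraction, "target_fraction", min = 0, max = 1,
               allow_min = FALSE)
  d10_gy * log10(1 / target_fraction)
}

#' Time to inactivation under a dose scenario
#'
#' The time at which a dormant population accumulates its inactivation
#' threshold dose: `threshold / effective_dose_rate`. A zero effective rate
#' yields the `Inf` ("never inactivated") sentinel, never an error. Times
#' describe dormant, non-repairing populations; metabolically active cells
#' performing continuous repair would survive longer.
#'
#' @param thresholds Tibble with columns `organism`, `threshold_dose_gy`
#'   (e.g. [reference_thresholds()]).
#' @param scenarios Scenario tibble ([dose_scenario()], [reference_scenarios()]).
#' @param weights Particle weights ([particle_weights()]).
#' @return Tibble with one row per (organism, scenario): `organism`,
#'   `scenario`, `threshold_dose_gy`, `effective_rate_gy_eq_yr`,
#'   `time_to_inactivation_yr`. Carries attribute
#'   `assumes_dormant_cells = TRUE`.
#' @examples
#' time_to_inactivation(reference_thresholds(),
#'                      dose_scenario("west_rand_low_gamma", 0.02))
#' @export
time_to_inactivation <- function(thresholds, scenarios,
                                 weights = particle_weights()) {
  survival_table(thresholds, scenarios, weights)
}

#' Organism-by-scenario survival table
#'
#' Computes [time_to_inactivation()] for every (organism, scenario) pair.
#' Within a scenario, times order identically to threshold doses, so the
#' packaged organisms always order E. coli < B. subtilis < D. radiodurans.
#'
#' @inheritParams time_to_inactivation
#' @return Long tibble, one row per (organism, scenario) pair; see
#'   [time_to_inactivation()].
#' @examples
#' survival_table(reference_thresholds(), reference_scenarios())
#' @export
survival_table <- function(thresholds, scenarios,
                           weights = particle_weights()) {
  check_columns(thresholds, c("organism", "threshold_dose_gy"), "thresholds")
  if (nrow(thresholds) == 0L || nrow(scenarios) == 0L) {
    abort("`thresholds` and `scenarios` must each have at least one row.",
          class = "radhab_validation_error")
  }
  check_number(thresholds$threshold_dose_gy, "threshold_dose_gy",
               min = 0, allow_min = FALSE)
  if (anyDuplicated(thresholds$organism)) {
    abort("Duplicate organism labels in `thresholds`.",
          class = "radhab_validation_error")
  }
  rates <- effective_dose_rate(scenarios, weights)

  out <- cross_join(select(thresholds, "organism", "threshold_dose_gy"),
                    select(rates, "scenario", "effective_rate_gy_eq_yr")) |>
    mutate(time_to_inactivation_yr = ifelse(
      .data$effective_rate_gy_eq_yr > 0,
      .data$threshold_dose_gy / .data$effective_rate_gy_eq_yr,
      Inf)) |>
    arrange(match(.data$scenario, scenarios$scenario),
            .data$threshold_dose_gy)
  attr(out, "assumes_dormant_cells") <- TRUE
  out
}

#' Format a survival table for reporting
#'
#' Rounds survival times to two significant figures (the precision used for
#' headline bounds such as "5200" or "750 000 years") and prints the
#' zero-rate sentinel as `"never"`. Raw full-precision values stay in the
#' unformatted table.
#'
#' @param table Output of [survival_table()].
#' @return The table with a character column `time_yr_2sf` added.
#' @export
format_survival_table <- function(table) {
  check_columns(table, c("organism", "scenario", "time_to_inactivation_yr"),
                "table")
  mutate(table, time_yr_2sf = ifelse(
    is.infinite(.data$time_to_inactivation_yr), "never",
    format(signif(.data$time_to_inactivation_yr, 2),
           big.mark = " ", scientific = FALSE, trim = TRUE)))
}

#' Read survival curves from delimited text
#'
#' Expects a TSV with columns `organism`, `dose_gy`, `surviving_fraction`;
#' `#` comments allowed. Each organism's points are validated as a curve.
#'
#' @param path File path.
#' @return Tibble of curve points; split by organism before fitting.
#' @export
read_survival_curves <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_columns(tbl, c("organism", "dose_gy", "surviving_fraction"),
                "survival curves")
  split(tbl, tbl$organism) |>
    lapply(function(x) check_survival_curve(arrange(x, .data$dose_gy)))
  tbl
}
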