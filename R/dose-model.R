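#' Construct an irradiation scenario
#'
#' A dose scenario names an absorbed dose rate (in gray per year, from in-rock
#' U/Th/K decay) together with the fraction of that dose delivered as alpha,
#' beta and gamma radiation. Scenarios are one-row tibbles so that several can
#' be stacked with [dplyr::bind_rows()] and fed to [survival_table()].
#'
#' @param name Scenario label (unique within a scenario set).
#' @param dose_rate_gy_per_yr Absorbed dose rate in Gy/yr; must be >= 0.
#' @param alpha,beta,gamma Fractions of the absorbed dose delivered by each
#'   particle type. Each must lie in \[0, 1\] and they must sum to 1 (within
#'   1e-9). `gamma` defaults to the remainder.
#'
#' @return A one-row tibble with columns `scenario`, `dose_rate_gy_per_yr`,
#'   `f_alpha`, `f_beta`, `f_gamma`.
#' @examples
#' dose_scenario("west_rand_low_gamma", 0.02)
#' dose_scenario("vaal_reef_high_mixed", 0.3, alpha = 0.5)
#' @export
dose_scenario <- function(name, dose_rate_gy_per_yr,
                          alpha = 0, beta = 0, gamma = 1 - alpha - beta) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "radhab_validation_error")
  }
  check_number(dose_rate_gy_per_yr, "dose_rate_gy_per_yr", min = 0)
  check_particle_mix(alpha, beta, gamma)
  tibble(
    scenario = name,
    dose_rate_gy_per_yr = dose_rate_gy_per_yr,
    f_alpha = alpha, f_beta = beta, f_gamma = gamma
  )
}

check_particle_mix <- function(alpha, beta, gamma) {
  for (nm in c("alpha", "beta", "gamma")) {
    check_number(get(nm), nm, min = 0, max = 1)
  }
  total <- alpha + beta + gamma
  if (abs(total - 1) > 1e-9) {
    abort(sprintf(
      "Particle-mix fractions must sum to 1: alpha = %s, beta = %s, gamma = %s (sum %s).",
      format(alpha), format(beta), format(gamma), format(total)),
      class = "radhab_validation_error")
  }
  invisible(TRUE)
}

check_scenarios <- function(scenarios) {
  check_columns(scenarios,
                c("scenario", "dose_rate_gy_per_yr", "f_alpha", "f_beta", "f_gamma"),
                "scenarios")
  check_number(scenarios$dose_rate_gy_per_yr, "dose_rate_gy_per_yr", min = 0)
  for (i in seq_len(nrow(scenarios))) {
    check_particle_mix(scenarios$f_alpha[i], scenarios$f_beta[i],
                       scenarios$f_gamma[i])
  }
  if (anyDuplicated(scenarios$scenario)) {
    abort("Scenario names must be unique.", class = "radhab_validation_error")
  }
  invisible(scenarios)
}

#' Biological weighting factors per particle type
#'
#' Relative-biological-effectiveness style weights applied to the absorbed
#' dose delivered by each particle type. The default weights alpha particles
#' by 20 (the standard radiation-protection quality factor for densely
#' ionising alpha radiation) and leave beta and gamma at 1.
#'
#' @param alpha,beta,gamma Positive multipliers; gamma defaults to 1 so that a
#'   pure-gamma scenario has effective rate equal to its absorbed rate.
#' @return A named numeric vector `c(alpha = , beta = , gamma = )`.
#' @examples
#' particle_weights()                 # alpha 20, beta 1, gamma 1
#' particle_weights(alpha = 10)
#' @export
particle_weights <- function(alpha = 20, beta = 1, gamma = 1) {
  for (nm in c("alpha", "beta", "gamma")) {
    check_number(get(nm), nm, min = 0, allow_min = FALSE)
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Effective (biologically weighted) dose rate
#'
#' Weights a scenario's absorbed dose rate by the particle mix:
#' `rate * (f_alpha * w_alpha + f_beta * w_beta + f_gamma * w_gamma)`,
#' reported in Gy-equivalent per year to distinguish weighted from absorbed
#' dose. Zero iff the absorbed rate is zero.
#'
#' @param scenarios A scenario tibble from [dose_scenario()] /
#'   [reference_scenarios()] (any number of rows).
#' @param weights Weights from [particle_weights()].
#' @return The input tibble with an `effective_rate_gy_eq_yr` column added.
#' @examples
#' effective_dose_rate(dose_scenario("low_gamma", 0.02))
#' @export
effective_dose_rate <- function(scenarios, weights = particle_weights()) {
  check_scenarios(scenarios)
  weights <- check_weights(weights)
  mutate(scenarios,
         effective_rate_gy_eq_yr = .data$dose_rate_gy_per_yr *
           (.data$f_alpha * weights[["alpha"]] +
            .data$f_beta * weights[["beta"]] +
            .data$f_gamma * weights[["gamma"]]))
}

check_weights <- function(weights) {
  if (is.list(weights)) weights <- unlist(weights)
  missing <- setdiff(c("alpha", "beta", "gamma"), names(weights))
  if (length(missing)) {
    abort(sprintf("`weights` must name alpha, beta and gamma (missing: %s).",
                  paste(missing, collapse = ", ")),
          class = "radhab_validation_error")
  }
  check_number(weights, "weights", min = 0, allow_min = FALSE)
  weights
}

#' Accumulated weighted dose over time
#'
#' Radiolytic exposure accumulates linearly: effective dose rate times the
#' number of years. Additive over disjoint intervals and monotone
#' non-decreasing in `years`.
#'
#' @inheritParams effective_dose_rate
#' @param years Duration in years (scalar, or one value per scenario row);
#'   must be >= 0.
#' @return The scenario tibble with `effective_rate_gy_eq_yr`, `years` and
#'   `dose_gy_eq` columns added.
#' @examples
#' accumulated_dose(dose_scenario("low_gamma", 0.02), years = 750000)
#' @export
accumulated_dose <- function(scenarios, years, weights = particle_weights()) {
  check_number(years, "years", min = 0)
  if (!length(years) %in% c(1L, nrow(scenarios))) {
    abort("`years` must be length 1 or one value per scenario.",
          class = "radhab_validation_error")
  }
  effective_dose_rate(scenarios, weights) |>
    mutate(years = years,
           dose_gy_eq = .data$effective_rate_gy_eq_yr * years)
}

#' Radionuclide inventory of a host rock
#'
#' @param uranium_ppm,thorium_ppm,potassium40_ppm Mass fractions in
#'   micrograms per gram of rock; all >= 0.
#' @return A one-row tibble with one column per nuclide.
#' @examples
#' radionuclide_inventory(uranium_ppm = 100)
#' @export
radionuclide_inventory <- function(uranium_ppm = 0, thorium_ppm = 0,
                                   potassium40_ppm = 0) {
  for (nm in c("uranium_ppm", "thorium_ppm", "potassium40_ppm")) {
    check_number(get(nm), nm, min = 0)
  }
  tibble(uranium_ppm = uranium_ppm, thorium_ppm = thorium_ppm,
         potassium40_ppm = potassium40_ppm)
}

#' Build a dose scenario from a radionuclide inventory
#'
#' Applies user-supplied linear per-ppm dose coefficients to an inventory:
#' the scenario's dose rate is the sum over nuclides and particle types of
#' `ppm * coefficient`, and its particle mix is proportional to the
#' per-particle contributions. Site-specific attenuation is not modelled;
#' coefficients encoding it must be supplied by the user. In particular the
#' shipped West Rand / Vaal Reef presets ([reference_scenarios()]) are
#' measured inputs, not outputs of this helper.
#'
#' @param inventory A one-row tibble from [radionuclide_inventory()].
#' @param coefficients Tibble with columns `nuclide` (one of `uranium`,
#'   `thorium`, `potassium40`), `particle` (`alpha`, `beta`, `gamma`) and
#'   `gy_per_yr_per_ppm` (>= 0). Every nuclide with a nonzero inventory must
#'   have at least one coefficient row.
#' @param name Label for the resulting scenario.
#' @return A one-row scenario tibble as from [dose_scenario()].
#' @examples
#' dose_rate_from_inventory(
#'   radionuclide_inventory(uranium_ppm = 1),
#'   tibble::tibble(nuclide = "uranium", particle = "alpha",
#'                  gy_per_yr_per_ppm = 0.02))
#' @export
dose_rate_from_inventory <- function(inventory, coefficients,
                                     name = "from_inventory") {
  check_columns(inventory, c("uranium_ppm", "thorium_ppm", "potassium40_ppm"),
                "inventory")
  check_columns(coefficients, c("nuclide", "particle", "gy_per_yr_per_ppm"),
                "coefficients")
  check_number(coefficients$gy_per_yr_per_ppm, "gy_per_yr_per_ppm", min = 0)
  bad_nuc <- setdiff(coefficients$nuclide, c("uranium", "thorium", "potassium40"))
  bad_par <- setdiff(coefficients$particle, c("alpha", "beta", "gamma"))
  if (length(bad_nuc) || length(bad_par)) {
    abort(sprintf("Unknown coefficient label(s): %s.",
                  paste(c(bad_nuc, bad_par), collapse = ", ")),
          class = "radhab_config_error")
  }

  ppm <- c(uranium = inventory$uranium_ppm[1],
           thorium = inventory$thorium_ppm[1],
           potassium40 = inventory$potassium40_ppm[1])
  uncovered <- setdiff(names(ppm)[ppm > 0], coefficients$nuclide)
  if (length(uncovered)) {
    abort(sprintf("No dose coefficient supplied for nonzero nuclide(s): %s.",
                  paste(uncovered, collapse = ", ")),
          class = "radhab_config_error")
  }

  contrib <- coefficients |>
    mutate(rate = .data$gy_per_yr_per_ppm * ppm[.data$nuclide]) |>
    group_by(.data$particle) |>
    summarise(rate = sum(.data$rate), .groups = "drop")
  total <- sum(contrib$rate)
  frac <- function(p) {
    if (total == 0) return(if (p == "gamma") 1 else 0)
    sum(contrib$rate[contrib$particle == p]) / total
  }
  dose_scenario(name, total,
                alpha = frac("alpha"), beta = frac("beta"), gamma = frac("gamma"))
}

#' Reference irradiation scenarios
#'
#' The two dose rates used for the Moab Khotsong habitability assessment —
#' 0.02 Gy/yr from West Rand uranium concentrations (1 ug/g U) and 0.3 Gy/yr
#' from the uranium-enriched Vaal Reef (100 ug/g U) — each combined with
#' three particle mixes: pure gamma, pure alpha, and 50% alpha / 50% gamma.
#' Both rates are measured site inputs (the mapping from ppm to Gy/yr is not
#' linear and is not recomputed here).
#'
#' @return A six-row scenario tibble.
#' @examples
#' reference_scenarios()
#' @export
reference_scenarios <- function() {
  sites <- tibble(site = c("west_rand_low", "vaal_reef_high"),
                  dose_rate_gy_per_yr = c(0.02, 0.3))
  mixes <- tibble(mix = c("gamma", "alpha", "mixed"),
                  f_alpha = c(0, 1, 0.5),
                  f_beta = 0,
                  f_gamma = c(1, 0, 0.5))
  cross_join(sites, mixes) |>
    mutate(scenario = paste(.data$site, .data$mix, sep = "_")) |>
    select("scenario", "dose_rate_gy_per_yr", "f_alpha", "f_beta", "f_gamma")
}

#' Radiolytic production rate of a chemical species
#'
#' Converts a radiolytic yield (G-value, molecules formed per 100 eV of
#' absorbed energy) and a dose rate into a molar production rate per litre of
#' water:
#' `P = G/100 * dose_rate * density * (eV per J) / N_A` in mol L^-1 yr^-1.
#' Linear in both the G-value and the dose rate.
#'
#' @param g_value Yield in molecules per 100 eV; >= 0. Vectorised.
#' @param dose_rate_gy_per_yr Absorbed dose rate in Gy/yr (J kg^-1 yr^-1).
#' @param water_density_kg_per_l Water density in kg/L (default 1; dense
#'   brines run slightly higher).
#' @return Production rate(s) in mol L^-1 yr^-1.
#' @examples
#' production_rate(g_value = 0.45, dose_rate_gy_per_yr = 0.3)  # H2 in pure water
#' @export
production_rate <- function(g_value, dose_rate_gy_per_yr,
                            water_density_kg_per_l = 1) {
  check_number(g_value, "g_value", min = 0)
  check_number(dose_rate_gy_per_yr, "dose_rate_gy_per_yr", min = 0)
  check_number(water_density_kg_per_l, "water_density_kg_per_l", min = 0)
  (g_value / 100) * dose_rate_gy_per_yr * water_density_kg_per_l *
    .EV_PER_JOULE / .AVOGADRO
}

#' Production table for a set of radiolytic species
#'
#' @param gvalues Tibble with columns `species`, `g_value`; defaults to the
#'   packaged pure-water table ([gvalue_defaults()]).
#' @inheritParams production_rate
#' @return `gvalues` with a `production_mol_per_l_yr` column added.
#' @export
radiolytic_production <- function(dose_rate_gy_per_yr,
                                  gvalues = gvalue_defaults(),
                                  water_density_kg_per_l = 1) {
  check_columns(gvalues, c("species", "g_value"), "gvalues")
  mutate(gvalues,
         production_mol_per_l_yr = production_rate(
           .data$g_value, dose_rate_gy_per_yr, water_density_kg_per_l))
}

#' Default radiolytic yields (pure water, gamma radiolysis)
#'
#' Literature primary yields for low-LET radiolysis of pure water, shipped as
#' an editable two-column table (`inst/extdata/gvalues_pure_water.tsv`).
#' Salinity and LET dependence of yields are not modelled; users with
#' brine-specific or alpha-track yields should load their own table with
#' [read_gvalue_table()].
#'
#' @return Tibble with columns `species`, `g_value` (molecules / 100 eV).
#' @export
gvalue_defaults <- function() {
  read_gvalue_table(system.file("extdata", "gvalues_pure_water.tsv",
                                package = "radhab", mustWork = TRUE))
}

#' Read a G-value table
#'
#' Two-column delimited text (`species`, `g_value`), `#` comments allowed.
#'
#' @param path File path.
#' @return Tibble with columns `species`, `g_value`.
#' @export
read_gvalue_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_columns(tbl, c("species", "g_value"), "G-value table")
  check_number(tbl$g_value, "g_value", min = 0)
  tbl
}

#' Read irradiation scenarios from a YAML/JSON config
#'
#' Accepts either a single scenario mapping or a list under a `scenarios`
#' key. Each scenario needs `name`, `dose_rate_gy_per_yr` and a `mix` mapping
#' with `alpha`/`beta`/`gamma` keys; a top-level `weights` mapping
#' (`alpha`/`beta`/`gamma`) is optional. Field-level problems are reported
#' with the scenario name.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return List with elements `scenarios` (tibble) and `weights` (named
#'   vector from [particle_weights()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  raw <- cfg$scenarios %||% list(cfg)
  scenarios <- map(raw, function(sc) {
    nm <- sc$name %||% "<unnamed>"
    for (field in c("name", "dose_rate_gy_per_yr", "mix")) {
      if (is.null(sc[[field]])) {
        abort(sprintf("Scenario '%s': missing required field `%s`.", nm, field),
              class = "radhab_config_error")
      }
    }
    dose_scenario(sc$name, sc$dose_rate_gy_per_yr,
                  alpha = sc$mix$alpha %||% 0,
                  beta = sc$mix$beta %||% 0,
                  gamma = sc$mix$gamma %||% 0)
  }) |> list_rbind()
  weights <- if (!is.null(cfg$weights)) {
    particle_weights(alpha = cfg$weights$alpha %||% 20,
                     beta = cfg$weights$beta %||% 1,
                     gamma = cfg$weights$gamma %||% 1)
  } else {
    particle_weights()
  }
  list(scenarios = check_scenarios(scenarios), weights = weights)
}
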