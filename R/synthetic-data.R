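#' Specification for the synthetic fixture generators
#'
#' Bundles the seed and the parameters every generator needs. One global
#' seed fans out to per-stage substreams (see Details), so
#' `simulate_taxonomy()` and `simulate_annotations()` can be regenerated
#' independently without disturbing each other.
#'
#' @details The substream seed for a stage is
#' `(seed %% 65536) * 31627 + hash(stage) mod (2^31 - 1)` where `hash` is a
#' small positional character hash; all generators wrap their draws in
#' [withr::with_seed()] so the caller's RNG state is untouched.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genomes Number of genomes to simulate.
#' @param family_proportions Named numeric vector of family proportions
#'   summing to 1 (within 1e-9).
#' @param module_targets Optional tibble `(genus, module_id, target)` of
#'   planted module-completeness fractions in \[0, 1\].
#' @param quality_distribution List with `completeness_mean`,
#'   `completeness_sd` (percent, truncated to \[0.1, 100\]) and
#'   `contamination_mean` (percent, exponential) for [simulate_quality()].
#' @param survival_curve_specs Optional tibble `(organism, true_d10_gy,
#'   n_points, noise_sd)` for [simulate_survival_curves()]; `noise_sd` is in
#'   decades of survival.
#' @param genera_per_family Genera to spread each family's genomes over
#'   (default 1).
#' @return A list of class `"simulation_spec"`.
#' @examples
#' simulation_spec(seed = 1, n_genomes = 10,
#'                 family_proportions = c(A = 0.6, B = 0.4))
#' @export
simulation_spec <- function(seed, n_genomes,
                            family_proportions,
                            module_targets = NULL,
                            quality_distribution = list(
                              completeness_mean = 60,
                              completeness_sd = 25,
                              contamination_mean = 2),
                            survival_curve_specs = NULL,
                            genera_per_family = 1) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.",
          class = "radhab_validation_error")
  }
  check_number(n_genomes, "n_genomes", min = 1)
  check_number(family_proportions, "family_proportions", min = 0, max = 1)
  if (is.null(names(family_proportions)) ||
      any(!nzchar(names(family_proportions)))) {
    abort("`family_proportions` must be a named vector.",
          class = "radhab_validation_error")
  }
  if (abs(sum(family_proportions) - 1) > 1e-9) {
    abort(sprintf("`family_proportions` must sum to 1 (got %s).",
                  format(sum(family_proportions))),
          class = "radhab_validation_error")
  }
  if (!is.null(module_targets)) {
    check_columns(module_targets, c("genus", "module_id", "target"),
                  "module_targets")
    check_number(module_targets$target, "target", min = 0, max = 1)
  }
  if (!is.null(survival_curve_specs)) {
    check_columns(survival_curve_specs,
                  c("organism", "true_d10_gy", "n_points", "noise_sd"),
                  "survival_curve_specs")
    check_number(survival_curve_specs$true_d10_gy, "true_d10_gy",
                 min = 0, allow_min = FALSE)
    check_number(survival_curve_specs$n_points, "n_points", min = 3)
    check_number(survival_curve_specs$noise_sd, "noise_sd", min = 0)
  }
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 family_proportions = family_proportions,
                 module_targets = module_targets,
                 quality_distribution = quality_distribution,
                 survival_curve_specs = survival_curve_specs,
                 genera_per_family = as.integer(genera_per_family)),
            class = "simulation_spec")
}

# stage-keyed substream seed; keeps every derived seed below 2^31 - 1
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer(((abs(as.numeric(seed)) %% 65536) * 31627 + h) %% 2147483647)
}

check_spec <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    abort("`spec` must come from simulation_spec().",
          class = "radhab_validation_error")
  }
  invisible(spec)
}

#' Apportion integer counts by largest remainder
#'
#' Hamilton apportionment: each class gets the floor of its quota
#' `n * proportion`; remaining units go to the classes with the largest
#' fractional remainders (ties broken by input order). Avoids the drift of
#' rounding each class independently — counts always sum to `n`.
#'
#' @param n Total count to apportion.
#' @param proportions Named numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @examples
#' largest_remainder(95, c(A = 0.58, B = 0.24, C = 0.08, other = 0.10))
#' @export
largest_remainder <- function(n, proportions) {
  check_number(proportions, "proportions", min = 0, max = 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1.", class = "radhab_validation_error")
  }
  quota <- n * proportions
  base <- floor(quota)
  extra <- round(n - sum(base))
  if (extra > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(extra)]
    base[take] <- base[take] + 1
  }
  setNames(as.integer(base), names(proportions))
}

#' Simulate a taxonomy table
#'
#' Generates `n_genomes` genome records whose family counts are the
#' largest-remainder apportionment of the spec's proportions. Each family's
#' genomes are spread round-robin over `genera_per_family` synthetic genera;
#' ranks above family are filled with synthetic placeholder lineages so the
#' table satisfies the no-gaps rank invariant. Row order is a seeded shuffle
#' (stage `"taxonomy"`), byte-identical across runs at a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @return Taxonomy tibble (`genome_id` + seven canonical ranks).
#' @export
simulate_taxonomy <- function(spec) {
  check_spec(spec)
  counts <- largest_remainder(spec$n_genomes, spec$family_proportions)
  family <- rep(names(counts), counts)
  genus <- paste0(family, "_g",
                  unlist(lapply(counts, function(k) {
                    if (k == 0) integer() else
                      rep_len(seq_len(spec$genera_per_family), k)
                  })))
  withr::with_seed(derive_seed(spec$seed, "taxonomy"), {
    ord <- sample.int(length(family))
  })
  tibble(
    genome_id = sprintf("SAG_%03d", seq_along(family)),
    domain = "Bacteria",
    phylum = "Synthetiphyla",
    class = "Synthetia",
    order = paste0(family[ord], "_order"),
    family = family[ord],
    genus = genus[ord],
    species = ""
  )
}

#' Simulate per-genome quality records
#'
#' Draws assembly completeness from a truncated normal (clamped to
#' \[0.1, 100\]) and contamination from an exponential, per the spec's
#' `quality_distribution`. Stage seed `"quality"`.
#'
#' @param spec A [simulation_spec()].
#' @param genome_ids Genome ids to cover; defaults to the ids
#'   [simulate_taxonomy()] would emit.
#' @return Quality tibble `(genome_id, completeness_pct, contamination_pct)`.
#' @export
simulate_quality <- function(spec, genome_ids = NULL) {
  check_spec(spec)
  genome_ids <- genome_ids %||% sprintf("SAG_%03d", seq_len(spec$n_genomes))
  qd <- spec$quality_distribution
  withr::with_seed(derive_seed(spec$seed, "quality"), {
    comp <- pmin(100, pmax(0.1, rnorm(length(genome_ids),
                                      qd$completeness_mean,
                                      qd$completeness_sd)))
    cont <- stats::rexp(length(genome_ids), rate = 1 / qd$contamination_mean)
  })
  tibble(genome_id = genome_ids,
         completeness_pct = comp,
         contamination_pct = cont)
}

#' Simulate quality records straddling retention thresholds
#'
#' Plants a known number of genomes passing and failing a retention rule,
#' with values drawn on either side of the completeness/contamination
#' boundaries — the fixture for testing the retention filter at scale
#' (e.g. 121 genomes of which 95 pass). Stage seed `"quality_straddle"`.
#'
#' @param seed Integer seed.
#' @param n_pass,n_fail Planted numbers of passing and failing genomes.
#' @param thresholds A [quality_thresholds()] object defining the boundary.
#' @return Quality tibble in seeded shuffled order.
#' @export
simulate_quality_straddle <- function(seed, n_pass, n_fail,
                                      thresholds = quality_thresholds()) {
  check_number(n_pass, "n_pass", min = 0)
  check_number(n_fail, "n_fail", min = 0)
  lo_c <- thresholds$min_completeness_pct
  hi_k <- thresholds$max_contamination_pct
  withr::with_seed(derive_seed(seed, "quality_straddle"), {
    pass <- tibble(
      completeness_pct = runif(n_pass, lo_c, 100),
      contamination_pct = runif(n_pass, 0, hi_k))
    mode <- sample(c("comp", "cont", "both"), n_fail, replace = TRUE)
    fail <- tibble(
      completeness_pct = ifelse(mode %in% c("comp", "both"),
                                runif(n_fail, 0, lo_c * 0.999),
                                runif(n_fail, lo_c, 100)),
      contamination_pct = ifelse(mode %in% c("cont", "both"),
                                 runif(n_fail, hi_k * 1.001, hi_k * 3),
                                 runif(n_fail, 0, hi_k)))
    out <- bind_rows(pass, fail)
    out <- out[sample.int(nrow(out)), ]
  })
  mutate(out, genome_id = sprintf("QC_%03d", seq_len(nrow(out))),
         .before = 1)
}

#' Simulate an annotation table with planted module completeness
#'
#' For every `(genus, module_id, target)` row of the spec's
#' `module_targets`, each genome of that genus receives annotations
#' completing the nearest achievable fraction of the module's steps
#' (`round(target * n_steps) / n_steps`, half-up); which steps, and which
#' alternative gene family within a step, are seeded draws (stage
#' `"annotations"`). Modules without a target stay at completeness 0. When
#' step granularity cannot represent a target exactly, a warning reports the
#' achieved value.
#'
#' @param spec A [simulation_spec()] with `module_targets`.
#' @param modules Module definitions ([module_definition()] /
#'   [simulate_modules()]).
#' @param taxonomy Taxonomy tibble from [simulate_taxonomy()].
#' @return Annotation tibble `(genome_id, gene_family_id, count)`.
#' @export
simulate_annotations <- function(spec, modules, taxonomy) {
  check_spec(spec)
  check_modules(modules)
  check_columns(taxonomy, c("genome_id", "genus"), "taxonomy")
  targets <- spec$module_targets
  if (is.null(targets)) {
    abort("`spec` has no module_targets.", class = "radhab_validation_error")
  }
  bad_mod <- setdiff(targets$module_id, modules$module_id)
  bad_gen <- setdiff(targets$genus, taxonomy$genus)
  if (length(bad_mod) || length(bad_gen)) {
    abort(sprintf("module_targets reference undefined %s: %s.",
                  if (length(bad_mod)) "modules" else "genera",
                  paste(c(bad_mod, bad_gen), collapse = ", ")),
          class = "radhab_validation_error")
  }

  step_list <- split(modules, modules$module_id)
  rows <- withr::with_seed(derive_seed(spec$seed, "annotations"), {
    pmap(targets, function(genus, module_id, target) {
      steps <- step_list[[module_id]]$alternatives
      n <- length(steps)
      k <- round_half_up(target * n)
      achieved <- k / n
      if (abs(achieved - target) > 1e-9) {
        warn(sprintf(
          "Target %.3f for (%s, %s) not reachable with %d steps; achieving %.3f.",
          target, genus, module_id, n, achieved))
      }
      genomes <- taxonomy$genome_id[taxonomy$genus == genus]
      if (k == 0 || length(genomes) == 0) return(NULL)
      list_rbind(map(genomes, function(g) {
        chosen <- sort(sample.int(n, k))
        fams <- map_chr(steps[chosen], function(alts)
          alts[[sample.int(length(alts), 1)]])
        tibble(genome_id = g, gene_family_id = fams, count = 1L)
      }))
    }) |> list_rbind()
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble(genome_id = character(), gene_family_id = character(),
                  count = integer()))
  }
  check_annotations(rows)
}

#' Simulate a bank of module definitions
#'
#' Synthetic modules with seeded step counts and per-step alternative gene
#' families, using KO-style identifiers unique to each module (stage
#' `"modules"`).
#'
#' @param n_modules Number of modules.
#' @param seed Integer seed.
#' @param steps_range Integer range of steps per module (default 2:6).
#' @param alts_range Integer range of alternatives per step (default 1:3).
#' @return Module-definition tibble.
#' @export
simulate_modules <- function(n_modules, seed, steps_range = 2:6,
                             alts_range = 1:3) {
  check_number(n_modules, "n_modules", min = 1)
  withr::with_seed(derive_seed(seed, "modules"), {
    list_rbind(map(seq_len(n_modules), function(i) {
      n_steps <- sample(steps_range, 1)
      steps <- map(seq_len(n_steps), function(s) {
        sprintf("K%05d", i * 1000 + s * 10 + seq_len(sample(alts_range, 1)))
      })
      module_definition(sprintf("M%05d", i), steps,
                        category = sprintf("category_%d", (i %% 5) + 1))
    }))
  })
}

#' Simulate noisy survival curves with known D10
#'
#' For each organism in the spec's `survival_curve_specs`, emits `n_points`
#' doses evenly spaced over \[0, 6 * D10\] (out to the one-in-a-million
#' threshold). The dose-zero point is the exact unirradiated control
#' `(0, 1)`; every positive-dose point follows
#' `S(D) = 10^(-D / D10) * 10^eps` with `eps ~ Normal(0, noise_sd)` in
#' decades. Stage seed `"survival_curves"`.
#'
#' @param spec A [simulation_spec()] with `survival_curve_specs`.
#' @return Tibble `(organism, dose_gy, surviving_fraction)`; doses strictly
#'   increasing within each organism.
#' @export
simulate_survival_curves <- function(spec) {
  check_spec(spec)
  specs <- spec$survival_curve_specs
  if (is.null(specs)) {
    abort("`spec` has no survival_curve_specs.",
          class = "radhab_validation_error")
  }
  withr::with_seed(derive_seed(spec$seed, "survival_curves"), {
    pmap(specs, function(organism, true_d10_gy, n_points, noise_sd, ...) {
      dose <- seq(0, 6 * true_d10_gy, length.out = n_points)
      eps <- c(0, rnorm(n_points - 1, 0, noise_sd))
      tibble(organism = organism, dose_gy = dose,
             surviving_fraction = pmin(1, 10^(-dose / true_d10_gy + eps)))
    }) |> list_rbind()
  })
}
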