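#' Run the survival analysis end to end
#'
#' Chains scenario construction, effective dose rates and
#' [survival_table()] from a single configuration, writing a TSV table, a
#' human-readable report and a machine-readable provenance block. Defaults
#' reproduce the packaged reference analysis: three organisms
#' ([reference_thresholds()]) by six scenarios ([reference_scenarios()])
#' with alpha weighted 20.
#'
#' @param config A list, or path to a YAML file, with optional fields:
#'   `scenarios` (scenario tibble, or a scenario-config structure as read by
#'   [read_scenario_config()]), `thresholds` (tibble `organism`,
#'   `threshold_dose_gy`), `weights` (list with `alpha`/`beta`/`gamma`),
#'   `out_dir` (directory for outputs; `NULL` skips writing), `seed`
#'   (recorded in provenance). Unknown fields raise an error.
#' @return Invisibly, a list with `table` (the survival tibble), `formatted`
#'   (2-significant-figure rendering) and `paths` (written files, if any).
#' @examples
#' res <- run_survival(list())
#' head(res$table)
#' @export
run_survival <- function(config = list()) {
  config <- load_config(config,
                        allowed = c("scenarios", "thresholds", "weights",
                                    "out_dir", "seed"))
  scenarios <- config$scenarios %||% reference_scenarios()
  if (!is.data.frame(scenarios)) {
    abort("`config$scenarios` must be a scenario tibble.",
          class = "radhab_config_error")
  }
  if (nrow(scenarios) == 0L) {
    abort("`config$scenarios` is empty: at least one scenario is required.",
          class = "radhab_config_error")
  }
  thresholds <- config$thresholds %||% reference_thresholds()
  weights <- if (is.null(config$weights)) particle_weights()
             else check_weights(config$weights)

  table <- survival_table(thresholds, scenarios, weights)
  formatted <- format_survival_table(table)
  paths <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(config$out_dir, "survival_table.tsv")
    readr::write_tsv(table, tsv)
    report <- file.path(config$out_dir, "survival_report.txt")
    writeLines(c(
      "Survival under accumulated radiolytic dose",
      "==========================================",
      "",
      sprintf("Particle weights: alpha=%g beta=%g gamma=%g",
              weights[["alpha"]], weights[["beta"]], weights[["gamma"]]),
      "Scenarios:",
      sprintf("  %s: %g Gy/yr (alpha %g / beta %g / gamma %g)",
              scenarios$scenario, scenarios$dose_rate_gy_per_yr,
              scenarios$f_alpha, scenarios$f_beta, scenarios$f_gamma),
      "Inactivation thresholds (Gy):",
      sprintf("  %s: %g", thresholds$organism, thresholds$threshold_dose_gy),
      "",
      "Times (years, 2 significant figures):",
      sprintf("  %-16s %-24s %s", formatted$organism, formatted$scenario,
              formatted$time_yr_2sf),
      "",
      paste("Note: times assume dormant, non-repairing populations;",
            "metabolically active cells performing continuous repair",
            "are expected to survive longer.")
    ), report)
    prov <- write_provenance(config$out_dir, config)
    paths <- c(table = tsv, report = report, provenance = prov)
  }
  invisible(list(table = table, formatted = formatted, paths = paths))
}

#' Run the annotation-profile analysis end to end
#'
#' Computes the completeness matrix, presence calls at both packaged
#' thresholds (strict > 0.70 for KEGG-style modules, non-strict >= 0.75 for
#' nutrient-cycling pathways), the genus-level aggregate over the top-3 most
#' complete genomes, and the family composition; optionally a shared-taxa
#' comparison against a second taxonomy. Writes TSV matrices plus
#' provenance.
#'
#' @param config A list, or path to a YAML file, with fields: `annotations`,
#'   `taxonomy`, `quality`, `modules` (tibbles or TSV paths — required);
#'   optional `compare_taxonomy` (tibble/path for [shared_taxa()]),
#'   `kegg_threshold` (default 0.70, strict), `pathway_threshold` (default
#'   0.75, non-strict), `top_n` (default 3), `shared_rank` (default
#'   `"family"`), `out_dir`, `seed`.
#' @return Invisibly, a list with `completeness`, `presence_kegg`,
#'   `presence_pathway`, `genus_pathways`, `composition`, `shared`
#'   (or `NULL`) and `paths`.
#' @export
run_profiles <- function(config) {
  config <- load_config(config,
                        allowed = c("annotations", "taxonomy", "quality",
                                    "modules", "compare_taxonomy",
                                    "kegg_threshold", "pathway_threshold",
                                    "top_n", "shared_rank", "out_dir", "seed"))
  for (field in c("annotations", "taxonomy", "quality", "modules")) {
    if (is.null(config[[field]])) {
      abort(sprintf("`config$%s` is required.", field),
            class = "radhab_config_error")
    }
  }
  annotations <- load_table(config$annotations, read_annotation_table)
  taxonomy <- load_table(config$taxonomy, read_taxonomy_table)
  quality <- load_table(config$quality, read_quality_table)
  modules <- load_table(config$modules, read_module_definitions)

  ids <- unique(annotations$genome_id)
  missing_tax <- setdiff(ids, taxonomy$genome_id)
  missing_q <- setdiff(ids, quality$genome_id)
  if (length(missing_tax) || length(missing_q)) {
    abort(c("Genome ids do not match across input files.",
            if (length(missing_tax))
              sprintf("Annotated but missing from taxonomy: %s",
                      paste(missing_tax, collapse = ", ")),
            if (length(missing_q))
              sprintf("Annotated but missing from quality: %s",
                      paste(missing_q, collapse = ", "))),
          class = "radhab_keyed_error")
  }

  kegg_thr <- config$kegg_threshold %||% 0.70
  path_thr <- config$pathway_threshold %||% 0.75
  top_n <- config$top_n %||% 3

  completeness <- module_completeness(annotations, modules,
                                      genomes = sort(taxonomy$genome_id))
  presence_kegg <- call_presence(completeness, kegg_thr, strict = TRUE)
  presence_pathway <- call_presence(completeness, path_thr, strict = FALSE)
  genus_pathways <- genus_aggregate(presence_pathway, taxonomy, quality,
                                    top_n = top_n)
  composition <- family_composition(taxonomy)
  shared <- NULL
  if (!is.null(config$compare_taxonomy)) {
    other <- load_table(config$compare_taxonomy, read_taxonomy_table)
    shared <- shared_taxa(taxonomy, other,
                          rank = config$shared_rank %||% "family")
  }

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- list(completeness = completeness,
                    presence_kegg = presence_kegg,
                    presence_pathway = presence_pathway,
                    genus_pathways = genus_pathways,
                    family_composition = composition)
    paths <- map_chr(names(outputs), function(nm) {
      p <- file.path(config$out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(outputs[[nm]], p)
      p
    })
    names(paths) <- names(outputs)
    if (!is.null(shared)) {
      p <- file.path(config$out_dir, "shared_taxa.tsv")
      readr::write_tsv(tibble(rank = config$shared_rank %||% "family",
                              taxon = shared), p)
      paths <- c(paths, shared_taxa = p)
    }
    paths <- c(paths, provenance = write_provenance(config$out_dir, config))
  }
  invisible(list(completeness = completeness, presence_kegg = presence_kegg,
                 presence_pathway = presence_pathway,
                 genus_pathways = genus_pathways, composition = composition,
                 shared = shared, paths = paths))
}

load_config <- function(config, allowed) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s.", config),
            class = "radhab_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a YAML file path.",
          class = "radhab_config_error")
  }
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s. Allowed: %s.",
                  paste(unknown, collapse = ", "),
                  paste(allowed, collapse = ", ")),
          class = "radhab_config_error")
  }
  config
}

load_table <- function(x, reader) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      abort(sprintf("Input file not found: %s.", x),
            class = "radhab_config_error")
    }
    return(reader(x))
  }
  abort("Inputs must be tibbles or file paths.",
        class = "radhab_config_error")
}

# provenance block: config hash + package version + seed, no timestamp so
# that reruns of the same config are byte-identical
write_provenance <- function(out_dir, config) {
  p <- file.path(out_dir, "provenance.json")
  hashable <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(
    list(package = "radhab",
         version = as.character(utils::packageVersion("radhab")),
         config_hash = rlang::hash(hashable),
         seed = config$seed %||% NA),
    p, auto_unbox = TRUE, pretty = TRUE, null = "null")
  p
}
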