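#' Define a metabolic module
#'
#' A module is an ordered list of steps, each step a set of alternative gene
#' families (KEGG orthologs, Pfam/TIGRFAM families, ...) any one of which
#' satisfies the step. This flat step-with-alternatives structure covers the
#' "OR" blocks of KEGG module definitions; nested boolean definitions should
#' be pre-flattened.
#'
#' @param module_id Module label (e.g. `"M00001"`).
#' @param steps List of character vectors, one per step, each non-empty.
#' @param category Optional functional category label.
#' @return Tibble with columns `module_id`, `category`, `step_index`,
#'   `alternatives` (list-column), one row per step.
#' @examples
#' module_definition("M_test", list(c("K001", "K002"), "K003"))
#' @export
module_definition <- function(module_id, steps, category = NA_character_) {
  if (length(steps) < 1L) {
    abort(sprintf("Module '%s' must have at least one step.", module_id),
          class = "radhab_definition_error")
  }
  if (any(lengths(steps) == 0L)) {
    abort(sprintf("Module '%s' has an empty step.", module_id),
          class = "radhab_definition_error")
  }
  tibble(module_id = module_id, category = category,
         step_index = seq_along(steps),
         alternatives = lapply(steps, as.character))
}

check_modules <- function(modules) {
  check_columns(modules, c("module_id", "step_index", "alternatives"), "modules")
  if (anyDuplicated(modules[c("module_id", "step_index")])) {
    abort("Duplicate (module_id, step_index) rows in module definitions.",
          class = "radhab_definition_error")
  }
  if (any(lengths(modules$alternatives) == 0L)) {
    abort("Module definitions contain an empty step.",
          class = "radhab_definition_error")
  }
  invisible(modules)
}

check_annotations <- function(annotations) {
  check_columns(annotations, c("genome_id", "gene_family_id", "count"),
                "annotations")
  check_number(annotations$count, "count", min = 0)
  # merge duplicate (genome, gene family) rows by summing counts
  annotations |>
    group_by(.data$genome_id, .data$gene_family_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Module completeness per genome
#'
#' For each genome and module, the fraction of the module's steps for which
#' the genome carries at least one qualifying gene family (any annotation
#' count > 0; multiplicity beyond presence is ignored). Genomes requested via
#' `genomes` but absent from the annotation table score 0 on every module
#' (with a note).
#'
#' @param annotations Tibble `(genome_id, gene_family_id, count)`; duplicate
#'   rows are merged by summing counts.
#' @param modules Module definitions ([module_definition()] rows bound
#'   together, or [read_module_definitions()]).
#' @param genomes Genomes to score; defaults to those present in
#'   `annotations`.
#' @return Long tibble `(genome_id, module_id, completeness)` with
#'   completeness in \[0, 1\], one row per genome-module pair.
#' @examples
#' ann <- tibble::tibble(genome_id = "g1", gene_family_id = c("K2", "K3"),
#'                       count = 1)
#' mod <- module_definition("M1", list(c("K1", "K2"), "K3", "K4"))
#' module_completeness(ann, mod)  # 2 of 3 steps
#' @export
module_completeness <- function(annotations, modules, genomes = NULL) {
  annotations <- check_annotations(annotations)
  check_modules(modules)
  genomes <- genomes %||% sort(unique(annotations$genome_id))
  absent <- setdiff(genomes, annotations$genome_id)
  if (length(absent)) {
    inform(sprintf(
      "%d genome(s) have no annotations and score 0 on every module: %s",
      length(absent), paste(head(absent, 5), collapse = ", ")))
  }

  present <- annotations |>
    filter(.data$count > 0, .data$genome_id %in% genomes)
  fams_by_genome <- split(present$gene_family_id, present$genome_id)

  steps <- tidyr::unnest(
    select(modules, "module_id", "step_index", "alternatives"),
    "alternatives") |>
    rename(gene_family_id = "alternatives")
  n_steps <- modules |> count(.data$module_id, name = "n_steps")

  grid <- cross_join(tibble(genome_id = genomes),
                     tibble(module_id = unique(modules$module_id)))
  hits <- map(genomes, function(g) {
    fams <- fams_by_genome[[g]] %||% character()
    steps |>
      filter(.data$gene_family_id %in% fams) |>
      distinct(.data$module_id, .data$step_index) |>
      count(.data$module_id, name = "n_hit") |>
      mutate(genome_id = g)
  }) |> list_rbind()

  grid |>
    left_join(hits, by = c("genome_id", "module_id")) |>
    left_join(n_steps, by = "module_id") |>
    mutate(completeness = ifelse(is.na(.data$n_hit), 0,
                                 .data$n_hit / .data$n_steps)) |>
    select("genome_id", "module_id", "completeness")
}

#' Threshold a completeness matrix into presence calls
#'
#' A module/pathway is called present in a genome when its completeness
#' exceeds the threshold — strictly (`> threshold`, the ">70% of KOFAM
#' annotations" KEGG-module rule) or non-strictly (`>= threshold`, the
#' ">=75% of gene annotations" nutrient-cycling pathway rule).
#'
#' @param completeness Long tibble `(genome_id, module_id, completeness)`
#'   from [module_completeness()].
#' @param threshold Completeness threshold in (0, 1].
#' @param strict If `TRUE` (default) presence requires completeness strictly
#'   above the threshold; if `FALSE`, at or above.
#' @return Long tibble `(genome_id, module_id, present)`.
#' @examples
#' m <- tibble::tibble(genome_id = "g", module_id = "M", completeness = 0.70)
#' call_presence(m, 0.70, strict = TRUE)$present   # FALSE: boundary excluded
#' call_presence(m, 0.70, strict = FALSE)$present  # TRUE
#' @export
call_presence <- function(completeness, threshold = 0.70, strict = TRUE) {
  check_columns(completeness, c("genome_id", "module_id", "completeness"),
                "completeness")
  check_number(threshold, "threshold", min = 0, max = 1, allow_min = FALSE)
  completeness |>
    mutate(present = if (strict) .data$completeness > threshold
           else .data$completeness >= threshold) |>
    select("genome_id", "module_id", "present")
}

#' Genus-level pathway presence over the most complete genomes
#'
#' For each genus, selects its `top_n` genomes by assembly completeness
#' (ties broken by lower contamination, then genome id) and calls a pathway
#' present for the genus if it is present in at least one selected genome —
#' the "top three most complete genomes per genus" summarisation rule.
#'
#' @param presence Long tibble `(genome_id, module_id, present)` from
#'   [call_presence()].
#' @param taxonomy Taxonomy tibble with `genome_id` and `genus` columns.
#' @param quality Tibble `(genome_id, completeness_pct, contamination_pct)`.
#' @param top_n Number of genomes per genus to consider (default 3); genera
#'   with fewer contribute all their genomes.
#' @return Long tibble `(genus, module_id, present)`.
#' @export
genus_aggregate <- function(presence, taxonomy, quality, top_n = 3) {
  check_columns(presence, c("genome_id", "module_id", "present"), "presence")
  check_columns(taxonomy, c("genome_id", "genus"), "taxonomy")
  check_quality(quality)
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
    abort("`top_n` must be a single integer >= 1.",
          class = "radhab_validation_error")
  }
  ids <- unique(presence$genome_id)
  missing_tax <- setdiff(ids, taxonomy$genome_id)
  missing_q <- setdiff(ids, quality$genome_id)
  if (length(missing_tax) || length(missing_q)) {
    abort(c("Genomes in the presence matrix lack required records.",
            if (length(missing_tax))
              sprintf("Missing taxonomy: %s", paste(missing_tax, collapse = ", ")),
            if (length(missing_q))
              sprintf("Missing quality: %s", paste(missing_q, collapse = ", "))),
          class = "radhab_keyed_error")
  }

  selected <- tibble(genome_id = ids) |>
    left_join(select(taxonomy, "genome_id", "genus"), by = "genome_id") |>
    left_join(select(quality, "genome_id", "completeness_pct",
                     "contamination_pct"), by = "genome_id") |>
    arrange(desc(.data$completeness_pct), .data$contamination_pct,
            .data$genome_id) |>
    group_by(.data$genus) |>
    slice_head(n = top_n) |>
    ungroup()

  presence |>
    inner_join(select(selected, "genome_id", "genus"), by = "genome_id") |>
    group_by(.data$genus, .data$module_id) |>
    summarise(present = any(.data$present), .groups = "drop")
}

check_quality <- function(quality) {
  check_columns(quality, c("genome_id", "completeness_pct", "contamination_pct"),
                "quality")
  check_number(quality$completeness_pct, "completeness_pct", min = 0, max = 100)
  check_number(quality$contamination_pct, "contamination_pct", min = 0)
  invisible(quality)
}

#' Family-level taxonomic composition
#'
#' Counts genomes per family and reports raw fractions (summing to exactly 1)
#' plus integer percents rounded half-up, the style used for composition
#' labels. Genomes with no family assignment are grouped under an explicit
#' `"unassigned"` bucket.
#'
#' @param taxonomy Taxonomy tibble with `genome_id` and `family` columns.
#' @return Tibble `(family, n, fraction, percent)` ordered by decreasing
#'   count.
#' @examples
#' tax <- tibble::tibble(genome_id = paste0("g", 1:4),
#'                       family = c("A", "A", "B", "C"))
#' family_composition(tax)
#' @export
family_composition <- function(taxonomy) {
  check_columns(taxonomy, c("genome_id", "family"), "taxonomy")
  if (nrow(taxonomy) == 0L) {
    abort("Taxonomy table is empty.", class = "radhab_data_error")
  }
  taxonomy |>
    mutate(family = ifelse(is.na(.data$family) | .data$family == "",
                           "unassigned", .data$family)) |>
    count(.data$family, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n),
           percent = round_half_up(100 * .data$fraction)) |>
    arrange(desc(.data$n), .data$family)
}

#' Taxa shared between two samples at a rank
#'
#' Intersection of the non-empty taxon names at one of the seven canonical
#' ranks — used e.g. to ask whether a brine community shares any families
#' with the mine's service water.
#'
#' @param a,b Taxonomy tibbles containing the rank column.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Sorted character vector of shared taxon names (possibly empty).
#' @export
shared_taxa <- function(a, b, rank = "family") {
  if (!is.character(rank) || length(rank) != 1L ||
      !rank %in% .CANONICAL_RANKS) {
    abort(sprintf("`rank` must be one of: %s.",
                  paste(.CANONICAL_RANKS, collapse = ", ")),
          class = "radhab_validation_error")
  }
  check_columns(a, rank, "a")
  check_columns(b, rank, "b")
  taxa <- function(x) {
    v <- x[[rank]]
    sort(unique(v[!is.na(v) & v != ""]))
  }
  intersect(taxa(a), taxa(b))
}

#' Family sets observed in the Moab Khotsong mine fluids
#'
#' The family-level identifications for the 101-level brine single-cell
#' genomes, the 1200-level dolomite-aquifer metagenome bins and the mine
#' service water. Only families explicitly reported are named; the service
#' water and 1200-level lists are padded to their reported family counts
#' (6 and 13) with synthetic placeholder labels, so intersections between
#' lists are exact while within-list diversity is representative.
#'
#' @return Named list of character vectors: `brine_101`, `dolomite_1200`,
#'   `service_water`.
#' @export
mine_fluid_families <- function() {
  shared <- c("Burkholderiaceae", "Rhodocyclaceae", "Thiobacillaceae")
  list(
    brine_101 = c("Halomonadaceae", "Microbacteriaceae", "Idiomarinaceae",
                  "Pseudomonadaceae", "Rhodospirillaceae", "Rhizobiaceae",
                  "Carnobacteriaceae", "Salinarimonadaceae"),
    dolomite_1200 = c(shared, paste0("dolomite_family_syn_", 1:10)),
    service_water = c(shared, paste0("service_family_syn_", 1:3))
  )
}

# --- readers -----------------------------------------------------------------

#' Read a per-genome annotation table
#'
#' Three-column TSV `(genome_id, gene_family_id, count)`; duplicate
#' (genome, gene family) rows are merged by summing counts.
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_annotation_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_annotations(tbl)
}

#' Read module definitions
#'
#' TSV with columns `module_id`, `step_index`, `alternatives`
#' (comma-separated gene families) and optionally `category`.
#'
#' @param path File path.
#' @return Module-definition tibble with an `alternatives` list-column.
#' @export
read_module_definitions <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_columns(tbl, c("module_id", "step_index", "alternatives"), "modules")
  if (!"category" %in% names(tbl)) tbl$category <- NA_character_
  tbl$alternatives <- strsplit(as.character(tbl$alternatives), ",[ ]*")
  check_modules(select(tbl, "module_id", "category", "step_index",
                       "alternatives"))
}

#' Read a taxonomy table
#'
#' Eight-column TSV: `genome_id` plus the seven canonical ranks. Genome ids
#' must be unique; a rank may be empty only if all ranks below it are empty.
#'
#' @param path File path.
#' @return Taxonomy tibble.
#' @export
read_taxonomy_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_taxonomy(tbl)
}

check_taxonomy <- function(tbl) {
  check_columns(tbl, c("genome_id", .CANONICAL_RANKS), "taxonomy")
  if (anyDuplicated(tbl$genome_id)) {
    abort("Duplicate genome_ids in taxonomy table.",
          class = "radhab_validation_error")
  }
  ranks <- as.matrix(tbl[.CANONICAL_RANKS])
  empty <- is.na(ranks) | ranks == ""
  bad <- apply(empty, 1, function(e) any(e[-length(e)] & !e[-1]))
  if (any(bad)) {
    abort(sprintf("Taxonomy rows with gaps above an assigned rank: %s.",
                  paste(tbl$genome_id[bad], collapse = ", ")),
          class = "radhab_validation_error")
  }
  tbl
}

#' Read a genome quality table
#'
#' TSV with columns `genome_id`, `completeness_pct`, `contamination_pct`.
#'
#' @param path File path.
#' @return Quality tibble.
#' @export
read_quality_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_quality(tbl)
  tbl
}
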