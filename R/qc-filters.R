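#' Retention thresholds for genome quality filtering
#'
#' Boundary semantics follow the exclusion wording of the single-cell
#' retention rule ("<1% completeness and/or >10% contamination were not
#' considered further"): the retained complement is completeness >= 1 AND
#' contamination <= 10, i.e. both comparators non-strict by default. Each
#' comparator can be flipped for rules stated the other way round.
#'
#' @param min_completeness_pct Completeness floor in percent (default 1).
#' @param max_contamination_pct Contamination ceiling in percent (default 10).
#' @param completeness_strict If `TRUE`, retention needs completeness
#'   strictly above the floor. Default `FALSE` (at or above).
#' @param contamination_strict If `TRUE`, retention needs contamination
#'   strictly below the ceiling. Default `FALSE` (at or below).
#' @return A list of class `"quality_thresholds"`.
#' @examples
#' quality_thresholds()  # the single-cell retention preset
#' @export
quality_thresholds <- function(min_completeness_pct = 1,
                               max_contamination_pct = 10,
                               completeness_strict = FALSE,
                               contamination_strict = FALSE) {
  check_number(min_completeness_pct, "min_completeness_pct", min = 0, max = 100)
  check_number(max_contamination_pct, "max_contamination_pct", min = 0)
  structure(list(min_completeness_pct = min_completeness_pct,
                 max_contamination_pct = max_contamination_pct,
                 completeness_strict = isTRUE(completeness_strict),
                 contamination_strict = isTRUE(contamination_strict)),
            class = "quality_thresholds")
}

#' Partition genomes into retained and rejected sets
#'
#' Applies completeness/contamination retention thresholds and reports, for
#' every rejected genome, which rule(s) fired. The retained and rejected
#' sets partition the input exactly, and re-filtering the retained set is a
#' no-op.
#'
#' @param quality Tibble `(genome_id, completeness_pct, contamination_pct)`.
#' @param thresholds A [quality_thresholds()] object; the default is the
#'   single-cell retention preset (keep completeness >= 1%,
#'   contamination <= 10%).
#' @return List with tibbles `retained` and `rejected`; `rejected` carries a
#'   `reasons` column (`"completeness"`, `"contamination"` or
#'   `"completeness,contamination"`).
#' @examples
#' q <- tibble::tibble(genome_id = c("a", "b"),
#'                     completeness_pct = c(0.5, 80),
#'                     contamination_pct = c(2, 3))
#' filter_genomes(q)$rejected$reasons  # "completeness"
#' @export
filter_genomes <- function(quality, thresholds = quality_thresholds()) {
  check_quality(quality)
  if (!inherits(thresholds, "quality_thresholds")) {
    abort("`thresholds` must come from quality_thresholds().",
          class = "radhab_validation_error")
  }
  comp_ok <- if (thresholds$completeness_strict) {
    quality$completeness_pct > thresholds$min_completeness_pct
  } else {
    quality$completeness_pct >= thresholds$min_completeness_pct
  }
  cont_ok <- if (thresholds$contamination_strict) {
    quality$contamination_pct < thresholds$max_contamination_pct
  } else {
    quality$contamination_pct <= thresholds$max_contamination_pct
  }
  reasons <- paste0(ifelse(comp_ok, "", "completeness"),
                    ifelse(comp_ok | cont_ok, "", ","),
                    ifelse(cont_ok, "", "contamination"))
  keep <- comp_ok & cont_ok
  list(retained = quality[keep, , drop = FALSE],
       rejected = mutate(quality[!keep, , drop = FALSE],
                         reasons = reasons[!keep]))
}

#' Tier metagenome bins by quality
#'
#' High-quality bins have completeness > 90% and contamination < 5%;
#' medium-quality bins (those not high) have completeness >= 50% and
#' contamination < 10%; everything else fails. Tiers are mutually exclusive
#' and exhaustive.
#'
#' @param quality Tibble `(genome_id, completeness_pct, contamination_pct)`.
#' @return The input with a `tier` column (`"high"`, `"medium"`, `"fail"`).
#' @examples
#' tier_bins(tibble::tibble(genome_id = "b1", completeness_pct = 91,
#'                          contamination_pct = 4.9))$tier  # "high"
#' @export
tier_bins <- function(quality) {
  check_quality(quality)
  mutate(quality, tier = dplyr::case_when(
    .data$completeness_pct > 90 & .data$contamination_pct < 5 ~ "high",
    .data$completeness_pct >= 50 & .data$contamination_pct < 10 ~ "medium",
    TRUE ~ "fail"))
}

#' Trim contig ends and drop short contigs
#'
#' Removes `trim_bp` bases from both ends of every contig and then retains
#' contigs whose trimmed length is strictly greater than `min_len` (the
#' assembly post-QC rule: trim 100 bp from ends, keep > 2000 bp). Trimming
#' happens before the length test; ids and input order are preserved.
#'
#' @param contigs A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param trim_bp Bases to remove from each end (default 100); >= 0.
#' @param min_len Minimum trimmed length, exclusive (default 2000); > 0.
#' @return A `DNAStringSet` of trimmed, retained contigs.
#' @examples
#' x <- Biostrings::DNAStringSet(c(keep = paste(rep("ACGT", 551), collapse = "")))
#' trim_filter_contigs(x)  # 2204 bp -> 2004 bp, retained
#' @export
trim_filter_contigs <- function(contigs, trim_bp = 100, min_len = 2000) {
  check_number(trim_bp, "trim_bp", min = 0)
  check_number(min_len, "min_len", min = 0, allow_min = FALSE)
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  } else if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (!methods::is(contigs, "DNAStringSet")) {
    abort("`contigs` must be a DNAStringSet, sequences, or a FASTA path.",
          class = "radhab_parse_error")
  }
  trimmed_len <- Biostrings::width(contigs) - 2 * trim_bp
  keep <- trimmed_len > min_len & trimmed_len > 0
  kept <- contigs[keep]
  if (length(kept) && trim_bp > 0) {
    kept <- Biostrings::subseq(kept, start = trim_bp + 1,
                               end = Biostrings::width(kept) - trim_bp)
  }
  kept
}

#' Assign genera to unannotated genomes by nucleotide identity
#'
#' Genomes without a taxonomy assignment inherit the genus of their
#' highest-identity annotated partner when the pairwise average nucleotide
#' identity (ANI) meets the cutoff (default >= 95%, the usual genus-scale
#' rule). Exact ANI ties are broken by lexicographic reference genome id.
#'
#' @param unassigned Character vector of genome ids lacking a genus.
#' @param taxonomy Taxonomy tibble (`genome_id`, `genus`) for annotated
#'   genomes.
#' @param ani Tibble `(query_genome, reference_genome, ani_pct)` with
#'   identities in \[0, 100\]. Records naming genomes outside
#'   `unassigned`/`taxonomy` raise a keyed error.
#' @param cutoff Minimum ANI in percent, inclusive (default 95).
#' @return Tibble `(genome_id, genus, reference_genome, ani_pct)`; genomes
#'   with no qualifying hit keep `genus = NA`.
#' @export
assign_genus_by_ani <- function(unassigned, taxonomy, ani, cutoff = 95) {
  check_columns(taxonomy, c("genome_id", "genus"), "taxonomy")
  check_columns(ani, c("query_genome", "reference_genome", "ani_pct"), "ani")
  check_number(ani$ani_pct, "ani_pct", min = 0, max = 100)
  check_number(cutoff, "cutoff", min = 0, max = 100, allow_min = FALSE)

  known <- c(unassigned, taxonomy$genome_id)
  unknown <- setdiff(c(ani$query_genome, ani$reference_genome), known)
  if (length(unknown)) {
    abort(sprintf("ANI records reference unknown genome(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "radhab_keyed_error")
  }

  hits <- ani |>
    filter(.data$query_genome %in% unassigned,
           .data$reference_genome %in% taxonomy$genome_id,
           .data$ani_pct >= cutoff) |>
    left_join(select(taxonomy, reference_genome = "genome_id", "genus"),
              by = "reference_genome") |>
    filter(!is.na(.data$genus)) |>
    arrange(desc(.data$ani_pct), .data$reference_genome) |>
    group_by(.data$query_genome) |>
    slice_head(n = 1) |>
    ungroup()

  tibble(genome_id = unassigned) |>
    left_join(select(hits, genome_id = "query_genome", "genus",
                     "reference_genome", "ani_pct"),
              by = "genome_id")
}
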