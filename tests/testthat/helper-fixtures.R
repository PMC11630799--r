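# Shared fixture builders. Everything is generated in code; no files.

make_taxonomy <- function(genomes, genus, family = paste0(genus, "aceae")) {
  tibble::tibble(
    genome_id = genomes,
    domain = "Bacteria", phylum = "P", class = "C",
    order = paste0(family, "_o"), family = family, genus = genus,
    species = ""
  )
}

make_quality <- function(genomes, completeness, contamination = 1) {
  tibble::tibble(genome_id = genomes,
                 completeness_pct = completeness,
                 contamination_pct = rep_len(contamination, length(genomes)))
}

# exact log-linear curve through (0, 1) for a planted D10
exact_curve <- function(d10, n_points = 5, max_dose = 6 * d10) {
  dose <- seq(0, max_dose, length.out = n_points)
  tibble::tibble(dose_gy = dose, surviving_fraction = 10^(-dose / d10))
}

# family proportions as listed for the 101-level brine community
brine_family_proportions <- function() {
  c(Halomonadaceae = 0.58, Microbacteriaceae = 0.24, Idiomarinaceae = 0.08,
    Pseudomonadaceae = 0.03, Rhodospirillaceae = 0.03, Rhizobiaceae = 0.02,
    Carnobacteriaceae = 0.01, Salinarimonadaceae = 0.01)
}
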