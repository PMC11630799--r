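test_that("module completeness is the satisfied-step fraction", {
  mod <- module_definition("M1", list("K1", "K2", "K3", "K4"))
  ann <- tibble::tibble(genome_id = "g1",
                        gene_family_id = c("K1", "K2", "K3"), count = 1)
  expect_equal(module_completeness(ann, mod)$completeness, 0.75)

  # genome with no hits scores zero (and absent genomes score zero, noted)
  none <- tibble::tibble(genome_id = "g1", gene_family_id = "K9", count = 1)
  expect_equal(module_completeness(none, mod)$completeness, 0)
  expect_message(
    res <- module_completeness(ann, mod, genomes = c("g1", "ghost")),
    "no annotations")
  expect_equal(res$completeness[res$genome_id == "ghost"], 0)

  # zero counts do not count as presence
  zero <- tibble::tibble(genome_id = "g1", gene_family_id = "K1", count = 0)
  expect_equal(module_completeness(zero, mod)$completeness, 0)
})

test_that("any one alternative satisfies a step (brute force over 2 steps)", {
  mod <- module_definition("M", list(c("A", "B"), "C"))
  # enumerate every subset of {A, B, C} and compare with direct evaluation
  fams <- c("A", "B", "C")
  for (bits in 0:7) {
    have <- fams[bitwAnd(bits, c(1, 2, 4)) > 0]
    expected <- (as.integer(any(c("A", "B") %in% have)) +
                   as.integer("C" %in% have)) / 2
    ann <- tibble::tibble(genome_id = "g",
                          gene_family_id = c(have, "pad"), count = 1)
    expect_equal(module_completeness(ann, mod)$completeness, expected,
                 info = paste("subset:", paste(have, collapse = ",")))
  }
})

test_that("completeness is monotone under added annotations", {
  mods <- dplyr::bind_rows(
    module_definition("M1", list(c("K1", "K2"), "K3", "K4")),
    module_definition("M2", list("K5", c("K6", "K7"))))
  fams <- sprintf("K%d", 1:7)
  withr::with_seed(42, {
    for (i in 1:20) {
      base_fams <- sample(fams, sample(0:5, 1))
      extra <- sample(setdiff(fams, base_fams), 1)
      ann <- function(f) tibble::tibble(genome_id = "g",
                                        gene_family_id = c(f, "pad"),
                                        count = 1)
      before <- module_completeness(ann(base_fams), mods)$completeness
      after <- module_completeness(ann(c(base_fams, extra)), mods)$completeness
      expect_true(all(after >= before))
    }
  })
})

test_that("duplicate annotation rows merge by summing counts", {
  mod <- module_definition("M", list("K1", "K2"))
  dup <- tibble::tibble(genome_id = "g", gene_family_id = c("K1", "K1"),
                        count = c(0, 1))
  expect_equal(module_completeness(dup, mod)$completeness, 0.5)
})

test_that("presence calls honour strict and non-strict boundaries", {
  cm <- tibble::tibble(genome_id = "g", module_id = "M",
                       completeness = c(0.70, 0.75, 0.71))
  cm$module_id <- c("M1", "M2", "M3")
  strict <- call_presence(cm, 0.70, strict = TRUE)
  expect_equal(strict$present, c(FALSE, TRUE, TRUE))   # 0.70 excluded
  nonstrict <- call_presence(cm, 0.75, strict = FALSE)
  expect_equal(nonstrict$present, c(FALSE, TRUE, FALSE)) # 0.75 included

  # monotone in completeness, anti-monotone in threshold
  grid <- tibble::tibble(genome_id = "g", module_id = sprintf("m%02d", 1:11),
                         completeness = seq(0, 1, by = 0.1))
  p1 <- call_presence(grid, 0.4)$present
  expect_equal(p1, grid$completeness > 0.4)
  p2 <- call_presence(grid, 0.8)$present
  expect_true(all(p1 >= p2))
})

test_that("genus aggregation selects the top-n most complete genomes", {
  genomes <- sprintf("g%d", 1:5)
  tax <- make_taxonomy(genomes, genus = "Halomonas")
  qual <- make_quality(genomes, completeness = c(90, 80, 70, 60, 50))
  # pathway present only in the 4th-most-complete genome -> absent at top 3
  pres <- tibble::tibble(genome_id = genomes, module_id = "path1",
                         present = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  agg <- genus_aggregate(pres, tax, qual, top_n = 3)
  expect_false(agg$present)
  # present in the single most-complete genome -> present
  pres2 <- pres
  pres2$present <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_true(genus_aggregate(pres2, tax, qual, top_n = 3)$present)
  # fewer genomes than top_n considers them all
  small <- genus_aggregate(pres2[4:5, ], tax[4:5, ], qual[4:5, ], top_n = 3)
  expect_false(small$present)
  small2 <- genus_aggregate(pres[4:5, ], tax[4:5, ], qual[4:5, ], top_n = 3)
  expect_true(small2$present)
})

test_that("genus aggregation ties break by contamination then id", {
  genomes <- sprintf("g%d", 1:4)
  tax <- make_taxonomy(genomes, genus = "G")
  qual <- tibble::tibble(genome_id = genomes,
                         completeness_pct = c(80, 80, 80, 80),
                         contamination_pct = c(5, 1, 2, 1))
  # top 3 by (completeness desc, contamination asc, id asc): g2, g4, g3
  pres <- tibble::tibble(genome_id = genomes, module_id = "m",
                         present = c(TRUE, FALSE, FALSE, FALSE))
  expect_false(genus_aggregate(pres, tax, qual, top_n = 3)$present)
})

test_that("genus aggregation equals brute force when top_n covers the genus", {
  withr::with_seed(7, {
    genomes <- sprintf("g%02d", 1:12)
    tax <- make_taxonomy(genomes,
                         genus = sample(c("A", "B", "C"), 12, replace = TRUE))
    qual <- make_quality(genomes, completeness = runif(12, 10, 99),
                         contamination = runif(12, 0, 9))
    pres <- tidyr::expand_grid(genome_id = genomes,
                               module_id = c("m1", "m2")) |>
      dplyr::mutate(present = runif(dplyr::n()) > 0.6)
    agg <- genus_aggregate(pres, tax, qual, top_n = 12)
    brute <- pres |>
      dplyr::left_join(tax[c("genome_id", "genus")], by = "genome_id") |>
      dplyr::group_by(genus, module_id) |>
      dplyr::summarise(present = any(present), .groups = "drop")
    expect_equal(as.data.frame(agg), as.data.frame(brute))
  })
})

test_that("genus aggregation reports missing taxonomy/quality by id", {
  pres <- tibble::tibble(genome_id = c("g1", "g2"), module_id = "m",
                         present = TRUE)
  tax <- make_taxonomy("g1", genus = "A")
  qual <- make_quality(c("g1", "g2"), completeness = 50)
  expect_error(genus_aggregate(pres, tax, qual), "g2",
               class = "radhab_keyed_error")
})

test_that("family composition reports counts, exact fractions and percents", {
  tax <- make_taxonomy(sprintf("g%d", 1:95),
                       genus = "x",
                       family = rep(c("Halomonadaceae", "other"), c(55, 40)))
  comp <- family_composition(tax)
  expect_equal(comp$n[comp$family == "Halomonadaceae"], 55)
  expect_equal(comp$percent[comp$family == "Halomonadaceae"], 58)  # 57.9 -> 58
  expect_equal(sum(comp$fraction), 1)
  expect_equal(sum(comp$n), 95)

  single <- family_composition(make_taxonomy("g1", "x", "F"))
  expect_equal(single$percent, 100)

  four <- family_composition(make_taxonomy(sprintf("g%d", 1:4), "x",
                                           family = c("A", "B", "C", "D")))
  expect_equal(four$percent, rep(25, 4))

  # unassigned families collect in an explicit bucket
  na_tax <- make_taxonomy(c("g1", "g2"), "x", family = c("A", NA))
  expect_true("unassigned" %in% family_composition(na_tax)$family)

  expect_error(family_composition(make_taxonomy(character(), character())),
               "empty", class = "radhab_data_error")
})

test_that("shared taxa intersect non-empty names at the requested rank", {
  fams <- mine_fluid_families()
  brine <- make_taxonomy(sprintf("b%d", seq_along(fams$brine_101)), "x",
                         family = fams$brine_101)
  service <- make_taxonomy(sprintf("s%d", seq_along(fams$service_water)), "x",
                           family = fams$service_water)
  dolomite <- make_taxonomy(sprintf("d%d", seq_along(fams$dolomite_1200)), "x",
                            family = fams$dolomite_1200)

  # the brine shares no family with the service water
  expect_length(shared_taxa(brine, service, "family"), 0)
  # dolomite aquifer and service water share exactly the three reported
  expect_equal(shared_taxa(dolomite, service, "family"),
               sort(c("Burkholderiaceae", "Rhodocyclaceae", "Thiobacillaceae")))
  # symmetry and idempotence
  expect_equal(shared_taxa(service, dolomite, "family"),
               shared_taxa(dolomite, service, "family"))
  expect_equal(shared_taxa(brine, brine, "family"),
               sort(fams$brine_101))
  # empty ranks never count as shared
  empty_sp <- shared_taxa(brine, brine, "species")
  expect_length(empty_sp, 0)

  expect_error(shared_taxa(brine, service, "tribe"), "rank",
               class = "radhab_validation_error")
})

test_that("annotation, taxonomy and module tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  ann_path <- file.path(dir, "ann.tsv")
  readr::write_tsv(tibble::tibble(genome_id = c("g1", "g1"),
                                  gene_family_id = c("K1", "K1"),
                                  count = c(1, 2)), ann_path)
  ann <- read_annotation_table(ann_path)
  expect_equal(nrow(ann), 1)         # duplicates merged
  expect_equal(ann$count, 3)

  mod_path <- file.path(dir, "mod.tsv")
  writeLines(c("module_id\tstep_index\talternatives",
               "M1\t1\tK1,K2", "M1\t2\tK3"), mod_path)
  mods <- read_module_definitions(mod_path)
  expect_equal(mods$alternatives[[1]], c("K1", "K2"))

  tax_path <- file.path(dir, "tax.tsv")
  readr::write_tsv(make_taxonomy(c("g1", "g2"), "Halomonas"), tax_path)
  expect_equal(nrow(read_taxonomy_table(tax_path)), 2)

  # a gap above an assigned rank is invalid
  bad <- make_taxonomy("g1", "Halomonas")
  bad$family <- ""
  bad_path <- file.path(dir, "bad.tsv")
  readr::write_tsv(bad, bad_path)
  expect_error(read_taxonomy_table(bad_path), "gaps",
               class = "radhab_validation_error")
})
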