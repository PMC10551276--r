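test_that("spectrum counts conserve across classifications", {
  cat168 <- example_catalog_168()
  s <- spectrum_summary(cat168, n_patients = 32)
  expect_equal(s$n_distinct_mutations, 168L)
  expect_equal(s$coding_count + s$noncoding_count, s$n_distinct_mutations)
  expect_equal(sum(s$complex_counts), s$coding_count)
  expect_equal(s$transition_count + s$transversion_count,
               s$n_distinct_mutations)
  expect_equal(sum(s$substitution_counts), s$n_distinct_mutations)
  # per-gene counts within RCI sum to the complex count
  rci_genes <- unique(mito_gene_map()$name[mito_gene_map()$complex == "RCI"])
  expect_equal(sum(s$gene_counts[names(s$gene_counts) %in% rci_genes]),
               unname(s$complex_counts["RCI"]))
  expect_equal(unname(s$complex_counts["RCI"]), 74L)
})

test_that("spectrum invariants hold on random catalogs", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(5:60, 1)
    pos <- sample.int(16569, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    cat <- mitosomatic:::annotate_mutations(
      data.frame(position = pos, ref_base = ref, alt_base = alt,
                 total_depth = 5000L, ref_reads = 2500L, alt_reads = 2500L),
      patient_id = "P1")
    s <- spectrum_summary(cat, n_patients = 1)
    expect_equal(s$coding_count + s$noncoding_count, s$n_distinct_mutations)
    expect_equal(sum(s$complex_counts), s$coding_count)
    expect_equal(s$transition_count + s$transversion_count,
                 s$n_distinct_mutations)
    expect_equal(sum(s$region_counts) + s$coding_count,
                 s$n_distinct_mutations)
  }
})

test_that("a mutation shared by k patients counts once in the spectrum", {
  cat <- rbind(key_catalog("P1", c("G3842A", "T7953G")),
               key_catalog("P2", "G3842A"))
  cat <- mitosomatic:::annotate_positions(cat)
  s <- spectrum_summary(cat, n_patients = 2)
  expect_equal(s$n_distinct_mutations, 2L)
  fr <- mutation_frequency(cat, n_patients = 2)
  expect_equal(fr$count[fr$key == "G3842A"], 2L)
  expect_equal(fr$percent[fr$key == "G3842A"], 100)
})

test_that("patient frequencies use round-half-up percents", {
  cat <- do.call(rbind, lapply(sprintf("P%02d", 1:12),
                               key_catalog, keys = "T7953G"))
  cat <- mitosomatic:::annotate_positions(cat)
  fr <- mutation_frequency(cat, n_patients = 32)
  expect_equal(fr$count, 12L)
  expect_equal(fr$percent, 38)       # 12/32 = 37.5 -> 38
  fr1 <- mutation_frequency(mitosomatic:::annotate_positions(
    key_catalog("P1", "G1888A")), n_patients = 32)
  expect_equal(fr1$percent, 3)       # 1/32 = 3.125 -> 3
  expect_error(mutation_frequency(cat, 0), "n_patients")
})

test_that("hotspot panel selects by frequency with deterministic order", {
  cat <- rbind(
    do.call(rbind, lapply(sprintf("P%02d", 1:12), key_catalog, keys = "T7953G")),
    do.call(rbind, lapply(sprintf("P%02d", 1:7), key_catalog, keys = "T4434G")),
    key_catalog("P01", "G1888A"))
  cat <- mitosomatic:::annotate_positions(cat)
  fr <- mutation_frequency(cat, n_patients = 32)
  panel <- hotspot_panel(fr, min_frequency = 0.19)
  expect_equal(panel$key, c("T7953G", "T4434G"))   # 38%, 22%; 3% excluded
  expect_true(all(panel$frequency >= 0.19))
  expect_equal(nrow(hotspot_panel(fr[0, ], 0.19)), 0L)
  expect_error(hotspot_panel(fr, 0), "min_frequency")
  expect_true(all(panel$key %in% fr$key))
})

test_that("novelty and pathogenicity come from the lookup table", {
  cat <- mitosomatic:::annotate_positions(
    key_catalog("P1", c("G3842A", "T7953G", "A10935G")))
  kv <- data.frame(position = c(7953L, 10935L), ref_base = c("T", "A"),
                   alt_base = c("G", "G"),
                   reported_in_databases = c(TRUE, TRUE),
                   pathogenic = c(TRUE, FALSE),
                   haplogroup_marker = FALSE)
  fl <- flag_known(cat, kv)
  expect_equal(fl$novel, c(TRUE, FALSE, FALSE))
  expect_equal(fl$pathogenic, c(FALSE, TRUE, FALSE))
  # empty table: everything novel, nothing pathogenic
  fl0 <- flag_known(cat)
  expect_true(all(fl0$novel))
  expect_false(any(fl0$pathogenic))
})

test_that("mutational load divides patient-mutation counts by group size", {
  cat <- mitosomatic:::annotate_positions(rbind(
    key_catalog("P1", c("G3842A", "T7953G", "A10935G")),
    key_catalog("P2", c("G3842A", "G1888A", "T4434G", "T14894G")),
    key_catalog("P3", c("G13709A", "T3572A", "A3520C", "G9500A",
                        "G5000A", "G6000A", "G7000A", "G12400A"))))
  groups <- data.frame(patient_id = c("P1", "P2", "P3", "P4", "P5"),
                       group = c("A", "A", "B", "B", "A"))
  load <- mutational_load(cat, groups)
  # group A: 7 patient-mutations over 3 patients (P5 has none)
  expect_equal(load$load[load$group == "A"], round(7 / 3, 1))
  expect_equal(load$load[load$group == "B"], 8 / 2)
  # single patient, 7 mutations -> 7.0
  one <- mutational_load(
    mitosomatic:::annotate_positions(key_catalog("Q1", sprintf("G%dA", 1:7))),
    data.frame(patient_id = "Q1", group = "all"))
  expect_equal(one$load, 7)
  expect_error(mutational_load(cat, groups[c(1, 1), ]), "exactly one")
})

test_that("overall load is additive over a region partition", {
  cat <- example_catalog_168()
  groups <- data.frame(patient_id = "COHORT", group = "all")
  total <- mutational_load(cat, groups, digits = 6)$load
  parts <- vapply(c("RCI", "RCIII", "RCIV", "RCV", "rRNA", "tRNA",
                    "control"), function(r)
    mutational_load(cat, groups, region = r, digits = 6)$load, 0)
  expect_equal(sum(parts), total)
})

test_that("region-restricted loads recover an injected ancestry ratio", {
  # truth-ledger comparison on a simulated two-ancestry cohort with
  # RCI-like load ratio ~ 4.1 : 1.8
  cfg <- simulation_config(
    n_patients = 120,
    ancestry_split = c(African = 0.5, European = 0.5),
    group_load_targets = c(African = 8.2, European = 3.6),
    hotspot_injection = NULL, ev_patient_fraction = 0, seed = 21)
  co <- simulate_cohort(cfg)
  rec <- evaluate_recovery(co)
  loads <- rec$group_loads
  ratio <- loads$load[loads$group == "African"] /
    loads$load[loads$group == "European"]
  expect_equal(ratio, 8.2 / 3.6, tolerance = 0.2)
})

test_that("identical catalogs give identical summaries (determinism)", {
  cat <- example_catalog_168()
  s1 <- spectrum_summary(cat, 32)
  s2 <- spectrum_summary(example_catalog_168(), 32)
  expect_identical(s1, s2)
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s1, path1)
  write_summary_json(s2, path2)
  expect_identical(readLines(path1), readLines(path2))
})
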