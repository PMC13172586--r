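small_config <- function(...) {
  simulation_config(proteins_per_fraction = c(4L, 5L, 6L),
                    length_range = c(80L, 300L), ...)
}

test_that("generation is reproducible under a seed and changes with it", {
  a <- generate_proteome(small_config(seed = 5))
  b <- generate_proteome(small_config(seed = 5))
  expect_identical(a$records, b$records)
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$features, b$features)
  c <- generate_proteome(small_config(seed = 6))
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("injected motifs and calcium features are recovered by the scanners", {
  patterns <- read_motif_file(default_motif_file())
  sim <- generate_proteome(small_config(seed = 9), patterns)
  prof <- profile_proteins(sim$records, sim$features, patterns)
  idx <- match(sim$truth$protein_id, prof$protein_id)
  # every injected motif instance must be matched (chance hits may add more)
  expect_true(all(prof$n_ox_motifs[idx] >= sim$truth$injected_ox_motifs))
  expect_true(all(prof$n_ca_sites[idx] == sim$truth$injected_ca_sites))
})

test_that("a single-residue composition yields the expected homopolymers", {
  bg <- setNames(c(1, rep(0, 19)), names(residue_background()))
  cfg <- small_config(seed = 3, background = bg, ox_protein_prob = 0,
                      ca_protein_prob = 0)
  sim <- generate_proteome(cfg)
  expect_true(all(grepl("^A+$", sim$records$sequence)))
})

test_that("generated files are accepted by every ingest reader", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 13)
  sim <- simulate_study(cfg, dir = dir)
  rec <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(rec$protein_id, sim$records$protein_id)
  expect_equal(rec$sequence, sim$records$sequence)
  tab <- read_abundance_table(file.path(dir, "abundance.tsv"))
  expect_equal(nrow(tab), nrow(sim$table))
  fs <- read_uniprot_features(file.path(dir, "features.txt"))
  expect_setequal(names(Filter(function(d) nrow(d) > 0, fs)),
                  names(sim$features))
  ro <- read_assay_table(file.path(dir, "assays.tsv"))
  expect_equal(nrow(ro), nrow(sim$readouts))
})

test_that("noiseless full-strength links reproduce the descriptor rank order", {
  links <- data.frame(property = "mw_da", assay = "aggregation", strength = 1)
  cfg <- small_config(seed = 17, planted_links = links, noise_sd = 0)
  sim <- simulate_study(cfg)
  tab <- normalize_abundance(sim$table)
  awm <- vapply(cfg$fraction_ids, function(f) {
    sel <- tab$fraction_id == f
    sum(tab$weight[sel] * sim$profiles$mw_da[match(tab$protein_id[sel],
                                                   sim$profiles$protein_id)])
  }, numeric(1))
  act <- sim$true_activity[cfg$fraction_ids, "aggregation"]
  expect_equal(order(act), order(awm))
  # measured panel reproduces the true activities exactly at zero noise
  panel <- activity_panel(sim$readouts)
  agg <- panel[panel$assay == "aggregation", ]
  expect_equal(agg$activity_pct[match(cfg$fraction_ids, agg$fraction_id)],
               unname(act), tolerance = 1e-9)
})

test_that("planted-link validation rejects unknown names", {
  links <- data.frame(property = "mw_da", assay = "dissolution", strength = 1)
  cfg <- small_config(seed = 1, planted_links = links)
  pro <- generate_proteome(cfg)
  expect_error(generate_assays(cfg, pro), "unknown assay")
  links2 <- data.frame(property = "not_a_column", assay = "growth",
                       strength = 1)
  cfg2 <- small_config(seed = 1, planted_links = links2)
  expect_error(generate_assays(cfg2, pro), "unknown descriptor")
})

test_that("default configuration mirrors the study dimensions", {
  cfg <- simulation_config()
  expect_equal(cfg$proteins_per_fraction,
               c(10L, 12L, 71L, 71L, 60L, 55L, 25L, 38L, 6L))
  expect_equal(sum(cfg$proteins_per_fraction), 348L)
  expect_equal(cfg$fraction_ids, paste0("SFQ", 1:9))
  expect_equal(cfg$replicate_count, 3L)
})
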