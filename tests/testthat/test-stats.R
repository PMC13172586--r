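make_table <- function(protein_id, fraction_id, intensity) {
  structure(data.frame(protein_id = protein_id, fraction_id = fraction_id,
                       intensity = intensity, weight = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("fraction_table", "data.frame"))
}

test_that("normalize_abundance yields within-fraction weights summing to 1", {
  tab <- make_table(c("a", "b", "c", "d"), c("F1", "F1", "F1", "F2"),
                    c(2, 3, 5, 7))
  norm <- normalize_abundance(tab)
  expect_equal(norm$weight[1:3], c(0.2, 0.3, 0.5))
  expect_equal(norm$weight[4], 1)
  sums <- tapply(norm$weight, norm$fraction_id, sum)
  expect_equal(unname(as.numeric(sums)), c(1, 1), tolerance = 1e-9)
  zero <- make_table("a", "F1", 0)
  expect_error(normalize_abundance(zero), "zero total")
})

test_that("spearman is Pearson on midranks with a t-approximate p", {
  expect_equal(spearman(c(1, 2, 3), c(2, 4, 6))$rs, 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$rs, -1)
  # hand mid-rank oracle for the tied example
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  expect_equal(spearman(x, y)$rs, cor(rx, ry), tolerance = 1e-12)
  # constant input is flagged, not an error
  flagged <- spearman(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(flagged$rs) && is.na(flagged$p))
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    base <- spearman(x, y)$rs
    expect_equal(spearman(exp(x), y)$rs, base, tolerance = 1e-12)
    expect_equal(spearman(x, y^3 + 5 * y)$rs, base, tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with the classical exact test", {
  set.seed(32)
  for (i in 1:5) {
    x <- sample(1:7); y <- sample(1:7)  # untied
    mine <- spearman(x, y, exact = TRUE)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(mine$rs, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, min(1, ref$p.value), tolerance = 1e-9)
  }
  expect_error(spearman(rnorm(10), rnorm(10), exact = TRUE), "n <= 9")
})

test_that("Benjamini-Hochberg matches hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(benjamini_hochberg(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("BH output dominates input, is capped, and preserves order", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(30, min = 1e-6)
    adj <- benjamini_hochberg(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("weighted entries carry weight-scaled properties and activities", {
  tab <- make_table(c("a", "b"), c("F1", "F1"), c(1, 1))
  prof <- data.frame(protein_id = c("a", "b"), length = c(10, 10),
                     mw_da = c(1e5, 2e5), pi = c(7, 7), gravy = c(-1, 1),
                     instability_index = c(30, 50),
                     frac_aromatic = 0.1, frac_polar = 0.3,
                     frac_nonpolar = 0.4, frac_positive = 0.2,
                     frac_negative = 0.1, n_ca_sites = c(0L, 2L),
                     n_ox_motifs = c(1L, 1L), ss_helix = 0.25,
                     ss_strand = 0.25, ss_turn = 0.25, ss_coil = 0.25)
  panel <- data.frame(fraction_id = "F1", assay = "aggregation",
                      activity_pct = 200, sem_pct = 1, n_replicates = 3L)
  entries <- build_weighted_entries(tab, prof, panel)
  expect_equal(nrow(entries), 2L)
  expect_equal(entries$aw_mw, c(0.5e5, 1e5))
  expect_equal(entries$aw_aggregation, c(100, 100))
  # missing profile and missing panel produce informative errors
  expect_error(build_weighted_entries(make_table("z", "F1", 1), prof, panel),
               "no profile for protein")
  tab2 <- make_table("a", "F9", 1)
  expect_error(build_weighted_entries(tab2, prof, panel),
               "no activity panel for fraction")
})

test_that("correlation screen flags a monotone construction and spares shuffled noise", {
  set.seed(34)
  n_per <- rep(12L, 5L)
  fr <- paste0("F", seq_along(n_per))
  fraction_of <- rep(fr, n_per)
  ids <- sprintf("p%03d", seq_len(sum(n_per)))
  # equal intensities: every weight is 1/12, so weight-scaling is a no-op
  tab <- make_table(ids, fraction_of, rep(1, sum(n_per)))
  # MW strictly increasing with fraction index (disjoint blocks)
  mw <- 1e5 * rep(seq_along(n_per), n_per) + seq_len(sum(n_per))
  prof <- data.frame(protein_id = ids, length = 100, mw_da = mw,
                     pi = 7, gravy = rnorm(sum(n_per), -0.4, 0.1),
                     instability_index = runif(sum(n_per), 20, 60),
                     frac_aromatic = 0.08, frac_polar = 0.3,
                     frac_nonpolar = 0.42, frac_positive = 0.12,
                     frac_negative = 0.16, n_ca_sites = 0L,
                     n_ox_motifs = rpois(sum(n_per), 4),
                     ss_helix = 0.25, ss_strand = 0.25, ss_turn = 0.25,
                     ss_coil = 0.25)
  tab <- normalize_abundance(tab)
  # activity strictly increasing in the fraction's weighted MW mean
  panel <- data.frame(fraction_id = fr, assay = "aggregation",
                      activity_pct = 100 + 10 * seq_along(fr), sem_pct = 1,
                      n_replicates = 3L)
  scr <- correlation_screen(tab, prof, panel)
  cell <- scr[scr$property == "mw" & scr$activity == "aggregation", ]
  expect_gt(cell$rs, 0.8)
  expect_true(cell$significant)
  expect_equal(sort(unique(scr$level)), c("fraction", "protein"))
  expect_equal(nrow(scr), 22L)  # one assay supplied -> 22 cells
  # constant aw descriptors (equal weights x constant composition) are
  # flagged NA, excluded from the family, never significant
  const_cells <- scr[scr$property %in% c("aromatic_pct", "polar_pct"), ]
  expect_true(all(is.na(const_cells$rs)))
  expect_true(all(!const_cells$significant))
})

test_that("fraction summaries report means, SEM and threshold splits", {
  prof <- data.frame(protein_id = c("a", "b", "c", "d"),
                     length = 100,
                     mw_da = c(4e4, 6e4, 3e4, 8e4), pi = c(5, 6, 7, 8),
                     gravy = c(-1, -1, -1, 1),
                     instability_index = c(30, 50, 45, 60),
                     frac_aromatic = 0.1, frac_polar = 0.25,
                     frac_nonpolar = 0.45, frac_positive = 0.15,
                     frac_negative = 0.15,
                     n_ca_sites = c(0L, 1L, 0L, 3L),
                     n_ox_motifs = c(2L, 0L, 1L, 1L),
                     ss_helix = 0.25, ss_strand = 0.25, ss_turn = 0.25,
                     ss_coil = 0.25)
  mem <- data.frame(protein_id = c("a", "b", "c", "d"),
                    fraction_id = c("F1", "F1", "F1", "F1"))
  s <- summarize_fractions(prof, mem)
  expect_equal(s$pct_low_mw, 50)
  expect_equal(s$pct_high_mw, 50)
  expect_equal(s$pct_hydrophilic, 75)
  expect_equal(s$pct_unstable, 75)
  expect_equal(s$pct_ca_binding, 50)
  expect_equal(s$pct_ox_binding, 75)
  expect_equal(s$mean_mw_da, mean(prof$mw_da))
  expect_equal(s$sem_mw_da, sd(prof$mw_da) / 2)
  # single-protein fraction: SEM is flagged undefined
  s1 <- summarize_fractions(prof, mem[1, ])
  expect_true(is.na(s1$sem_mw_da))
  expect_error(summarize_fractions(prof,
                                   data.frame(protein_id = "zz",
                                              fraction_id = "F1")),
               "no profile")
})
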