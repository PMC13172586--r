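test_that("molecular weight matches hand sums and is additive", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 1e-4)
  expect_equal(compute_mw("GG"), 132.12, tolerance = 1e-4)
  # additivity: mw(s1 + s2) = mw(s1) + mw(s2) - water
  set.seed(1)
  for (i in 1:10) {
    s1 <- random_seq(sample(1:30, 1), stonescreen:::AA_STANDARD)
    s2 <- random_seq(sample(1:30, 1), stonescreen:::AA_STANDARD)
    expect_equal(compute_mw(paste0(s1, s2)),
                 compute_mw(s1) + compute_mw(s2) - 18.01524,
                 tolerance = 1e-9)
  }
  expect_error(compute_mw(""), "non-empty")
  expect_error(compute_mw("MXV"), "non-standard residue")
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy and order-invariant", {
  expect_equal(compute_gravy("AAAA"), 1.8)
  expect_equal(compute_gravy("RRRR"), -4.5)
  expect_equal(compute_gravy("AR"), -1.35)
  set.seed(2)
  s <- random_seq(50, stonescreen:::AA_STANDARD)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(compute_gravy(s), compute_gravy(perm))
})

test_that("instability index matches the published dipeptide formula", {
  expect_equal(compute_instability("AA"), 5.0)
  expect_equal(compute_instability("AAAA"), 7.5)  # (10/4) * 3 * DIWV(A,A)
  expect_error(compute_instability("A"), "length >= 2")
  # values cross-checked against an independent ProtParam implementation
  expect_equal(compute_instability("MFPCDVENWCTHCDQQDIDVQCWEIWCWWP"),
               66.3567, tolerance = 1e-4)
  expect_equal(compute_instability("RWRNLIGIDWLTSMRLYDETQGMFSQCDVW"),
               47.35, tolerance = 1e-4)
  # order sensitivity: a permutation generally changes the index
  expect_false(isTRUE(all.equal(compute_instability("ADCA"),
                                compute_instability("ACDA"))))
})

test_that("theoretical pI has the two-group closed form and tracks the grid oracle", {
  pka <- pka_bjellqvist()
  pk <- setNames(pka$pka, pka$group)
  expect_equal(compute_pi("A"), (pk[["Nterm_A"]] + pk[["Cterm"]]) / 2,
               tolerance = 1e-3)
  expect_equal(compute_pi("AAAA"), compute_pi("A"), tolerance = 1e-3)
  expect_lt(compute_pi(strrep("D", 20)), 4)
})

test_that("composition fractions partition the sequence", {
  expect_equal(unname(compute_composition("DDEE")["frac_negative"]), 1.0)
  expect_equal(unname(compute_composition("KRKR")["frac_positive"]), 1.0)
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(80, stonescreen:::AA_STANDARD)
    comp <- compute_composition(s)
    expect_equal(unname(sum(comp[c("frac_polar", "frac_nonpolar",
                                   "frac_positive", "frac_negative")])), 1,
                 tolerance = 1e-9)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(compute_composition(s), compute_composition(perm))
  }
  expect_error(class_scheme(polar = c("S")), "disjoint cover")
})

test_that("threshold classifications follow the >= boundary convention", {
  expect_equal(classify_mw(c(49999, 50000, 50001)), c("low", "high", "high"))
  expect_equal(classify_stability(c(39.9, 40, 40.1)),
               c("stable", "unstable", "unstable"))
  expect_equal(classify_hydropathy(c(-0.37, 0, 0.1)),
               c("hydrophilic", "hydrophobic", "hydrophobic"))
  # negative indices occur (the dipeptide table has negative weights) and
  # fall on the stable side of the 40 threshold
  expect_equal(classify_stability(-10), "stable")
  expect_error(classify_stability(NA_real_), "finite")
})
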