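test_that("read_fasta parses headers, uppercases, and applies residue policies", {
  path <- fixture_fasta(list("p1 some description" = "MKV", "p2" = "adr"))
  rec <- read_fasta(path)
  expect_equal(rec$protein_id, c("p1", "p2"))
  expect_equal(rec$sequence, c("MKV", "ADR"))
  expect_equal(rec$description[1], "some description")

  path2 <- fixture_fasta(list(p1 = "MXV"))
  expect_error(read_fasta(path2), "non-standard residue 'X' at position 2")
  expect_message(rec2 <- read_fasta(path2, unknown_policy = "skip_residue"),
                 "1 non-standard residue")
  expect_equal(rec2$sequence, "MV")

  path3 <- fixture_fasta(list("p1 a" = "MK", "p1 b" = "MR"))
  expect_error(read_fasta(path3), "duplicate id p1")
})

test_that("skip_residue output contains only the 20 standard residues", {
  path <- fixture_fasta(list(p1 = "MBVJXZOUAK"))
  rec <- suppressMessages(read_fasta(path, unknown_policy = "skip_residue"))
  expect_equal(rec$sequence, "MVAK")
  expect_true(all(strsplit(rec$sequence, "")[[1]] %in% stonescreen:::AA_STANDARD))
})

test_that("abundance table reader handles wide and long layouts and zero omission", {
  dir <- withr::local_tempdir()
  wide <- file.path(dir, "wide.tsv")
  writeLines(c("protein_id\tSFQ1\tSFQ2", "p1\t2\t0", "p2\t1\t3"), wide)
  t1 <- read_abundance_table(wide)
  expect_equal(nrow(t1), 3L)  # p1/SFQ2 omitted
  expect_equal(attr(t1, "fraction_ids"), c("SFQ1", "SFQ2"))
  expect_false(any(t1$protein_id == "p1" & t1$fraction_id == "SFQ2"))

  long <- file.path(dir, "long.tsv")
  writeLines(c("protein_id\tfraction_id\tintensity",
               "p1\tSFQ1\t2", "p2\tSFQ1\t3"), long)
  t2 <- read_abundance_table(long)
  expect_equal(nrow(t2), 2L)
  expect_equal(t2$intensity, c(2, 3))

  neg <- file.path(dir, "neg.tsv")
  writeLines(c("protein_id\tSFQ1", "p1\t-5"), neg)
  expect_error(read_abundance_table(neg), "negative intensity")
})

test_that("wide layout honors an intensity-column prefix", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mq.tsv")
  writeLines(c("Protein IDs\tiBAQ SFQ1\tiBAQ SFQ2\tPeptides",
               "p1\t4\t6\t12"), path)
  t1 <- read_abundance_table(path, intensity_column = "iBAQ")
  expect_equal(sort(t1$fraction_id), c("SFQ1", "SFQ2"))
  expect_equal(t1$intensity[t1$fraction_id == "SFQ2"], 6)
})

test_that("fraction and assay tables round-trip through their writers", {
  dir <- withr::local_tempdir()
  tab <- structure(data.frame(protein_id = c("a", "b"),
                              fraction_id = c("F1", "F1"),
                              intensity = c(1.25, 3.5), weight = NA_real_),
                   class = c("fraction_table", "data.frame"))
  p <- write_abundance_table(tab, file.path(dir, "t.tsv"))
  back <- read_abundance_table(p)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$intensity, tab$intensity)

  ro <- fixture_readouts()
  p2 <- write_assay_table(ro, file.path(dir, "a.tsv"))
  back2 <- read_assay_table(p2)
  expect_equal(back2$metric_value, ro$metric_value)
  expect_equal(back2$fraction_id, ro$fraction_id)
})

test_that("assay reader validates enums, duplicates and domains", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  ro <- fixture_readouts()
  ro$assay[1] <- "dissolution"
  write.table(ro, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_assay_table(path), "unknown assay")

  ro <- fixture_readouts()
  ro$replicate[2] <- 1L
  expect_error(validate_assay_readouts(ro), "duplicate replicate")

  ro <- fixture_readouts()
  ro$metric_value[1] <- -1
  expect_error(validate_assay_readouts(ro), "nonnegative")
})

test_that("UniProt flat-text reader captures BINDING, DOMAIN and CA_BIND", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "up.txt")
  writeLines(c(
    "ID   FBN1_TEST            Reviewed;         120 AA.",
    "AC   P00001; P99999;",
    "FT   BINDING         10",
    'FT                   /ligand="Ca(2+)"',
    "FT   BINDING         30..32",
    'FT                   /ligand="Zn(2+)"',
    "FT   DOMAIN          5..40",
    'FT                   /note="EGF-like 1; calcium-binding"',
    "FT   CA_BIND         50..60",
    "FT   HELIX           70..80",
    "//",
    "ID   EMPTY_TEST           Reviewed;          10 AA.",
    "AC   P00002;",
    "//"), path)
  fs <- read_uniprot_features(path)
  expect_named(fs, c("P00001", "P00002"))
  f1 <- fs[["P00001"]]
  expect_equal(nrow(f1), 4L)  # HELIX ignored
  expect_equal(f1$label[f1$kind == "BINDING" & f1$start == 10], "Ca(2+)")
  expect_equal(f1$label[f1$kind == "DOMAIN"], "EGF-like 1; calcium-binding")
  expect_equal(nrow(fs[["P00002"]]), 0L)
})

test_that("malformed UniProt locations are rejected with a line number", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.txt")
  writeLines(c("ID   X_TEST", "AC   P1;",
               "FT   BINDING         ten", "//"), path)
  expect_error(read_uniprot_features(path), "line 3")
})

test_that("motif files parse and malformed patterns fail at load", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  writeLines(c("# comment", "oxm1\tK-x(2)-R"), path)
  pats <- read_motif_file(path)
  expect_named(pats, "oxm1")
  expect_s3_class(pats$oxm1, "prosite_pattern")

  writeLines("bad\tK-x(", path)
  expect_error(read_motif_file(path), "unparseable PROSITE element")
})
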