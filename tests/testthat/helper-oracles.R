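# Independent oracles and fixture builders shared across the test files.

# Brute-force instability index: explicit loop over dipeptides with direct
# table lookup (no vectorized indexing).
oracle_instability <- function(sequence) {
  chars <- strsplit(sequence, "")[[1L]]
  w <- diwv_weights()
  total <- 0
  for (i in seq_len(length(chars) - 1L)) {
    total <- total + w[chars[i], chars[i + 1L]]
  }
  10 / length(chars) * total
}

# Dense-grid charge scan: net charge evaluated at 0.001-pH steps; the pI is
# the midpoint of the step where the charge changes sign.
oracle_pi_grid <- function(sequence, step = 0.001) {
  chars <- strsplit(sequence, "")[[1L]]
  pka <- pka_bjellqvist()
  pk <- setNames(pka$pka, pka$group)
  sgn <- setNames(pka$sign, pka$group)
  nt <- paste0("Nterm_", chars[1L])
  ct <- paste0("Cterm_", chars[length(chars)])
  groups <- rbind(
    data.frame(pka = pk[[if (nt %in% names(pk)) nt else "Nterm"]], pos = TRUE),
    data.frame(pka = pk[[if (ct %in% names(pk)) ct else "Cterm"]], pos = FALSE),
    do.call(rbind, lapply(c("K", "R", "H", "D", "E", "C", "Y"), function(a) {
      k <- sum(chars == a)
      if (!k) return(NULL)
      data.frame(pka = rep(pk[[a]], k), pos = sgn[[a]] == "positive")
    })))
  charge <- function(ph) {
    sum(1 / (1 + 10^(ph - groups$pka[groups$pos]))) -
      sum(1 / (1 + 10^(groups$pka[!groups$pos] - ph)))
  }
  grid <- seq(0, 14, by = step)
  q <- vapply(grid, charge, numeric(1L))
  i <- which(q[-length(q)] > 0 & q[-1L] <= 0)[1L]
  (grid[i] + grid[i + 1L]) / 2
}

# Recursive PROSITE matcher: for a start position, the smallest end such that
# the whole pattern is satisfied (exploring repeat lengths shortest-first),
# or NA. Independent of the regex-based scanner.
oracle_match_end <- function(elements, chars, pos) {
  if (!length(elements)) return(pos - 1L)
  el <- elements[[1L]]
  for (len in el$min:el$max) {
    last <- pos + len - 1L
    if (last > length(chars)) return(NA_integer_)
    if (all(chars[pos:last] %in% el$allowed)) {
      res <- oracle_match_end(elements[-1L], chars, last + 1L)
      if (!is.na(res)) return(res)
    }
  }
  NA_integer_
}

oracle_scan <- function(sequence, pp) {
  chars <- strsplit(sequence, "")[[1L]]
  hits <- NULL
  for (s in seq_along(chars)) {
    e <- oracle_match_end(pp$elements, chars, s)
    if (!is.na(e)) hits <- rbind(hits, data.frame(start = s, end = e))
  }
  hits
}

# Random sequence over an alphabet.
random_seq <- function(n, alphabet = c("A", "K", "R", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All sequences of length 1..max_len over an alphabet.
all_seqs <- function(alphabet, max_len) {
  out <- character()
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

# Write a FASTA fixture and return its path.
fixture_fasta <- function(entries, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.fasta")
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}

# A small assay readout table with known activities.
fixture_readouts <- function() {
  rbind(
    data.frame(assay = "aggregation", condition = "negative_control",
               fraction_id = "", replicate = 1:3,
               metric_value = c(100, 110, 120)),
    data.frame(assay = "aggregation", condition = "blank",
               fraction_id = "", replicate = 1:3,
               metric_value = c(90, 100, 110)),
    data.frame(assay = "aggregation", condition = "fraction",
               fraction_id = "F1", replicate = 1:3,
               metric_value = c(150, 150, 150)),
    data.frame(assay = "aggregation", condition = "fraction",
               fraction_id = "F2", replicate = 1:3,
               metric_value = c(99, 110, 121)))
}
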