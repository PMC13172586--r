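# Seeded synthetic study generator: protein sequences, UniProt-style feature
# fixtures, abundances, and assay readouts with planted monotone links
# between abundance-weighted properties and activities.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design the pipeline targets: 9 fractions with
#' 10, 12, 71, 71, 60, 55, 25, 38 and 6 proteins (348 protein-in-fraction
#' entries), sequence lengths 80-7000 residues, log-normal within-fraction
#' abundances, 3 replicate readouts per assay condition, and activity ranges
#' per assay matching the observed spans (crystallization may be inhibitory;
#' aggregation is strongly promoting). Planted links make a fraction's true
#' activity a strictly increasing function of the fraction's
#' abundance-weighted mean of the chosen descriptor.
#'
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce identical datasets.
#' @param proteins_per_fraction Integer vector, proteins per fraction.
#' @param fraction_ids Fraction names (default SFQ1..SFQn).
#' @param length_range Sequence length interval (residues).
#' @param abundance_meanlog,abundance_sdlog Log-normal intensity parameters.
#'   The default sdlog 2 spans roughly 3-4 orders of magnitude within a
#'   fraction, as in MS relative-abundance tables.
#' @param planted_links data.frame with columns `property` (a profile column
#'   name, e.g. `"mw_da"`), `assay`, `strength` in \[0, 1\]. Empty (NULL) for
#'   a null dataset.
#' @param noise_sd Replicate noise, as a coefficient of variation of the
#'   readout (default 0.03).
#' @param replicate_count Replicates per condition (default 3).
#' @param ca_protein_prob Probability a protein receives injected calcium
#'   BINDING features (default 0.2).
#' @param ox_protein_prob Probability a protein receives injected
#'   oxalate-motif instances (default 0.9).
#' @param ca_sites_mean,ox_motifs_mean Mean injected site/motif counts among
#'   carriers (1 + Poisson).
#' @param background Residue sampling frequencies (default
#'   [residue_background()]).
#' @param activity_ranges Named list, per assay, of the `c(lo, hi)` span of
#'   true fraction activities (percent).
#' @param baselines Named vector of reference-condition readout levels per
#'   assay (counts per field or micrometres).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              proteins_per_fraction = c(10L, 12L, 71L, 71L, 60L, 55L, 25L, 38L, 6L),
                              fraction_ids = paste0("SFQ", seq_along(proteins_per_fraction)),
                              length_range = c(80L, 7000L),
                              abundance_meanlog = log(1e7),
                              abundance_sdlog = 2,
                              planted_links = NULL,
                              noise_sd = 0.03,
                              replicate_count = 3L,
                              ca_protein_prob = 0.2,
                              ox_protein_prob = 0.9,
                              ca_sites_mean = 3,
                              ox_motifs_mean = 4.5,
                              background = residue_background(),
                              activity_ranges = list(
                                crystallization = c(-18, 23),
                                growth = c(-10, 65),
                                aggregation = c(178, 320),
                                adhesion = c(45, 57)),
                              baselines = c(crystallization = 100,
                                            growth = 25,
                                            aggregation = 30,
                                            adhesion = 50)) {
  stopifnot(all(proteins_per_fraction >= 1L),
            length(fraction_ids) == length(proteins_per_fraction),
            length(length_range) == 2L, length_range[1L] >= 10L,
            length_range[1L] <= length_range[2L],
            noise_sd >= 0, replicate_count >= 1L)
  if (!is.null(planted_links)) {
    stopifnot(is.data.frame(planted_links),
              all(c("property", "assay", "strength") %in% names(planted_links)),
              all(planted_links$strength >= 0 & planted_links$strength <= 1))
  }
  structure(list(seed = as.integer(seed),
                 proteins_per_fraction = as.integer(proteins_per_fraction),
                 fraction_ids = fraction_ids,
                 length_range = as.integer(length_range),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 planted_links = planted_links,
                 noise_sd = noise_sd,
                 replicate_count = as.integer(replicate_count),
                 ca_protein_prob = ca_protein_prob,
                 ox_protein_prob = ox_protein_prob,
                 ca_sites_mean = ca_sites_mean,
                 ox_motifs_mean = ox_motifs_mean,
                 background = background,
                 activity_ranges = activity_ranges,
                 baselines = baselines),
            class = "sim_config")
}

# A concrete residue string satisfying a parsed PROSITE pattern (minimal
# repeat counts; first allowed residue of each element).
.motif_instance <- function(pp) {
  paste(vapply(pp$elements, function(el) {
    strrep(el$allowed[1L], el$min)
  }, character(1L)), collapse = "")
}

#' Generate a synthetic proteome
#'
#' Draws residue-wise sequences from the background composition, assigns
#' log-normal abundances, injects oxalate-motif-matching substrings into a
#' configurable share of proteins, and assigns calcium BINDING features
#' (ligand `Ca(2+)`) to another share. Reproducible under the config seed.
#'
#' @param config A [simulation_config()].
#' @param patterns Named list of parsed motif patterns whose instances are
#'   injected (default: the shipped synthetic motif file).
#' @return List with `records` (as [read_fasta()]), `features` (named list as
#'   [read_uniprot_features()]), `table` (a `fraction_table`, weights unset),
#'   and `truth` (per-protein injected counts).
#' @export
generate_proteome <- function(config, patterns = read_motif_file(default_motif_file())) {
  set.seed(config$seed)
  n_total <- sum(config$proteins_per_fraction)
  ids <- sprintf("SYN%04d", seq_len(n_total))
  fraction_of <- rep(config$fraction_ids, config$proteins_per_fraction)
  lens <- sample(config$length_range[1L]:config$length_range[2L],
                 n_total, replace = TRUE)
  instances <- vapply(patterns, .motif_instance, character(1L))
  if (any(nchar(instances) > config$length_range[1L])) {
    stop("motif instance longer than the minimum sequence length")
  }
  inj_ox <- integer(n_total)
  inj_ca <- integer(n_total)
  features <- vector("list", n_total)
  names(features) <- ids
  aa <- names(config$background)
  # residues for all proteins drawn in one pass, then sliced per protein
  big <- paste(sample(aa, sum(lens), replace = TRUE, prob = config$background),
               collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1L, ends)
  slot_w <- max(nchar(instances))
  for (i in seq_len(n_total)) {
    # oxalate motif injection: replace disjoint stretches with literal
    # instances of randomly chosen patterns
    if (stats::runif(1) < config$ox_protein_prob) {
      k <- 1L + stats::rpois(1L, max(config$ox_motifs_mean - 1, 0))
      n_slots <- lens[i] %/% slot_w
      k <- min(k, n_slots)
      slots <- sample(n_slots, k)
      for (s in slots) {
        inst <- instances[[sample(length(instances), 1L)]]
        at <- (s - 1L) * slot_w + 1L
        substr(seqs[i], at, at + nchar(inst) - 1L) <- inst
      }
      inj_ox[i] <- k
    }
    # calcium BINDING features at random residues
    if (stats::runif(1) < config$ca_protein_prob) {
      k <- 1L + stats::rpois(1L, max(config$ca_sites_mean - 1, 0))
      pos <- sort(sample(lens[i], k))
      features[[i]] <- data.frame(protein_id = ids[i], kind = "BINDING",
                                  start = pos, end = pos,
                                  label = "Ca(2+)", stringsAsFactors = FALSE)
      inj_ca[i] <- k
    }
  }
  intens <- stats::rlnorm(n_total, config$abundance_meanlog,
                          config$abundance_sdlog)
  table <- structure(
    data.frame(protein_id = ids, fraction_id = fraction_of,
               intensity = intens, weight = NA_real_,
               stringsAsFactors = FALSE),
    fraction_ids = config$fraction_ids,
    class = c("fraction_table", "data.frame"))
  records <- data.frame(protein_id = ids, sequence = seqs,
                        description = paste0("synthetic protein in ", fraction_of),
                        stringsAsFactors = FALSE)
  list(records = records, features = Filter(Negate(is.null), features),
       table = table,
       truth = data.frame(protein_id = ids, fraction_id = fraction_of,
                          injected_ox_motifs = inj_ox,
                          injected_ca_sites = inj_ca,
                          stringsAsFactors = FALSE))
}

#' Generate synthetic assay readouts
#'
#' For each planted link, the fraction-level true activity is a strictly
#' increasing function (min-max scaled rank position) of the fraction's
#' abundance-weighted descriptor mean, mixed with an independent uniform
#' component in proportion `1 - strength`, mapped onto the assay's activity
#' range. Unplanted assays get activities drawn independently of the
#' descriptors. Replicate readouts are the implied metric level times
#' log-normal-free Gaussian noise (`noise_sd` CV); negative-control and blank
#' replicates are generated around the configured baselines.
#'
#' @param config A [simulation_config()].
#' @param proteome Result of [generate_proteome()].
#' @param profiles Optional precomputed profile table (computed on the fly
#'   when NULL and a planted link needs descriptor values).
#' @return List with `readouts` (as [read_assay_table()]) and
#'   `true_activity` (fraction x assay true activity percentages).
#' @export
generate_assays <- function(config, proteome, profiles = NULL) {
  set.seed(config$seed + 1L)
  fractions <- config$fraction_ids
  nf <- length(fractions)
  links <- config$planted_links
  if (!is.null(links) && nrow(links)) {
    bad <- setdiff(links$assay, .assay_levels)
    if (length(bad)) stop("unknown assay in planted_links: ", bad[1L])
    if (is.null(profiles)) {
      profiles <- profile_proteins(proteome$records, proteome$features,
                                   patterns = read_motif_file(default_motif_file()))
    }
    bad_p <- setdiff(links$property, names(profiles))
    if (length(bad_p)) stop("unknown descriptor in planted_links: ", bad_p[1L])
  }
  table <- normalize_abundance(proteome$table)
  aw_mean <- function(column) {
    vapply(fractions, function(f) {
      sel <- table$fraction_id == f
      sum(table$weight[sel] *
            profiles[[column]][match(table$protein_id[sel], profiles$protein_id)])
    }, numeric(1L))
  }
  minmax <- function(v) {
    if (max(v) == min(v)) return(rep(0.5, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  true_act <- matrix(NA_real_, nrow = nf, ncol = length(.assay_levels),
                     dimnames = list(fractions, .assay_levels))
  for (a in .assay_levels) {
    rng <- config$activity_ranges[[a]]
    u <- stats::runif(nf)
    link <- if (!is.null(links)) links[links$assay == a, , drop = FALSE] else NULL
    if (!is.null(link) && nrow(link)) {
      g <- minmax(aw_mean(link$property[1L]))
      s <- link$strength[1L]
      v <- s * g + (1 - s) * u
    } else {
      v <- u
    }
    true_act[, a] <- rng[1L] + (rng[2L] - rng[1L]) * v
  }
  reps <- seq_len(config$replicate_count)
  rows <- list()
  for (a in .assay_levels) {
    base <- config$baselines[[a]]
    noise <- function(k) 1 + stats::rnorm(k, 0, config$noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      assay = a, condition = "negative_control", fraction_id = "",
      replicate = reps, metric_value = base * noise(length(reps)),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      assay = a, condition = "blank", fraction_id = "",
      replicate = reps, metric_value = 0.85 * base * noise(length(reps)),
      stringsAsFactors = FALSE)
    for (f in fractions) {
      level <- base * (1 + true_act[f, a] / 100)
      rows[[length(rows) + 1L]] <- data.frame(
        assay = a, condition = "fraction", fraction_id = f,
        replicate = reps, metric_value = pmax(level * noise(length(reps)), 0),
        stringsAsFactors = FALSE)
    }
  }
  readouts <- do.call(rbind, rows)
  list(readouts = validate_assay_readouts(readouts),
       true_activity = true_act)
}

#' Generate a complete synthetic study (proteome + assays)
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: when given, writes `proteins.fasta`,
#'   `features.txt` (UniProt-style flat text, synthetic), `abundance.tsv` and
#'   `assays.tsv` in the formats the ingest readers consume.
#' @return List combining [generate_proteome()] and [generate_assays()]
#'   output (`records`, `features`, `table`, `truth`, `readouts`,
#'   `true_activity`, `profiles`).
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL) {
  patterns <- read_motif_file(default_motif_file())
  proteome <- generate_proteome(config, patterns)
  profiles <- profile_proteins(proteome$records, proteome$features, patterns)
  assays <- generate_assays(config, proteome, profiles)
  out <- c(proteome, assays, list(profiles = profiles))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    aa <- Biostrings::AAStringSet(stats::setNames(proteome$records$sequence,
                                                  proteome$records$protein_id))
    Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"), width = 60L)
    .write_uniprot_fixture(proteome$features, proteome$records,
                           file.path(dir, "features.txt"))
    write_abundance_table(proteome$table, file.path(dir, "abundance.tsv"))
    write_assay_table(assays$readouts, file.path(dir, "assays.tsv"))
  }
  out
}

#' Monte-Carlo parameter-recovery study of the correlation screen
#'
#' Runs `n_reps` seeded replicates of the full synthetic pipeline. Each
#' replicate generates a proteome and profiles it once, then produces two
#' independent assay datasets from it: one with the configured planted links
#' and one null dataset (no links), and screens both. Reported are, per
#' replicate, whether each planted cell was flagged significant, and, per
#' screen cell, how often it was flagged in the null replicates.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r` for its proteome and
#'   planted assays and an offset seed for its null assays.
#' @param planted_links data.frame as in [simulation_config()].
#' @param config Base [simulation_config()] (its seed and planted links are
#'   overridden per replicate).
#' @return List: `planted_flagged` (n_reps x planted-links logical matrix),
#'   `planted_rs` (same shape, observed rs), `null_flag_count` (screen-cell
#'   data.frame with `n_flagged` over the null replicates), `n_reps`.
#' @export
simulate_recovery <- function(n_reps = 200L, seed = 1L,
                              planted_links = data.frame(
                                property = "mw_da", assay = "aggregation",
                                strength = 0.9),
                              config = simulation_config()) {
  patterns <- read_motif_file(default_motif_file())
  nl <- nrow(planted_links)
  planted_flagged <- matrix(NA, n_reps, nl)
  planted_rs <- matrix(NA_real_, n_reps, nl)
  prop_key <- .screen_property_key(planted_links$property)
  null_count <- NULL
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    cfg$planted_links <- planted_links
    proteome <- generate_proteome(cfg, patterns)
    profiles <- profile_proteins(proteome$records, proteome$features, patterns)
    table <- normalize_abundance(proteome$table)
    planted <- generate_assays(cfg, proteome, profiles)
    scr <- correlation_screen(table, profiles,
                              activity_panel(planted$readouts))
    for (j in seq_len(nl)) {
      cell <- scr[scr$property == prop_key[j] &
                    scr$activity == planted_links$assay[j], ]
      planted_flagged[r, j] <- cell$significant
      planted_rs[r, j] <- cell$rs
    }
    cfg_null <- cfg
    cfg_null$seed <- as.integer(seed + r + 500000L)
    cfg_null$planted_links <- NULL
    null <- generate_assays(cfg_null, proteome, profiles)
    scr0 <- correlation_screen(table, profiles,
                               activity_panel(null$readouts))
    if (is.null(null_count)) {
      null_count <- scr0[, c("property", "activity")]
      null_count$n_flagged <- 0L
    }
    null_count$n_flagged <- null_count$n_flagged + scr0$significant
  }
  list(planted_flagged = planted_flagged, planted_rs = planted_rs,
       null_flag_count = null_count, n_reps = n_reps)
}

# profile column name -> screen property row name
.screen_property_key <- function(columns) {
  reg <- .screen_properties()
  key <- reg$property[match(columns, reg$column)]
  if (anyNA(key)) stop("no screen row for descriptor: ",
                       columns[which(is.na(key))[1L]])
  key
}

# Minimal UniProt-style flat text for the synthetic feature sets.
.write_uniprot_fixture <- function(features, records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in records$protein_id) {
    len <- nchar(records$sequence[records$protein_id == id])
    writeLines(sprintf("ID   %s              Reviewed;        %d AA.", id, len), con)
    writeLines(sprintf("AC   %s;", id), con)
    fs <- features[[id]]
    if (!is.null(fs) && nrow(fs)) {
      for (j in seq_len(nrow(fs))) {
        loc <- if (fs$start[j] == fs$end[j]) sprintf("%d", fs$start[j]) else
          sprintf("%d..%d", fs$start[j], fs$end[j])
        writeLines(sprintf("FT   %-15s %s", fs$kind[j], loc), con)
        if (fs$kind[j] == "BINDING") {
          writeLines(sprintf('FT                   /ligand="%s"', fs$label[j]), con)
        } else if (nzchar(fs$label[j])) {
          writeLines(sprintf('FT                   /note="%s"', fs$label[j]), con)
        }
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}
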