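# End-to-end orchestration: profile all proteins, run the correlation
# screen, write TSV reports and a run manifest.

.default_config <- function() {
  list(reference = "negative_control",   # activity reference condition
       unit = "pooled",                  # correlation unit for protein rows
       family = "screen",                # BH family
       alpha = 0.05,
       rs_threshold = 0.8,
       ss_window = 17,
       unknown_policy = "reject",
       intensity_column = "intensity",
       seed = 1)
}

#' Read a plain-text `key: value` configuration file
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#' `NULL` path returns the full default configuration.
#'
#' @param path Path to the config file, or NULL.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: ", ln)
    key <- kv[2L]; val <- trimws(kv[3L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
  }
  cfg
}

#' Profile every protein of a FASTA file
#'
#' Wraps ingest + descriptor computation: reads sequences, optional UniProt
#' features and motif patterns, computes the full profile table and writes it
#' as one TSV row per protein.
#'
#' @param fasta Path to the FASTA file.
#' @param uniprot Optional path to UniProt flat-text features.
#' @param motifs Optional path to a PROSITE motif file (default: the shipped
#'   synthetic placeholder set).
#' @param out Optional output TSV path.
#' @param config Configuration list (see [read_config()]).
#' @return The profile table, invisibly when `out` is given.
#' @export
run_profile <- function(fasta, uniprot = NULL, motifs = default_motif_file(),
                        out = NULL, config = read_config()) {
  records <- read_fasta(fasta, unknown_policy = config$unknown_policy)
  features <- if (!is.null(uniprot)) read_uniprot_features(uniprot) else NULL
  patterns <- if (!is.null(motifs)) read_motif_file(motifs) else NULL
  profiles <- profile_proteins(records, features, patterns,
                               window = as.integer(config$ss_window))
  if (!is.null(out)) {
    write_profiles(profiles, out)
    return(invisible(profiles))
  }
  profiles
}

#' Run the abundance-weighted correlation screen end to end
#'
#' Normalizes the abundance table, converts assay readouts into the activity
#' panel, runs [correlation_screen()], writes the screen table, the list of
#' significant cells, the per-fraction summaries and a run manifest into
#' `out_dir`.
#'
#' @param profiles Profile table (or path to one written by [run_profile()]).
#' @param abundance Path to the abundance TSV, or a `fraction_table`.
#' @param assays Path to the assay readout TSV, or a readout data.frame.
#' @param out_dir Output directory (created if needed); NULL to skip writing.
#' @param config Configuration list (see [read_config()]).
#' @param inputs Optional named character vector of input file paths recorded
#'   (with checksums) in the manifest.
#' @return List with `screen`, `panel`, `summaries`, `significant`.
#' @export
run_screen <- function(profiles, abundance, assays, out_dir = NULL,
                       config = read_config(), inputs = NULL) {
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  table <- if (is.character(abundance)) {
    read_abundance_table(abundance, intensity_column = config$intensity_column)
  } else abundance
  readouts <- if (is.character(assays)) read_assay_table(assays) else
    validate_assay_readouts(assays)
  extra <- setdiff(table$protein_id, profiles$protein_id)
  missing <- setdiff(profiles$protein_id, table$protein_id)
  if (length(extra)) {
    stop("abundance table names protein(s) with no profile: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  table <- normalize_abundance(table)
  panel <- activity_panel(readouts, reference = config$reference)
  screen <- correlation_screen(table, profiles, panel,
                               unit = config$unit, family = config$family,
                               alpha = config$alpha,
                               rs_threshold = config$rs_threshold)
  summaries <- summarize_fractions(profiles, table)
  significant <- screen[screen$significant, , drop = FALSE]
  res <- list(screen = screen, panel = panel, summaries = summaries,
              significant = significant)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(screen, "screen.tsv")
    wt(significant, "significant.tsv")
    wt(panel, "activity_panel.tsv")
    wt(summaries, "fraction_summaries.tsv")
    write_manifest(out_dir, config, inputs,
                   ignored_proteins = missing)
  }
  res
}

#' Write a run manifest
#'
#' Records the package version, the configuration snapshot, input-file
#' checksums and a timestamp. Exactly one manifest per output directory.
#'
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @param inputs Named character vector of input paths (checksummed with
#'   md5), or NULL.
#' @param ignored_proteins Profile-only protein ids absent from the abundance
#'   table, recorded for transparency.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, inputs = NULL,
                           ignored_proteins = character()) {
  path <- file.path(out_dir, "MANIFEST.txt")
  lines <- c(
    paste0("tool: stonescreen ", as.character(utils::packageVersion("stonescreen"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("config.", names(config), ": ",
           vapply(config, as.character, character(1L))))
  if (!is.null(inputs) && length(inputs)) {
    sums <- tools::md5sum(unname(inputs))
    lines <- c(lines, paste0("input.", names(inputs), ": ", unname(inputs),
                             " md5=", unname(sums)))
  }
  if (length(ignored_proteins)) {
    lines <- c(lines, paste0("profiles_without_abundance: ",
                             paste(ignored_proteins, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
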