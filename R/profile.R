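# One-stop per-protein descriptor profiling: physicochemical descriptors,
# binding counts, and secondary-structure fractions in a single table.

#' Compute the full physicochemical profile of a set of proteins
#'
#' One row per protein: length, molecular weight, theoretical pI, GRAVY,
#' instability index, residue-class composition fractions, calcium-binding
#' site count, oxalate-binding motif count, and four-state
#' secondary-structure fractions.
#'
#' @param records data.frame from [read_fasta()] (columns `protein_id`,
#'   `sequence`).
#' @param features Optional named list from [read_uniprot_features()]; when
#'   absent, `n_ca_sites` is 0 for proteins without an entry.
#' @param patterns Optional named list of parsed motif patterns from
#'   [read_motif_file()]; when absent, `n_ox_motifs` is 0.
#' @param scheme Residue [class_scheme()].
#' @param window Secondary-structure window width (see [predict_ss()]).
#' @param ss Optional data.frame from [import_ss()]; proteins found there use
#'   the imported fractions instead of the built-in predictor.
#' @return data.frame of per-protein descriptors (a physicochemical profile
#'   table).
#' @export
profile_proteins <- function(records, features = NULL, patterns = NULL,
                             scheme = class_scheme(), window = 17L,
                             ss = NULL) {
  n <- nrow(records)
  if (!n) stop("no protein records")
  if (anyDuplicated(records$protein_id)) {
    stop("duplicate protein_id in records")
  }
  masses <- residue_masses()
  kd <- kyte_doolittle()
  diwv <- diwv_weights()
  prop <- ss_propensities()
  pka <- pka_bjellqvist()
  class_idx <- lapply(scheme, match, AA_STANDARD)
  regexes <- if (length(patterns)) {
    lapply(patterns, function(pp) {
      if (is.character(pp)) pp <- parse_prosite(pp)
      paste0("(?=(", .prosite_regex(pp), "))")
    })
  } else NULL

  num <- matrix(NA_real_, nrow = n, ncol = 16L)
  colnames(num) <- c("length", "mw_da", "pi", "gravy", "instability_index",
                     "frac_aromatic", "frac_polar", "frac_nonpolar",
                     "frac_positive", "frac_negative", "n_ca_sites",
                     "n_ox_motifs", "ss_helix", "ss_strand", "ss_turn",
                     "ss_coil")
  for (i in seq_len(n)) {
    id <- records$protein_id[i]
    sq <- records$sequence[i]
    codes <- .seq_codes(sq, id = id)
    L <- length(codes)
    counts <- tabulate(codes, nbins = 20L)
    mw <- sum(masses[codes]) + MASS_WATER_DA
    gravy <- mean(kd[codes])
    instab <- if (L >= 2L) (10 / L) * sum(diwv[cbind(codes[-L], codes[-1L])]) else NA_real_
    groups <- .pi_groups(codes, pka)
    lo <- 0; hi <- 14
    while (hi - lo >= 1e-3) {
      mid <- (lo + hi) / 2
      if (.net_charge(mid, groups) > 0) lo <- mid else hi <- mid
    }
    pi_val <- (lo + hi) / 2
    comp <- vapply(class_idx, function(ix) sum(counts[ix]) / L, numeric(1L))
    if (!is.null(ss) && id %in% ss$protein_id) {
      r <- ss[ss$protein_id == id, ][1L, ]
      ssf <- c(r$ss_helix, r$ss_strand, r$ss_turn, r$ss_coil)
    } else {
      states <- .predict_ss_states(codes, window, prop)
      ssf <- tabulate(states, nbins = 4L) / L
    }
    n_ca <- if (!is.null(features)) count_calcium_sites(features[[id]]) else 0L
    n_ox <- if (!is.null(regexes)) .count_motifs_fast(sq, regexes) else 0L
    num[i, ] <- c(L, mw, pi_val, gravy, instab, comp, n_ca, n_ox, ssf)
  }
  res <- data.frame(protein_id = records$protein_id, num,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write / read a profile table TSV
#' @param profiles data.frame from [profile_proteins()].
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
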