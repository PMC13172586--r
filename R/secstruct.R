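# Four-state secondary-structure fractions: a built-in window-averaged
# propensity predictor, and an importer for externally computed predictions.

#' Predict four-state secondary-structure fractions
#'
#' Each residue is assigned the argmax over helix, extended strand, beta turn
#' and random coil of the window-averaged propensity values (the window is
#' truncated at the termini); ties break by the fixed state order helix >
#' strand > turn > coil. Fractions are state counts divided by the sequence
#' length.
#'
#' This is a transparent single-sequence propensity method, not a
#' reimplementation of database-trained predictors such as SOPMA; for
#' comparisons against numbers produced with such tools, import their output
#' with [import_ss()] instead.
#'
#' @inheritParams compute_mw
#' @param window Odd window width (residues) for propensity averaging;
#'   default 17.
#' @param propensity_table 20 x 4 matrix as returned by [ss_propensities()].
#' @return Named numeric vector `ss_helix`, `ss_strand`, `ss_turn`,
#'   `ss_coil`, summing to 1.
#' @export
predict_ss <- function(sequence, window = 17L,
                       propensity_table = ss_propensities()) {
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  codes <- .seq_codes(sequence)
  states <- .predict_ss_states(codes, window, propensity_table)
  counts <- tabulate(states, nbins = 4L)
  stats::setNames(counts / length(codes),
                  c("ss_helix", "ss_strand", "ss_turn", "ss_coil"))
}

# Per-residue state indices (1 = helix, 2 = strand, 3 = turn, 4 = coil) from
# truncated-window moving averages of the four propensity tracks.
.predict_ss_states <- function(codes, window, propensity_table) {
  L <- length(codes)
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  denom <- hi - lo + 1L
  avg <- matrix(0, nrow = L, ncol = 4L)
  for (k in 1:4) {
    cs <- c(0, cumsum(propensity_table[codes, k]))
    avg[, k] <- (cs[hi + 1L] - cs[lo]) / denom
  }
  # max.col(ties.method = "first") realizes the helix > strand > turn > coil
  # tie-break because columns are in that order
  max.col(avg, ties.method = "first")
}

#' Import externally computed secondary-structure fractions
#'
#' Accepts either a TSV with columns `protein_id`, `helix`, `strand`, `turn`,
#' `coil` (fractions renormalized when they sum within \[0.98, 1.02\],
#' otherwise an error), or raw per-residue state strings in the `H/E/T/C`
#' alphabet, one `protein_id<TAB>states` pair per line (line wrapping of the
#' state string across continuation lines without an id is tolerated).
#'
#' @param path Input file path.
#' @return data.frame with columns `protein_id`, `ss_helix`, `ss_strand`,
#'   `ss_turn`, `ss_coil`, `source`.
#' @export
import_ss <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("\thelix", first, fixed = TRUE)) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "helix", "strand", "turn", "coil")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    tot <- d$helix + d$strand + d$turn + d$coil
    bad <- which(tot < 0.98 | tot > 1.02)
    if (length(bad)) {
      stop("fractions for ", d$protein_id[bad[1L]], " sum to ",
           format(tot[bad[1L]]), ", outside [0.98, 1.02]")
    }
    out <- data.frame(protein_id = d$protein_id,
                      ss_helix = d$helix / tot, ss_strand = d$strand / tot,
                      ss_turn = d$turn / tot, ss_coil = d$coil / tot,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    ids <- character(); states <- character()
    for (ln in lines) {
      if (grepl("\t", ln, fixed = TRUE)) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        ids <- c(ids, parts[1L])
        states <- c(states, gsub("\\s", "", parts[2L]))
      } else {
        if (!length(ids)) stop("state line before any protein_id line")
        states[length(states)] <- paste0(states[length(states)],
                                         gsub("\\s", "", ln))
      }
    }
    rows <- lapply(seq_along(ids), function(i) {
      ch <- strsplit(states[i], "", fixed = TRUE)[[1L]]
      idx <- match(ch, c("H", "E", "T", "C"))
      if (anyNA(idx)) {
        stop("unknown state letter '", ch[which(is.na(idx))[1L]],
             "' for ", ids[i])
      }
      counts <- tabulate(idx, nbins = 4L)
      data.frame(protein_id = ids[i],
                 ss_helix = counts[1L] / length(ch),
                 ss_strand = counts[2L] / length(ch),
                 ss_turn = counts[3L] / length(ch),
                 ss_coil = counts[4L] / length(ch),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out$source <- "imported"
  out
}
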