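# Calcium-binding site counting from UniProt feature annotations and
# per-fraction binding summaries.

#' Count calcium-binding sites from UniProt features
#'
#' Counts, per the default rule: (i) `BINDING` features whose ligand is
#' `Ca(2+)`, (ii) `DOMAIN` features whose description contains
#' "calcium-binding" (case-insensitive), and (iii) legacy `CA_BIND` features.
#' Overlapping spans from (i) and (iii) are merged and counted once, so an
#' entry annotated in both the current and legacy styles is not
#' double-counted; domain-based counts (ii) are added on top.
#'
#' @param features data.frame of features for one protein (columns
#'   `protein_id`, `kind`, `start`, `end`, `label`), one element of the list
#'   returned by [read_uniprot_features()].
#' @param use_binding,use_domain,use_ca_bind Logical switches for the three
#'   parts of the counting rule.
#' @return Integer count (>= 0).
#' @export
count_calcium_sites <- function(features, use_binding = TRUE,
                                use_domain = TRUE, use_ca_bind = TRUE) {
  if (is.null(features) || !nrow(features)) return(0L)
  spans <- features[
    (use_binding & features$kind == "BINDING" &
       grepl("Ca(2+)", features$label, fixed = TRUE)) |
    (use_ca_bind & features$kind == "CA_BIND"),
    c("start", "end"), drop = FALSE]
  n_span <- 0L
  if (nrow(spans)) {
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    cur_end <- -1L
    for (i in seq_len(nrow(spans))) {
      if (spans$start[i] > cur_end) {
        n_span <- n_span + 1L
        cur_end <- spans$end[i]
      } else {
        cur_end <- max(cur_end, spans$end[i])
      }
    }
  }
  n_dom <- if (use_domain) {
    sum(features$kind == "DOMAIN" &
          grepl("calcium-binding", features$label, ignore.case = TRUE))
  } else 0L
  as.integer(n_span + n_dom)
}

#' Summarize calcium- and oxalate-binding over one fraction
#'
#' Percentages are taken over all proteins of the fraction; the mean number
#' of sites/motifs per protein is taken over binders only (proteins with a
#' count of at least 1), which is the only denominator consistent with
#' nonzero per-protein means in fractions that contain non-binders. When a
#' fraction has no binders the mean is reported as 0 and flagged.
#'
#' @param ca_counts Integer vector of calcium-binding site counts, one per
#'   protein in the fraction.
#' @param ox_counts Integer vector of oxalate-binding motif counts, same
#'   proteins.
#' @return One-row data.frame: `n_proteins`, `pct_ca_proteins`,
#'   `mean_ca_sites`, `sem_ca_sites`, `ca_defined`, `pct_ox_proteins`,
#'   `mean_ox_motifs`, `sem_ox_motifs`, `ox_defined`.
#' @export
summarize_binding <- function(ca_counts, ox_counts) {
  n <- length(ca_counts)
  if (n == 0L || length(ox_counts) != n) {
    stop("need equal, nonzero numbers of calcium and oxalate counts")
  }
  binder_stats <- function(counts) {
    b <- counts[counts >= 1L]
    if (!length(b)) {
      list(pct = 0, mean = 0, sem = NA_real_, defined = FALSE)
    } else {
      list(pct = 100 * length(b) / n, mean = mean(b), sem = .sem(b),
           defined = TRUE)
    }
  }
  ca <- binder_stats(ca_counts)
  ox <- binder_stats(ox_counts)
  data.frame(n_proteins = n,
             pct_ca_proteins = ca$pct, mean_ca_sites = ca$mean,
             sem_ca_sites = ca$sem, ca_defined = ca$defined,
             pct_ox_proteins = ox$pct, mean_ox_motifs = ox$mean,
             sem_ox_motifs = ox$sem, ox_defined = ox$defined)
}
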