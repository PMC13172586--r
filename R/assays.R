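# Conversion of raw crystal-assay readouts into per-fraction
# promoting-activity percentages.

#' Compute promoting-activity percentages for one assay
#'
#' For each fraction, every replicate readout is expressed relative to the
#' mean of the reference condition:
#' `activity_i = 100 * (x_i - mean(ref)) / mean(ref)`.
#' The reported activity is the mean over replicates and its SEM; positive
#' values denote promotion, negative values inhibition. Replicates are
#' treated as independent experiments (no pairing with specific reference
#' replicates).
#'
#' @param readouts data.frame of assay readouts (see [read_assay_table()]);
#'   rows for other assays are ignored.
#' @param assay Which assay to compute (`"crystallization"`, `"growth"`,
#'   `"aggregation"` or `"adhesion"`).
#' @param reference Reference condition: `"negative_control"` (default; a
#'   lysozyme control in the laboratory protocol) or `"blank"` (crystal
#'   buffer without protein).
#' @return data.frame with one row per fraction: `fraction_id`, `assay`,
#'   `activity_pct`, `sem_pct`, `n_replicates`.
#' @export
compute_activity <- function(readouts, assay,
                             reference = c("negative_control", "blank")) {
  reference <- match.arg(reference)
  assay <- match.arg(assay, .assay_levels)
  d <- readouts[readouts$assay == assay, , drop = FALSE]
  ref <- d$metric_value[d$condition == reference]
  if (!length(ref)) stop("no '", reference, "' readouts for assay ", assay)
  ref_mean <- mean(ref)
  if (ref_mean <= 0) stop("reference mean must be > 0 for assay ", assay)
  fr <- d[d$condition == "fraction", , drop = FALSE]
  if (!nrow(fr)) stop("no fraction readouts for assay ", assay)
  ids <- unique(fr$fraction_id)
  rows <- lapply(ids, function(id) {
    x <- fr$metric_value[fr$fraction_id == id]
    act <- 100 * (x - ref_mean) / ref_mean
    data.frame(fraction_id = id, assay = assay,
               activity_pct = mean(act), sem_pct = .sem(act),
               n_replicates = length(act), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compute the full activity panel (all four assays)
#'
#' @inheritParams compute_activity
#' @return data.frame stacking [compute_activity()] over every assay present
#'   in `readouts`.
#' @export
activity_panel <- function(readouts, reference = c("negative_control", "blank")) {
  reference <- match.arg(reference)
  assays <- intersect(.assay_levels, unique(readouts$assay))
  if (!length(assays)) stop("no known assays in readouts")
  out <- do.call(rbind, lapply(assays, function(a) {
    compute_activity(readouts, a, reference)
  }))
  rownames(out) <- NULL
  out
}

#' Replicate-level activity table for downstream significance testing
#'
#' Emits the tidy replicate-level table (one row per fraction x assay x
#' replicate, with its per-replicate activity percentage) that standard
#' multiple-comparison procedures (ANOVA with post hoc tests, Kruskal-Wallis)
#' consume. No test is performed here.
#'
#' @inheritParams compute_activity
#' @return data.frame with columns `fraction_id`, `assay`, `replicate`,
#'   `metric_value`, `activity_pct`.
#' @export
compare_to_reference <- function(readouts, reference = c("negative_control", "blank")) {
  reference <- match.arg(reference)
  if (!nrow(readouts)) {
    return(data.frame(fraction_id = character(), assay = character(),
                      replicate = integer(), metric_value = numeric(),
                      activity_pct = numeric(), stringsAsFactors = FALSE))
  }
  validate_assay_readouts(readouts)
  assays <- intersect(.assay_levels, unique(readouts$assay))
  rows <- lapply(assays, function(a) {
    d <- readouts[readouts$assay == a, , drop = FALSE]
    ref_mean <- mean(d$metric_value[d$condition == reference])
    fr <- d[d$condition == "fraction", , drop = FALSE]
    if (!nrow(fr)) return(NULL)
    data.frame(fraction_id = fr$fraction_id, assay = a,
               replicate = fr$replicate, metric_value = fr$metric_value,
               activity_pct = 100 * (fr$metric_value - ref_mean) / ref_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
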