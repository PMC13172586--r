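# Abundance normalization and weighting, the pooled Spearman correlation
# screen of abundance-weighted properties against abundance-weighted
# activities with Benjamini-Hochberg adjustment and the |rs| > 0.8 rule, and
# per-fraction descriptive summaries.

# Registry of the screen's 22 property rows, in output order.
# level "protein": the descriptor is a per-protein profile column and is
# correlated over pooled protein-in-fraction entries (abundance-weighted on
# both sides). level "fraction": the descriptor is a percentage that only
# exists per fraction (abundance-weighted share of proteins in a class) and
# is correlated over fractions.
.screen_properties <- function() {
  data.frame(
    property = c("ca_binding_proteins_pct", "ca_sites_per_protein",
                 "ox_binding_proteins_pct", "ox_motifs_per_protein",
                 "mw", "low_mw_pct", "high_mw_pct",
                 "instability_index", "stable_pct", "unstable_pct",
                 "gravy", "hydrophilic_pct", "hydrophobic_pct",
                 "aromatic_pct", "polar_pct", "nonpolar_pct",
                 "positive_pct", "negative_pct",
                 "helix_pct", "strand_pct", "turn_pct", "coil_pct"),
    group = c(rep("binding", 4L), rep("mw", 3L), rep("stability", 3L),
              rep("hydropathicity", 3L), rep("composition", 5L),
              rep("secondary_structure", 4L)),
    level = c("fraction", "protein", "fraction", "protein",
              "protein", "fraction", "fraction",
              "protein", "fraction", "fraction",
              "protein", "fraction", "fraction",
              rep("protein", 5L), rep("protein", 4L)),
    column = c(NA, "n_ca_sites", NA, "n_ox_motifs",
               "mw_da", NA, NA,
               "instability_index", NA, NA,
               "gravy", NA, NA,
               "frac_aromatic", "frac_polar", "frac_nonpolar",
               "frac_positive", "frac_negative",
               "ss_helix", "ss_strand", "ss_turn", "ss_coil"),
    stringsAsFactors = FALSE)
}

#' Normalize raw intensities into within-fraction weights
#'
#' Sets `weight = intensity / fraction total` so that weights sum to 1 within
#' every fraction (the relative abundance of each protein in its fraction).
#'
#' @param table A `fraction_table` (see [read_abundance_table()]).
#' @return The table with the `weight` column filled in.
#' @export
normalize_abundance <- function(table) {
  if (!nrow(table)) stop("empty fraction table")
  if (any(table$intensity < 0)) stop("negative intensity")
  totals <- tapply(table$intensity, table$fraction_id, sum)
  zero <- names(totals)[totals <= 0]
  if (length(zero)) stop("fraction with zero total intensity: ", zero[1L])
  table$weight <- table$intensity / as.numeric(totals[table$fraction_id])
  table
}

#' Build pooled abundance-weighted entries
#'
#' One entry per (protein, fraction) pair: each per-protein descriptor is
#' multiplied by the protein's within-fraction weight (`aw_<descriptor>`),
#' and the fraction's whole-fraction activity percentage is assigned to each
#' member protein scaled by the same weight (`aw_<assay>`). These pooled
#' entries are the unit of the correlation screen for per-protein
#' descriptors.
#'
#' @param table Normalized `fraction_table` (see [normalize_abundance()]).
#' @param profiles Profile table from [profile_proteins()].
#' @param panel Activity panel from [activity_panel()].
#' @return data.frame of weighted entries.
#' @export
build_weighted_entries <- function(table, profiles, panel) {
  if (anyNA(table$weight)) table <- normalize_abundance(table)
  missing_prof <- setdiff(table$protein_id, profiles$protein_id)
  if (length(missing_prof)) {
    stop("no profile for protein(s): ",
         paste(utils::head(missing_prof, 5L), collapse = ", "))
  }
  missing_frac <- setdiff(table$fraction_id, panel$fraction_id)
  if (length(missing_frac)) {
    stop("no activity panel for fraction(s): ",
         paste(missing_frac, collapse = ", "))
  }
  reg <- .screen_properties()
  prot_rows <- reg[reg$level == "protein", , drop = FALSE]
  prof_idx <- match(table$protein_id, profiles$protein_id)
  out <- data.frame(protein_id = table$protein_id,
                    fraction_id = table$fraction_id,
                    weight = table$weight, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(prot_rows))) {
    out[[paste0("aw_", prot_rows$property[i])]] <-
      table$weight * profiles[[prot_rows$column[i]]][prof_idx]
  }
  assays <- unique(panel$assay)
  for (a in assays) {
    act <- panel$activity_pct[panel$assay == a]
    names(act) <- panel$fraction_id[panel$assay == a]
    out[[paste0("aw_", a)]] <- table$weight * as.numeric(act[table$fraction_id])
  }
  if (anyNA(out)) stop("non-finite abundance-weighted values")
  out
}

#' Spearman rank correlation with a t-approximation p value
#'
#' rs is the Pearson correlation of mid-ranks (ties receive average ranks).
#' The two-sided p value uses the t approximation with n - 2 degrees of
#' freedom; with `exact = TRUE` and n <= 9 it is instead the exact two-sided
#' permutation probability of `|rs|` at least as large as observed.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @param exact Use the exact permutation null (n <= 9 only).
#' @return List with `rs`, `p`, `n`. A constant input yields `rs = NA` and
#'   `p = NA` (flagged, excluded from any adjustment family).
#' @export
spearman <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rs = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  rs <- max(-1, min(1, rs))
  if (exact) {
    if (n > 9L) stop("exact permutation p only supported for n <= 9")
    p <- .spearman_exact_p(rx, ry, rs)
  } else {
    if (abs(rs) == 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      p <- min(1, max(p, .Machine$double.xmin))
    }
  }
  list(rs = rs, p = p, n = n)
}

# Exact two-sided permutation p: proportion of permutations of ry whose
# |rs| >= |rs observed| (within numerical tolerance). Enumerates n! mid-rank
# permutations; n <= 9 keeps this tractable.
.spearman_exact_p <- function(rx, ry, rs_obs) {
  n <- length(rx)
  sx <- stats::sd(rx); mx <- mean(rx)
  sy <- stats::sd(ry); my <- mean(ry)
  # rs for a permutation p of ry: (sum(rx * ry[p]) / n - mx * my) * n/(n-1) / (sx * sy)
  perms <- .all_permutations(n)
  s <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
  rs_all <- (s - n * mx * my) / ((n - 1) * sx * sy)
  mean(abs(rs_all) >= abs(rs_obs) - 1e-12)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' Step-up false-discovery-rate adjustment over one family of tests; the
#' family size defaults to the number of p values supplied.
#'
#' @param p Numeric vector of raw p values in (0, 1].
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p values, capped at 1.
#' @export
benjamini_hochberg <- function(p, m = length(p)) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH", n = m)
}

#' Abundance-weighted Spearman correlation screen
#'
#' For every property row and every assay, computes the Spearman rank
#' correlation between the abundance-weighted property and the
#' abundance-weighted activity, adjusts the raw p values by
#' Benjamini-Hochberg over the whole screen (one family), and flags a cell
#' significant when `p_adj < alpha` and `|rs| > rs_threshold`.
#'
#' Per-protein descriptors (MW, instability index, GRAVY, composition and
#' secondary-structure fractions, binding counts per protein) are correlated
#' over pooled protein-in-fraction entries (see [build_weighted_entries()]);
#' percentage-type rows (share of calcium-binding, low/high-MW,
#' stable/unstable, hydrophilic/hydrophobic, oxalate-binding proteins) only
#' exist per fraction and are correlated over fractions, using the
#' abundance-weighted share (summed weights of qualifying proteins) against
#' the fraction activity. `unit = "fraction"` switches the per-protein rows
#' to fraction-level weighted means as a sensitivity analysis.
#'
#' @param table Normalized `fraction_table`.
#' @param profiles Profile table from [profile_proteins()].
#' @param panel Activity panel from [activity_panel()].
#' @param unit `"pooled"` (default) or `"fraction"`.
#' @param family `"screen"` (one BH family over all cells, default) or
#'   `"per_activity"`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param rs_threshold Absolute-rs significance threshold (default 0.8).
#' @param exact Use the exact permutation p for fraction-level cells when the
#'   number of fractions is <= 9.
#' @return data.frame with one row per property x activity cell: `property`,
#'   `group`, `level`, `activity`, `n`, `rs`, `p`, `p_adj`, `significant`.
#' @export
correlation_screen <- function(table, profiles, panel,
                               unit = c("pooled", "fraction"),
                               family = c("screen", "per_activity"),
                               alpha = 0.05, rs_threshold = 0.8,
                               exact = FALSE) {
  unit <- match.arg(unit)
  family <- match.arg(family)
  if (anyNA(table$weight)) table <- normalize_abundance(table)
  entries <- build_weighted_entries(table, profiles, panel)
  if (nrow(entries) < 3L) stop("need at least 3 entries")
  reg <- .screen_properties()
  assays <- intersect(.assay_levels, unique(panel$assay))
  fractions <- unique(table$fraction_id)
  frac_pct <- .fraction_percentages(table, profiles, fractions)
  act_by_assay <- lapply(assays, function(a) {
    v <- panel$activity_pct[panel$assay == a]
    names(v) <- panel$fraction_id[panel$assay == a]
    as.numeric(v[fractions])
  })
  names(act_by_assay) <- assays

  cells <- vector("list", nrow(reg) * length(assays))
  k <- 0L
  for (i in seq_len(nrow(reg))) {
    prop <- reg$property[i]
    for (a in assays) {
      k <- k + 1L
      if (reg$level[i] == "protein" && unit == "pooled") {
        x <- entries[[paste0("aw_", prop)]]
        y <- entries[[paste0("aw_", a)]]
        res <- spearman(x, y)
      } else if (reg$level[i] == "protein") {
        # fraction-level sensitivity unit: weighted means vs activity
        x <- vapply(fractions, function(f) {
          sel <- table$fraction_id == f
          sum(table$weight[sel] *
                profiles[[reg$column[i]]][match(table$protein_id[sel],
                                                profiles$protein_id)])
        }, numeric(1L))
        res <- spearman(x, act_by_assay[[a]],
                        exact = exact && length(fractions) <= 9L)
      } else {
        x <- frac_pct[[prop]]
        res <- spearman(x, act_by_assay[[a]],
                        exact = exact && length(fractions) <= 9L)
      }
      cells[[k]] <- data.frame(property = prop, group = reg$group[i],
                               level = reg$level[i], activity = a,
                               n = res$n, rs = res$rs, p = res$p,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (family == "screen") {
    out$p_adj[ok] <- benjamini_hochberg(out$p[ok])
  } else {
    for (a in assays) {
      sel <- ok & out$activity == a
      out$p_adj[sel] <- benjamini_hochberg(out$p[sel])
    }
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha &
    !is.na(out$rs) & abs(out$rs) > rs_threshold
  rownames(out) <- NULL
  out
}

# Abundance-weighted percentage rows per fraction: 100 * summed weight of
# qualifying proteins.
.fraction_percentages <- function(table, profiles, fractions) {
  idx <- match(table$protein_id, profiles$protein_id)
  flags <- data.frame(
    ca_binding_proteins_pct = profiles$n_ca_sites[idx] >= 1L,
    ox_binding_proteins_pct = profiles$n_ox_motifs[idx] >= 1L,
    low_mw_pct = classify_mw(profiles$mw_da[idx]) == "low",
    high_mw_pct = classify_mw(profiles$mw_da[idx]) == "high",
    stable_pct = classify_stability(profiles$instability_index[idx]) == "stable",
    unstable_pct = classify_stability(profiles$instability_index[idx]) == "unstable",
    hydrophilic_pct = classify_hydropathy(profiles$gravy[idx]) == "hydrophilic",
    hydrophobic_pct = classify_hydropathy(profiles$gravy[idx]) == "hydrophobic")
  out <- lapply(flags, function(fl) {
    vapply(fractions, function(f) {
      sel <- table$fraction_id == f
      100 * sum(table$weight[sel][fl[sel]])
    }, numeric(1L))
  })
  out
}

#' Per-fraction descriptive summaries of a profile table
#'
#' For each fraction: mean and SEM (over the proteins of the fraction,
#' unweighted) of every numeric descriptor, plus the proportion splits at the
#' conventional thresholds (low/high MW at 50 kDa, stable/unstable at
#' instability index 40, hydrophilic/hydrophobic at GRAVY 0) and the
#' percentage of calcium- and oxalate-binding proteins.
#'
#' @param profiles Profile table from [profile_proteins()].
#' @param membership data.frame with columns `protein_id`, `fraction_id`
#'   (e.g. a `fraction_table`).
#' @return data.frame with one row per fraction.
#' @export
summarize_fractions <- function(profiles, membership) {
  fractions <- unique(membership$fraction_id)
  num_cols <- c("mw_da", "pi", "gravy", "instability_index",
                "frac_aromatic", "frac_polar", "frac_nonpolar",
                "frac_positive", "frac_negative", "n_ca_sites",
                "n_ox_motifs", "ss_helix", "ss_strand", "ss_turn", "ss_coil")
  rows <- lapply(fractions, function(f) {
    ids <- membership$protein_id[membership$fraction_id == f]
    if (!length(ids)) stop("empty fraction: ", f)
    miss <- setdiff(ids, profiles$protein_id)
    if (length(miss)) stop("no profile for protein(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    p <- profiles[match(ids, profiles$protein_id), , drop = FALSE]
    stats_row <- list(fraction_id = f, n_proteins = nrow(p))
    for (cc in num_cols) {
      stats_row[[paste0("mean_", cc)]] <- mean(p[[cc]])
      stats_row[[paste0("sem_", cc)]] <- .sem(p[[cc]])
    }
    stats_row$pct_low_mw <- 100 * mean(classify_mw(p$mw_da) == "low")
    stats_row$pct_high_mw <- 100 * mean(classify_mw(p$mw_da) == "high")
    stats_row$pct_stable <- 100 * mean(classify_stability(p$instability_index) == "stable")
    stats_row$pct_unstable <- 100 * mean(classify_stability(p$instability_index) == "unstable")
    stats_row$pct_hydrophilic <- 100 * mean(classify_hydropathy(p$gravy) == "hydrophilic")
    stats_row$pct_hydrophobic <- 100 * mean(classify_hydropathy(p$gravy) == "hydrophobic")
    stats_row$pct_ca_binding <- 100 * mean(p$n_ca_sites >= 1L)
    stats_row$pct_ox_binding <- 100 * mean(p$n_ox_motifs >= 1L)
    as.data.frame(stats_row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
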