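# ProtParam-equivalent sequence descriptors: average-mass MW, theoretical pI,
# GRAVY, Guruprasad instability index, and residue-class composition.

#' Molecular weight of a protein sequence (average masses)
#'
#' Sum of average (isotope-abundance-weighted) residue masses plus one water
#' mass, matching ProtParam. Posttranslational modifications are not
#' considered.
#'
#' @param sequence Amino-acid sequence over the 20 standard residues.
#' @return Molecular weight in daltons.
#' @export
compute_mw <- function(sequence) {
  codes <- .seq_codes(sequence)
  sum(residue_masses()[codes]) + MASS_WATER_DA
}

#' GRAVY (grand average of hydropathicity) score
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues.
#' Negative values indicate hydrophilic sequences.
#'
#' @inheritParams compute_mw
#' @return GRAVY score.
#' @export
compute_gravy <- function(sequence) {
  codes <- .seq_codes(sequence)
  mean(kyte_doolittle()[codes])
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum` of the dipeptide instability weights (DIWV) over the
#' `L - 1` overlapping dipeptides; dipeptides absent from the published table
#' weigh 1.0. Values of 40 and above conventionally indicate an unstable
#' protein.
#'
#' @inheritParams compute_mw
#' @return Instability index (requires length >= 2).
#' @export
compute_instability <- function(sequence) {
  codes <- .seq_codes(sequence)
  L <- length(codes)
  if (L < 2L) stop("instability index requires sequence length >= 2")
  w <- diwv_weights()
  (10 / L) * sum(w[cbind(codes[-L], codes[-1L])])
}

#' Theoretical isoelectric point
#'
#' pH of zero net charge from Henderson-Hasselbalch sums over the termini and
#' the D, E, C, Y, H, K, R side chains, found by bisection on \[0, 14\]. The
#' default pKa set is the Bjellqvist set used by ProtParam, including its
#' residue-specific N-/C-terminal pKa overrides.
#'
#' @inheritParams compute_mw
#' @param pka_set data.frame as returned by [pka_bjellqvist()] (columns
#'   `group`, `sign`, `pka`).
#' @param tol Bisection stops when the pH interval is narrower than this.
#' @return Theoretical pI.
#' @export
compute_pi <- function(sequence, pka_set = pka_bjellqvist(), tol = 1e-3) {
  codes <- .seq_codes(sequence)
  groups <- .pi_groups(codes, pka_set)
  f <- function(ph) .net_charge(ph, groups)
  lo <- 0; hi <- 14
  if (f(lo) < 0 || f(hi) > 0) {
    stop("net charge does not cross zero on [0, 14]")
  }
  while (hi - lo >= tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Ionizable groups of a sequence: plain list of pka / positive-flag / count
# vectors (kept free of data.frame overhead; called once per protein).
.pi_groups <- function(codes, pka_set) {
  first <- AA_STANDARD[codes[1L]]
  last <- AA_STANDARD[codes[length(codes)]]
  pk <- stats::setNames(pka_set$pka, pka_set$group)
  sgn <- stats::setNames(pka_set$sign, pka_set$group)
  nterm_key <- if (paste0("Nterm_", first) %in% names(pk)) paste0("Nterm_", first) else "Nterm"
  cterm_key <- if (paste0("Cterm_", last) %in% names(pk)) paste0("Cterm_", last) else "Cterm"
  counts <- tabulate(codes, nbins = 20L)
  names(counts) <- AA_STANDARD
  side <- intersect(c("K", "R", "H", "D", "E", "C", "Y"), names(pk))
  list(
    pka = c(pk[[nterm_key]], pk[[cterm_key]], unname(pk[side])),
    positive = c(TRUE, FALSE, unname(sgn[side]) == "positive"),
    count = c(1, 1, unname(counts[side]))
  )
}

.net_charge <- function(ph, groups) {
  pos <- groups$positive
  cp <- sum(groups$count[pos] / (1 + 10^(ph - groups$pka[pos])))
  cn <- sum(groups$count[!pos] / (1 + 10^(groups$pka[!pos] - ph)))
  cp - cn
}

#' Residue classification scheme
#'
#' Builds (and validates) the five residue classes used for composition
#' fractions. The four charge/polarity classes must form a disjoint cover of
#' the 20 standard residues; the aromatic class overlaps them and is reported
#' separately. The default scheme: aromatic \{F, W, Y\}; positive \{K, R, H\};
#' negative \{D, E\}; polar \{S, T, N, Q, C, Y, G\}; nonpolar
#' \{A, V, L, I, P, M, F, W\}.
#'
#' @param aromatic,positive,negative,polar,nonpolar Character vectors of
#'   one-letter residue codes.
#' @return An object of class `class_scheme`.
#' @export
class_scheme <- function(aromatic = c("F", "W", "Y"),
                         positive = c("K", "R", "H"),
                         negative = c("D", "E"),
                         polar = c("S", "T", "N", "Q", "C", "Y", "G"),
                         nonpolar = c("A", "V", "L", "I", "P", "M", "F", "W")) {
  sets <- list(aromatic = aromatic, positive = positive, negative = negative,
               polar = polar, nonpolar = nonpolar)
  for (nm in names(sets)) {
    bad <- setdiff(sets[[nm]], AA_STANDARD)
    if (length(bad)) stop("non-standard residue in ", nm, " class: ", bad[1L])
  }
  four <- c(sets$positive, sets$negative, sets$polar, sets$nonpolar)
  if (anyDuplicated(four) || length(setdiff(AA_STANDARD, four))) {
    stop("positive/negative/polar/nonpolar must be a disjoint cover of the 20 residues")
  }
  structure(sets, class = "class_scheme")
}

#' Residue-class composition fractions
#'
#' Fraction of residues falling in each class of a [class_scheme()]. Under
#' the default scheme the four charge/polarity fractions sum to 1; the
#' aromatic fraction overlaps them.
#'
#' @inheritParams compute_mw
#' @param scheme A [class_scheme()].
#' @return Named numeric vector `frac_aromatic`, `frac_polar`,
#'   `frac_nonpolar`, `frac_positive`, `frac_negative`.
#' @export
compute_composition <- function(sequence, scheme = class_scheme()) {
  if (!inherits(scheme, "class_scheme")) stop("scheme must be a class_scheme")
  codes <- .seq_codes(sequence)
  counts <- tabulate(codes, nbins = 20L)
  L <- length(codes)
  frac <- function(set) sum(counts[match(set, AA_STANDARD)]) / L
  c(frac_aromatic = frac(scheme$aromatic),
    frac_polar = frac(scheme$polar),
    frac_nonpolar = frac(scheme$nonpolar),
    frac_positive = frac(scheme$positive),
    frac_negative = frac(scheme$negative))
}

#' Threshold classifications used in the per-fraction summaries
#'
#' Binary splits at the conventional thresholds: molecular weight 50 kDa,
#' instability index 40, GRAVY 0. Values exactly on a threshold take the
#' upper class (high / unstable / hydrophobic): the sources define these
#' splits with strict inequalities on both sides, so a single consistent
#' ">= threshold" rule resolves the (measure-zero) boundary.
#'
#' @param mw_da Molecular weight in daltons.
#' @return `classify_mw`: `"low"` or `"high"`.
#' @export
classify_mw <- function(mw_da) {
  stopifnot(all(mw_da > 0))
  ifelse(mw_da >= 50000, "high", "low")
}

#' @rdname classify_mw
#' @param ii Instability index. May be negative: the published dipeptide
#'   weight table contains negative entries, so short acid-rich sequences can
#'   score below zero; any value below 40 is stable.
#' @return `classify_stability`: `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(ii) {
  if (any(!is.finite(ii))) stop("instability index must be finite")
  ifelse(ii >= 40, "unstable", "stable")
}

#' @rdname classify_mw
#' @param gravy GRAVY score.
#' @return `classify_hydropathy`: `"hydrophilic"` or `"hydrophobic"`.
#' @export
classify_hydropathy <- function(gravy) {
  ifelse(gravy >= 0, "hydrophobic", "hydrophilic")
}
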