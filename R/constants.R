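#' @keywords internal
"_PACKAGE"

# The 20 standard residues in alphabetical one-letter order; all descriptor
# tables are indexed in this order.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Non-standard one-letter codes handled by the skip_residue ingest policy.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

MASS_WATER_DA <- 18.01524

.tables <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "stonescreen")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}

.read_table_file <- function(file) {
  utils::read.delim(.extdata(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.cached <- function(key, build) {
  if (!exists(key, envir = .tables, inherits = FALSE)) {
    assign(key, build(), envir = .tables)
  }
  get(key, envir = .tables, inherits = FALSE)
}

#' Named vector of Kyte-Doolittle hydropathy values
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  .cached("kd", function() {
    d <- .read_table_file("kyte_doolittle_hydropathy.tsv")
    stats::setNames(d$hydropathy, d$aa)[AA_STANDARD]
  })
}

#' Named vector of average residue masses (Da)
#' @return Named numeric vector over the 20 standard residues.
#' @export
residue_masses <- function() {
  .cached("mass", function() {
    d <- .read_table_file("residue_masses_average.tsv")
    stats::setNames(d$mass_da, d$aa)[AA_STANDARD]
  })
}

#' Guruprasad dipeptide instability weight (DIWV) matrix
#'
#' 20 x 20 matrix of dipeptide instability weights; rows index the first
#' residue of the dipeptide, columns the second. Dipeptides absent from the
#' published table carry weight 1.0 in the shipped file.
#' @return Numeric matrix with residue dimnames.
#' @export
diwv_weights <- function() {
  .cached("diwv", function() {
    d <- .read_table_file("diwv_instability_weights.tsv")
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$aa
    m[AA_STANDARD, AA_STANDARD]
  })
}

#' Bjellqvist pKa set used by the theoretical-pI calculation
#'
#' The side-chain, terminal, and residue-specific terminal pKa values of the
#' Bjellqvist set as used by ProtParam.
#' @return data.frame with columns group, sign, pka.
#' @export
pka_bjellqvist <- function() {
  .cached("pka", function() .read_table_file("pka_bjellqvist.tsv"))
}

#' Four-state secondary-structure propensity table
#'
#' Per-residue helix/strand/turn/coil propensities used by [predict_ss()].
#' See the data file header and the methods vignette for provenance.
#' @return Numeric matrix, 20 residues x 4 states.
#' @export
ss_propensities <- function() {
  .cached("ssprop", function() {
    d <- .read_table_file("ss_propensities.tsv")
    m <- as.matrix(d[, c("helix", "strand", "turn", "coil")])
    rownames(m) <- d$aa
    m[AA_STANDARD, ]
  })
}

#' Background amino-acid frequencies for synthetic proteomes
#' @return Named numeric vector of probabilities summing to 1.
#' @export
residue_background <- function() {
  .cached("bg", function() {
    d <- .read_table_file("residue_background_freqs.tsv")
    v <- stats::setNames(d$freq_pct, d$aa)[AA_STANDARD]
    v / sum(v)
  })
}

#' Path of the shipped synthetic placeholder oxalate-motif file
#'
#' The shipped motif set is a synthetic stand-in so the pipeline runs without
#' external resources; replace it with the published oxalate-binding motif
#' definitions for real analyses. Outputs record the motif-file checksum.
#' @return File path.
#' @export
default_motif_file <- function() .extdata("oxalate_motifs_synthetic.tsv")

# sequence -> integer codes into AA_STANDARD; stops on non-standard residues.
# `id` (when given) is only used to build error messages.
.seq_codes <- function(sequence, id = NULL, what = NULL) {
  label <- function() {
    if (!is.null(what)) what
    else if (!is.null(id)) paste0("sequence of ", id)
    else "sequence"
  }
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(label(), " must be a single non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  codes <- match(chars, AA_STANDARD)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("non-standard residue '", chars[bad], "' at position ", bad,
         " in ", label())
  }
  codes
}

.assay_levels <- c("crystallization", "growth", "aggregation", "adhesion")
.condition_levels <- c("blank", "negative_control", "fraction")

.sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
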