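# Readers and writers for all external inputs: FASTA sequences, the
# protein-by-fraction abundance table, UniProt flat-text feature annotations,
# PROSITE-syntax motif files, and raw crystal-assay readout tables.

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased. Residues outside the 20 standard one-letter
#' codes are either rejected (default) or removed, depending on
#' `unknown_policy`. Downstream descriptor tables (residue masses,
#' Kyte-Doolittle, DIWV, propensities) are defined only on the 20 standard
#' residues, so silent substitution is never performed.
#'
#' @param path Path to a FASTA file.
#' @param unknown_policy `"reject"` (error on any non-standard residue, the
#'   default) or `"skip_residue"` (drop `B J O U X Z` with a message giving
#'   the count).
#' @return data.frame with columns `protein_id`, `sequence`, `description`.
#' @export
read_fasta <- function(path, unknown_policy = c("reject", "skip_residue")) {
  unknown_policy <- match.arg(unknown_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1L])
  seqs <- toupper(as.character(aa))
  if (unknown_policy == "skip_residue") {
    pat <- paste0("[", paste(AA_NONSTANDARD, collapse = ""), "]")
    n_before <- sum(nchar(seqs))
    seqs <- gsub(pat, "", seqs)
    skipped <- n_before - sum(nchar(seqs))
    if (skipped > 0L) {
      message(skipped, " non-standard residue(s) skipped")
    }
  }
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for id ", ids[i])
    .seq_codes(seqs[i], what = paste0("sequence of ", ids[i]))
  }
  data.frame(protein_id = ids, sequence = unname(seqs),
             description = unname(desc), stringsAsFactors = FALSE)
}

#' Read a protein-by-fraction relative-abundance table
#'
#' Accepts the two layouts MS workflows produce: a wide table (one protein-id
#' column plus one intensity column per fraction, as in MaxQuant
#' proteinGroups exports) or a long table with `protein_id` / `fraction_id` /
#' intensity columns. The layout is auto-detected from the header. Zero and
#' missing intensities are omitted; fraction order follows header (wide) or
#' first-appearance (long) order. Weights are left unset; see
#' [normalize_abundance()].
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param intensity_column For wide tables, an optional column-name prefix
#'   selecting which MaxQuant quantity to use (e.g. `"iBAQ"` picks columns
#'   `iBAQ <fraction>`); for long tables, the name of the intensity column.
#'   Default `"intensity"`.
#' @return A `fraction_table` data.frame with columns `protein_id`,
#'   `fraction_id`, `intensity`, `weight` (NA until normalized) and attribute
#'   `fraction_ids`.
#' @export
read_abundance_table <- function(path, intensity_column = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- names(d)
  lc <- tolower(cn)
  id_col <- which(lc %in% c("protein_id", "protein ids", "protein", "majority protein ids"))[1L]
  if (is.na(id_col)) id_col <- 1L
  if (all(c("protein_id", "fraction_id") %in% lc)) {
    # long layout
    int_col <- which(lc == tolower(intensity_column))[1L]
    if (is.na(int_col)) int_col <- which(lc == "intensity")[1L]
    if (is.na(int_col)) stop("no intensity column '", intensity_column, "' in long table")
    out <- data.frame(
      protein_id = as.character(d[[which(lc == "protein_id")[1L]]]),
      fraction_id = as.character(d[[which(lc == "fraction_id")[1L]]]),
      intensity = as.numeric(d[[int_col]]),
      stringsAsFactors = FALSE
    )
    fraction_ids <- unique(out$fraction_id)
  } else {
    # wide layout: fraction columns either bare fraction names or
    # "<intensity_column> <fraction>"
    other <- setdiff(seq_along(cn), id_col)
    pref <- paste0("^", intensity_column, "[ .]")
    pref_cols <- other[grepl(pref, cn[other], ignore.case = TRUE)]
    if (length(pref_cols)) {
      frac_cols <- pref_cols
      frac_names <- sub(pref, "", cn[frac_cols], ignore.case = TRUE)
    } else {
      num_ok <- vapply(other, function(j) is.numeric(d[[j]]) || all(!is.na(suppressWarnings(as.numeric(d[[j]])))), logical(1L))
      frac_cols <- other[num_ok]
      frac_names <- cn[frac_cols]
    }
    if (!length(frac_cols)) stop("no recognizable fraction columns in ", path)
    long <- lapply(seq_along(frac_cols), function(k) {
      data.frame(protein_id = as.character(d[[id_col]]),
                 fraction_id = frac_names[k],
                 intensity = as.numeric(d[[frac_cols[k]]]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, long)
    fraction_ids <- frac_names
  }
  if (anyNA(out$intensity)) out <- out[!is.na(out$intensity), , drop = FALSE]
  if (any(out$intensity < 0)) {
    bad <- out[out$intensity < 0, ][1L, ]
    stop("negative intensity for ", bad$protein_id, " in ", bad$fraction_id)
  }
  out <- out[out$intensity > 0, , drop = FALSE]
  key <- paste(out$protein_id, out$fraction_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (protein, fraction) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  }
  out$weight <- NA_real_
  rownames(out) <- NULL
  structure(out, fraction_ids = fraction_ids,
            class = c("fraction_table", "data.frame"))
}

#' Write a fraction table as a long-format TSV
#'
#' Round-trips through [read_abundance_table()].
#' @param table A `fraction_table` data.frame.
#' @param path Output path.
#' @export
write_abundance_table <- function(table, path) {
  utils::write.table(table[, c("protein_id", "fraction_id", "intensity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- UniProt flat text ----

#' Read feature annotations from UniProt flat-text entries
#'
#' Parses `FT` lines of one or more flat-text entries and keeps the three
#' feature kinds used for calcium-binding counting: `BINDING` (with its
#' `/ligand` qualifier), `DOMAIN` (with its `/note` description), and legacy
#' `CA_BIND`. All other feature kinds are ignored. Entries are keyed by the
#' first `AC` accession (falling back to the `ID` name).
#'
#' @param path Path to a UniProt flat-text file.
#' @return Named list (one element per entry) of data.frames with columns
#'   `protein_id`, `kind`, `start`, `end`, `label`.
#' @export
read_uniprot_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  entries <- list()
  cur_id <- NULL
  cur_ac <- NULL
  feats <- list()
  open <- NULL   # feature awaiting qualifiers
  keep <- c("BINDING", "DOMAIN", "CA_BIND")

  flush_open <- function() {
    if (!is.null(open)) feats[[length(feats) + 1L]] <<- open
    open <<- NULL
  }
  flush_entry <- function() {
    flush_open()
    if (is.null(cur_id) && is.null(cur_ac)) return(invisible())
    id <- if (!is.null(cur_ac)) cur_ac else cur_id
    df <- if (length(feats)) {
      do.call(rbind, lapply(feats, as.data.frame, stringsAsFactors = FALSE))
    } else {
      data.frame(kind = character(), start = integer(), end = integer(),
                 label = character(), stringsAsFactors = FALSE)
    }
    df <- cbind(protein_id = rep(id, nrow(df)), df, stringsAsFactors = FALSE)
    entries[[id]] <<- df
    cur_id <<- NULL; cur_ac <<- NULL; feats <<- list()
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    if (tag == "ID") {
      cur_id <- strsplit(trimws(substr(ln, 6L, nchar(ln))), "\\s+")[[1L]][1L]
    } else if (tag == "AC" && is.null(cur_ac)) {
      cur_ac <- sub(";.*$", "", trimws(substr(ln, 6L, nchar(ln))))
    } else if (tag == "//") {
      flush_entry()
    } else if (tag == "FT") {
      body <- substr(ln, 6L, nchar(ln))
      if (grepl("^\\S", body)) {
        # new feature line: KEY  location
        flush_open()
        parts <- strsplit(trimws(body), "\\s+")[[1L]]
        key <- parts[1L]
        if (!(key %in% keep)) next
        if (length(parts) < 2L) {
          stop("malformed FT line ", i, ": missing location")
        }
        loc <- parts[2L]
        m <- regmatches(loc, regexec("^[<>?]?(\\d+)(?:\\.\\.[<>?]?(\\d+))?$", loc))[[1L]]
        if (!length(m)) stop("malformed FT location at line ", i, ": ", loc)
        s <- as.integer(m[2L])
        e <- if (nzchar(m[3L])) as.integer(m[3L]) else s
        if (s > e) stop("malformed FT span at line ", i, ": start > end")
        open <- list(kind = key, start = s, end = e, label = "")
      } else {
        # continuation / qualifier line
        if (is.null(open)) {
          # continuation of an ignored feature
          next
        }
        q <- trimws(body)
        if (grepl('^/ligand="', q)) {
          open$label <- sub('^/ligand="([^"]*)".*$', "\\1", q)
        } else if (grepl('^/note="', q)) {
          open$label <- sub('^/note="([^"]*)".*$', "\\1", q)
        } else if (grepl("^/", q) || open$kind == "CA_BIND" ||
                   nzchar(open$label)) {
          # other qualifier or wrapped description text: append plain text
          if (!grepl("^/", q)) {
            open$label <- paste0(open$label, if (nzchar(open$label)) " ", gsub('"', "", q))
          }
        } else {
          stop("malformed FT continuation at line ", i)
        }
      }
    }
  }
  flush_entry()
  entries
}

# ---- PROSITE motif file ----

#' Read a PROSITE-syntax motif file
#'
#' One `name<TAB>pattern` pair per line; `#` starts a comment. Each pattern
#' is parsed eagerly so malformed patterns fail at load time.
#'
#' @param path Path to the motif file.
#' @return Named list of parsed patterns (class `prosite_pattern`).
#' @export
read_motif_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("motif line must be 'name<TAB>pattern': ", ln)
    out[[parts[1L]]] <- parse_prosite(parts[2L])
  }
  out
}

# ---- assay readout table ----

#' Read a raw crystal-assay readout table
#'
#' Tab-delimited with columns `assay`, `condition`, `fraction_id`,
#' `replicate`, `metric_value`. Assays are crystallization (crystal count per
#' field), growth (crystal size, micrometres), aggregation (aggregate count
#' per field) and adhesion (adherent crystals per field); conditions are
#' `blank`, `negative_control` or `fraction`.
#'
#' @param path Path to the TSV.
#' @return data.frame of validated readouts.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(fraction_id = "character"))
  need <- c("assay", "condition", "fraction_id", "replicate", "metric_value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("assay table missing column(s): ", paste(miss, collapse = ", "))
  d$fraction_id[is.na(d$fraction_id)] <- ""
  validate_assay_readouts(d)
}

#' @rdname read_assay_table
#' @param readouts data.frame of assay readouts to validate.
#' @export
validate_assay_readouts <- function(readouts) {
  bad_assay <- setdiff(unique(readouts$assay), .assay_levels)
  if (length(bad_assay)) stop("unknown assay: ", paste(bad_assay, collapse = ", "))
  bad_cond <- setdiff(unique(readouts$condition), .condition_levels)
  if (length(bad_cond)) stop("unknown condition: ", paste(bad_cond, collapse = ", "))
  if (any(!is.finite(readouts$metric_value)) || any(readouts$metric_value < 0)) {
    stop("metric_value must be nonnegative and finite")
  }
  if (any(readouts$replicate < 1L)) stop("replicate indices must be >= 1")
  key <- paste(readouts$assay, readouts$condition, readouts$fraction_id,
               readouts$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate replicate: ", key[duplicated(key)][1L])
  }
  readouts[, c("assay", "condition", "fraction_id", "replicate", "metric_value")]
}

#' Write an assay readout table (round-trips through [read_assay_table()])
#' @param readouts data.frame of assay readouts.
#' @param path Output path.
#' @export
write_assay_table <- function(readouts, path) {
  utils::write.table(readouts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
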