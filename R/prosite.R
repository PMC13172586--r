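# PROSITE-syntax pattern parsing and sequence scanning.
#
# Supported grammar (PROSITE user manual): elements separated by '-'; an
# element is a residue letter, 'x' (any residue), '[ABC]' (allowed set) or
# '{ABC}' (excluded set), optionally followed by a repeat count '(n)' or
# range '(n,m)'. A trailing '.' is tolerated; the '<' and '>' anchors are
# accepted as first/last elements.

#' Parse a PROSITE-syntax pattern
#'
#' @param pattern Pattern string, e.g. `"[KR]-x(2)-K-x-[KR]"`.
#' @return An object of class `prosite_pattern`: a list with the source
#'   string, the parsed element list (each element: allowed-residue vector,
#'   min and max repeat), and anchor flags.
#' @export
parse_prosite <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("pattern must be a single non-empty string")
  }
  raw <- pattern
  p <- sub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(p, "<")
  if (anchor_start) p <- substr(p, 2L, nchar(p))
  anchor_end <- endsWith(p, ">")
  if (anchor_end) p <- substr(p, 1L, nchar(p) - 1L)
  if (!nzchar(p)) stop("zero-length pattern: ", raw)
  toks <- strsplit(p, "-", fixed = TRUE)[[1L]]
  if (any(!nzchar(toks))) stop("empty element in pattern: ", raw)
  elements <- lapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
      tok))[[1L]]
    if (!length(m) || !nzchar(m[2L])) {
      stop("unparseable PROSITE element '", tok, "' in pattern: ", raw)
    }
    core <- m[2L]
    if (core == "x") {
      allowed <- AA_STANDARD
    } else if (startsWith(core, "[")) {
      set <- strsplit(gsub("[][]", "", core), "")[[1L]]
      bad <- setdiff(set, AA_STANDARD)
      if (length(bad)) stop("non-standard residue '", bad[1L], "' in element '",
                            tok, "' of pattern: ", raw)
      allowed <- set
    } else if (startsWith(core, "{")) {
      set <- strsplit(gsub("[{}]", "", core), "")[[1L]]
      bad <- setdiff(set, AA_STANDARD)
      if (length(bad)) stop("non-standard residue '", bad[1L], "' in element '",
                            tok, "' of pattern: ", raw)
      allowed <- setdiff(AA_STANDARD, set)
    } else {
      if (!(core %in% AA_STANDARD)) {
        stop("non-standard residue '", core, "' in pattern: ", raw)
      }
      allowed <- core
    }
    nmin <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    nmax <- if (nzchar(m[4L])) as.integer(m[4L]) else nmin
    if (nmin < 1L || nmax < nmin) {
      stop("invalid repeat count in element '", tok, "' of pattern: ", raw)
    }
    list(allowed = allowed, min = nmin, max = nmax)
  })
  structure(list(pattern = raw, elements = elements,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", x$pattern, " (", length(x$elements),
      " elements)\n", sep = "")
  invisible(x)
}

# Convert a parsed pattern to a PCRE fragment. Variable-range repeats use
# lazy quantifiers so each match start reports its shortest satisfying span.
.prosite_regex <- function(pp) {
  frag <- vapply(pp$elements, function(el) {
    cls <- if (length(el$allowed) == 20L) {
      "."
    } else if (length(el$allowed) == 1L) {
      el$allowed
    } else if (length(el$allowed) > 10L) {
      paste0("[^", paste(setdiff(AA_STANDARD, el$allowed), collapse = ""), "]")
    } else {
      paste0("[", paste(el$allowed, collapse = ""), "]")
    }
    rep <- if (el$min == 1L && el$max == 1L) {
      ""
    } else if (el$min == el$max) {
      paste0("{", el$min, "}")
    } else {
      paste0("{", el$min, ",", el$max, "}?")
    }
    paste0(cls, rep)
  }, character(1L))
  paste0(if (pp$anchor_start) "^", paste(frag, collapse = ""),
         if (pp$anchor_end) "$")
}

#' Scan a sequence for PROSITE motif matches
#'
#' Under the default `all_starts` mode every start position whose window
#' satisfies the pattern yields one hit; variable-range elements are matched
#' shortest-first, so the reported span is the shortest satisfying window at
#' that start. Under `non_overlapping`, matches are taken greedily left to
#' right and a new match may only start after the previous one ends.
#'
#' @param record A one-row data.frame with `protein_id` and `sequence` (as
#'   returned by [read_fasta()]), or a single sequence string.
#' @param patterns Named list of `prosite_pattern` objects (see
#'   [read_motif_file()]), or character patterns which are parsed on the fly.
#' @param overlap `"all_starts"` (default) or `"non_overlapping"`.
#' @return data.frame with columns `protein_id`, `motif_name`, `start`,
#'   `end`, sorted by (start, motif_name).
#' @export
scan_motifs <- function(record, patterns, overlap = c("all_starts", "non_overlapping")) {
  overlap <- match.arg(overlap)
  if (is.character(record)) {
    record <- data.frame(protein_id = "seq1", sequence = record,
                         stringsAsFactors = FALSE)
  }
  sequence <- record$sequence[1L]
  .seq_codes(sequence)  # validates
  id <- record$protein_id[1L]
  if (length(patterns) && is.null(names(patterns))) {
    names(patterns) <- paste0("motif", seq_along(patterns))
  }
  hits <- list()
  for (nm in names(patterns)) {
    pp <- patterns[[nm]]
    if (is.character(pp)) pp <- parse_prosite(pp)
    rx <- .prosite_regex(pp)
    m <- gregexpr(paste0("(?=(", rx, "))"), sequence, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
    keep <- lens > 0L
    starts <- starts[keep]; lens <- lens[keep]
    if (!length(starts)) next
    ends <- starts + lens - 1L
    if (overlap == "non_overlapping") {
      sel <- logical(length(starts))
      last_end <- 0L
      for (i in seq_along(starts)) {
        if (starts[i] > last_end) {
          sel[i] <- TRUE
          last_end <- ends[i]
        }
      }
      starts <- starts[sel]; ends <- ends[sel]
    }
    if (length(starts)) {
      hits[[nm]] <- data.frame(protein_id = id, motif_name = nm,
                               start = starts, end = ends,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(protein_id = character(), motif_name = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count oxalate-binding motif occurrences in a protein
#'
#' Total motif hits under the configured overlap mode. A protein is
#' considered oxalate-binding when its count is at least 1.
#'
#' @inheritParams scan_motifs
#' @return Integer count (>= 0).
#' @export
count_oxalate_motifs <- function(record, patterns,
                                 overlap = c("all_starts", "non_overlapping")) {
  nrow(scan_motifs(record, patterns, overlap))
}

# Fast path used by the profiling loop: counts matches of pre-compiled
# regexes in one sequence without building hit data.frames.
.count_motifs_fast <- function(sequence, regexes) {
  total <- 0L
  for (rx in regexes) {
    m <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      total <- total + sum(attr(m, "capture.length")[, 1L] > 0L)
    }
  }
  total
}
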