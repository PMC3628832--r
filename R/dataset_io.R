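#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on load. The header token before the first
#' whitespace becomes the accession; the remainder of the header (if any)
#' becomes the name. Only the 20 standard residues plus the ambiguity codes
#' X, B, Z, U, O are accepted.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A tibble with one row per record: `accession`, `name`,
#'   `sequence`, `length`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKLV"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path), class = "idp_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  accession <- sub("[[:space:]].*$", "", headers)
  name <- trimws(sub("^[^[:space:]]+", "", headers))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) {
      abort(sprintf("empty sequence for entry '%s'", headers[i]),
            class = "idp_data_error")
    }
    chars <- seq_chars(seqs[i])
    bad <- which(!chars %in% AA_ALLOWED)
    if (length(bad) > 0) {
      abort(sprintf(
        "entry '%s': non-amino-acid character '%s' at position %d",
        headers[i], chars[bad[1]], bad[1]), class = "idp_data_error")
    }
    if (!nzchar(accession[i])) {
      abort(sprintf("entry %d has an empty header", i), class = "idp_data_error")
    }
  }
  tibble(accession = unname(accession), name = unname(name),
         sequence = unname(seqs), length = nchar(unname(seqs)))
}

# ---- intervals --------------------------------------------------------------

COMPLEX_GROUPS <- c("Sm", "U1", "U2", "U5", "U4/U6", "U4/U6.U5", "Lsm", "RES",
                    "NTC", "NTC-related", "Early", "Known", "Step2",
                    "Disassembly", "CBP", "Other")

empty_intervals <- function() {
  tibble(start = integer(0), end = integer(0))
}

#' Parse a semicolon-separated interval field
#'
#' Tokens are 1-based inclusive `"start-end"` pairs. In lenient mode a token
#' with `end < start`, `start < 1`, or (when `length` is known)
#' `end > length` is moved to the flagged list; in strict mode it raises.
#'
#' @param text the raw cell text (may be `NA` or empty = no intervals).
#' @param length protein length for bounds checking, or `NA` to skip.
#' @param policy `"lenient"` or `"strict"`.
#' @return A list with `valid` (tibble `start`, `end`, sorted by start) and
#'   `flagged` (character vector of raw tokens).
#' @export
#' @examples
#' parse_intervals("15-32;7-7", length = 100)
parse_intervals <- function(text, length = NA,
                            policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(valid = empty_intervals(), flagged = character(0)))
  }
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  ok_form <- grepl("^[0-9]+-[0-9]+$", tokens)
  starts <- suppressWarnings(as.integer(sub("-.*$", "", tokens)))
  ends <- suppressWarnings(as.integer(sub("^.*-", "", tokens)))
  valid <- ok_form & starts >= 1L & ends >= starts &
    (is.na(length) | ends <= length)
  if (any(!valid) && policy == "strict") {
    abort(sprintf("malformed interval token '%s'", tokens[!valid][1]),
          class = "idp_data_error")
  }
  iv <- tibble(start = starts[valid], end = ends[valid])
  list(valid = arrange(iv, .data$start, .data$end),
       flagged = tokens[!valid])
}

#' Interval lengths
#'
#' @param intervals a data frame with integer columns `start` and `end`
#'   (1-based inclusive).
#' @return Integer vector `end - start + 1`, one per row.
#' @export
#' @examples
#' interval_length(tibble::tibble(start = c(15, 7), end = c(32, 7)))
interval_length <- function(intervals) {
  bad <- which(intervals$start < 1 | intervals$end < intervals$start)
  if (length(bad) > 0) {
    abort(sprintf("invalid interval %d-%d",
                  intervals$start[bad[1]], intervals$end[bad[1]]),
          class = "idp_data_error")
  }
  as.integer(intervals$end - intervals$start + 1L)
}

#' Do intervals overlap?
#'
#' Rows of `a` and `b` are compared pairwise (recycled if one has one row).
#' Two 1-based inclusive intervals overlap iff
#' `max(starts) <= min(ends)`; adjacency (e.g. 1-10 vs 11-20) is not overlap.
#'
#' @param a,b data frames with columns `start` and `end`.
#' @return Logical vector.
#' @export
#' @examples
#' intervals_overlap(tibble::tibble(start = 111, end = 128),
#'                   tibble::tibble(start = 122, end = 135))
intervals_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), ]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), ]
  pmax(a$start, b$start) <= pmin(a$end, b$end)
}

# ---- annotation table -------------------------------------------------------

ANNOTATION_COLUMNS <- c("accession", "protein_name", "gene_name",
                        "complex_group", "mw_kda", "length", "fit", "vlxt",
                        "foldindex", "ronn", "morfs", "aibs",
                        "human_ortholog", "pdb")

#' Read a protein annotation table
#'
#' Reads the tab-delimited per-protein annotation format: one row per
#' protein with identification (`accession`, `protein_name`, `gene_name`,
#' `complex_group`), size (`mw_kda`, `length`), four whole-protein disorder
#' content scores in `[0, 1]` (`fit`, `vlxt`, `foldindex`, `ronn`), two
#' semicolon-separated interval lists (`morfs` -- predicted molecular
#' recognition features; `aibs` -- ANCHOR-indicated binding sites), and
#' optional `human_ortholog` / `pdb` annotations.
#'
#' In lenient mode (the default) malformed interval tokens are moved to the
#' `morfs_flagged` / `aibs_flagged` columns with a warning and recorded in
#' the `validation` attribute; strict mode raises on the first problem.
#'
#' @param path path to the TSV file (header row required).
#' @param policy `"lenient"` or `"strict"`.
#' @return A tibble with one row per table line; `morfs` and `aibs` are
#'   list-columns of interval tibbles (sorted by start), `*_flagged` are
#'   list-columns of raw rejected tokens, `pdb` is a list-column of
#'   character vectors. Attribute `validation` holds a tibble of
#'   (accession, field, raw, problem, severity) records.
#' @export
#' @examples
#' rows <- spliceosome_annotation()
#' nrow(rows)
read_annotation_table <- function(path, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(sprintf("annotation table not found: '%s'", path),
          class = "idp_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation table missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "idp_data_error")
  }
  raw <- raw[ANNOTATION_COLUMNS]

  bad_group <- setdiff(unique(raw$complex_group), COMPLEX_GROUPS)
  if (length(bad_group) > 0) {
    abort(sprintf("unknown complex_group label(s): %s",
                  paste(bad_group, collapse = ", ")),
          class = "idp_data_error")
  }

  validation <- list()
  dup <- duplicated(raw$accession)
  if (any(dup)) {
    if (policy == "strict") {
      abort(sprintf("duplicate accession(s): %s",
                    paste(unique(raw$accession[dup]), collapse = ", ")),
            class = "idp_data_error")
    }
    warn(sprintf("duplicate accession(s) kept-first: %s",
                 paste(unique(raw$accession[dup]), collapse = ", ")))
    validation <- c(validation, list(tibble(
      accession = raw$accession[dup], field = "accession",
      raw = raw$accession[dup], problem = "duplicate (first kept)",
      severity = "warning")))
    raw <- raw[!dup, ]
  }

  length_int <- as.integer(raw$length)
  scores <- lapply(raw[c("fit", "vlxt", "foldindex", "ronn")], as.numeric)
  for (nm in names(scores)) {
    out_of_range <- which(!is.na(scores[[nm]]) &
                            (scores[[nm]] < 0 | scores[[nm]] > 1))
    if (length(out_of_range) > 0) {
      abort(sprintf("content score '%s' outside [0, 1] for %s", nm,
                    raw$accession[out_of_range[1]]),
            class = "idp_data_error")
    }
  }

  parse_col <- function(col, field) {
    parsed <- map2(raw[[col]], length_int,
                   function(txt, len) parse_intervals(txt, len, policy))
    flagged <- map(parsed, "flagged")
    n_flag <- map_int(flagged, length)
    if (any(n_flag > 0)) {
      idx <- which(n_flag > 0)
      warn(sprintf("%d malformed %s interval token(s) flagged (rows: %s)",
                   sum(n_flag), field,
                   paste(raw$accession[idx], collapse = ", ")))
      validation[[length(validation) + 1]] <<- bind_rows(map(idx, function(i) {
        tibble(accession = raw$accession[i], field = field,
               raw = flagged[[i]],
               problem = "malformed or out-of-bounds interval",
               severity = "warning")
      }))
    }
    list(valid = map(parsed, "valid"), flagged = flagged)
  }
  morfs_parsed <- parse_col("morfs", "morfs")
  aibs_parsed <- parse_col("aibs", "aibs")

  out <- tibble(
    accession = raw$accession,
    protein_name = raw$protein_name,
    gene_name = dplyr::coalesce(raw$gene_name, ""),
    complex_group = factor(raw$complex_group, levels = COMPLEX_GROUPS),
    mw_kda = as.numeric(raw$mw_kda),
    length = length_int,
    fit = scores$fit, vlxt = scores$vlxt,
    foldindex = scores$foldindex, ronn = scores$ronn,
    morfs = morfs_parsed$valid, aibs = aibs_parsed$valid,
    morfs_flagged = morfs_parsed$flagged, aibs_flagged = aibs_parsed$flagged,
    human_ortholog = dplyr::coalesce(raw$human_ortholog, ""),
    pdb = map(raw$pdb, function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else
        trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    })
  )
  attr(out, "validation") <- if (length(validation) > 0) {
    bind_rows(validation)
  } else {
    tibble(accession = character(0), field = character(0),
           raw = character(0), problem = character(0), severity = character(0))
  }
  out
}

#' Write an annotation table back to TSV
#'
#' Inverse of [read_annotation_table()]: interval list-columns are
#' serialized as semicolon-separated `start-end` tokens with any flagged
#' tokens appended verbatim, so a lenient read/write/read round-trip is
#' lossless.
#'
#' @param rows a tibble from [read_annotation_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(rows, path) {
  fmt_iv <- function(valid, flagged) {
    toks <- c(sprintf("%d-%d", valid$start, valid$end), flagged)
    paste(toks, collapse = ";")
  }
  flat <- tibble(
    accession = rows$accession,
    protein_name = rows$protein_name,
    gene_name = rows$gene_name,
    complex_group = as.character(rows$complex_group),
    mw_kda = rows$mw_kda,
    length = rows$length,
    fit = rows$fit, vlxt = rows$vlxt,
    foldindex = rows$foldindex, ronn = rows$ronn,
    morfs = unlist(map2(rows$morfs, rows$morfs_flagged, fmt_iv)),
    aibs = unlist(map2(rows$aibs, rows$aibs_flagged, fmt_iv)),
    human_ortholog = rows$human_ortholog,
    pdb = map_chr(rows$pdb, paste, collapse = ";")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' The packaged yeast spliceosome annotation table
#'
#' A curated annotation of 109 Saccharomyces cerevisiae spliceosomal
#' proteins: complex membership (Sm, U1, U2, U5, U4/U6, U4/U6.U5, Lsm, RES,
#' NTC, NTC-related and further functional groups), molecular weight and
#' length, whole-protein disorder content under four predictors, and
#' predicted disorder-based binding sites (alpha-MoRFs and
#' ANCHOR-indicated binding sites) as residue intervals.
#'
#' @param policy `"lenient"` (default) or `"strict"`; the printed source
#'   table contains two malformed interval tokens, so lenient is the mode
#'   that reproduces the published counts.
#' @return The annotation tibble (see [read_annotation_table()]).
#' @export
spliceosome_annotation <- function(policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  suppressWarnings(
    read_annotation_table(idp_file("yeast_spliceosome_annotation.tsv"),
                          policy = policy))
}
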