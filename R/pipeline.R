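#' Run configuration for the end-to-end pipeline
#'
#' A flat key-value configuration: input paths, analysis parameters, and an
#' output directory. Can be built in code or read from a YAML-subset file
#' with [read_run_config()]; values passed here override file values.
#'
#' @param fasta path to a FASTA file of sequences, or `NULL`.
#' @param annotation path to an annotation TSV, or `NULL`.
#' @param scores_dir directory of per-residue score files named
#'   `<accession>.txt`, or `NULL` (the sliding-window unfoldability profile
#'   is then the per-residue stage for any sequences supplied).
#' @param out_dir output directory for report files.
#' @param window_width sliding window width (odd, default 21).
#' @param threshold binarization threshold for calibrated scores (0.5).
#' @param min_len long-disordered-region cutoff (default 30).
#' @param content_low,content_high content class cutoffs (0.10, 0.30).
#' @param boundary path to a CDF boundary file, or `NULL` for the default.
#' @param seed integer seed for any stochastic stage (default 1).
#' @return An object of class `idp_run_config`.
#' @export
run_config <- function(fasta = NULL, annotation = NULL, scores_dir = NULL,
                       out_dir, window_width = 21, threshold = 0.5,
                       min_len = 30, content_low = 0.10, content_high = 0.30,
                       boundary = NULL, seed = 1) {
  for (p in c(fasta, annotation, scores_dir, boundary)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configured input does not exist: '%s'", p),
            class = "idp_config_error")
    }
  }
  window_spec(window_width)               # validates
  content_class_scheme(content_low, content_high)
  if (min_len < 1) {
    abort("`min_len` must be >= 1", class = "idp_config_error")
  }
  structure(list(fasta = fasta, annotation = annotation,
                 scores_dir = scores_dir, out_dir = out_dir,
                 window_width = as.integer(window_width),
                 threshold = threshold, min_len = as.integer(min_len),
                 content_low = content_low, content_high = content_high,
                 boundary = boundary, seed = as.integer(seed)),
            class = "idp_run_config")
}

#' @rdname run_config
#' @param path YAML-subset config file (flat keys as above).
#' @param ... overrides applied on top of the file values.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: '%s'", path),
          class = "idp_config_error")
  }
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

# atomic text write: temp file in the same directory, then rename
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the end-to-end cohort analysis
#'
#' Orchestrates the stages in analysis order -- per-residue profiles,
#' binary disorder masks, contents, CH-CDF classification, cohort
#' statistics -- over whatever inputs the configuration provides, and
#' degrades gracefully: with only an annotation table the binding-site
#' statistics are produced and profile-dependent fields are unavailable;
#' with sequences but no imported scores the sliding-window unfoldability
#' stage supplies the masks (CDF distances then need calibrated scores and
#' are skipped).
#'
#' Writes `per_protein.tsv`, `cohort.json` and `params.log` into
#' `out_dir` (atomically: temp file then rename). Reruns with the same
#' configuration produce byte-identical files.
#'
#' @param config an [run_config()] object.
#' @return The `idp_cohort_summary`, invisibly, with attribute `files`
#'   naming the written reports.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "idp_run_config")) {
    abort("`config` must come from run_config()", class = "idp_config_error")
  }
  if (is.null(config$fasta) && is.null(config$annotation)) {
    abort("configuration provides no inputs", class = "idp_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- content_class_scheme(config$content_low, config$content_high)
  window <- window_spec(config$window_width)
  boundary <- if (is.null(config$boundary)) default_cdf_boundary() else
    read_cdf_boundary(config$boundary)

  rows <- if (!is.null(config$annotation)) {
    suppressWarnings(read_annotation_table(config$annotation, "lenient"))
  }
  records <- if (!is.null(config$fasta)) read_fasta(config$fasta)

  profiles <- NULL
  masks <- NULL
  if (!is.null(records)) {
    if (!is.null(config$scores_dir)) {
      profiles <- bind_rows(map2(records$accession, records$length,
        function(acc, len) {
          import_score_profile(
            file.path(config$scores_dir, paste0(acc, ".txt")), len,
            accession = acc)
        }))
      masks <- binarize(profiles, config$threshold)
    } else {
      fip <- foldindex_profile(records, window = window)
      masks <- tibble(accession = fip$accession, threshold = 0,
                      mask = fip$mask)
    }
  }
  contents <- if (!is.null(masks)) disorder_content(masks)
  points <- if (!is.null(records) && !is.null(profiles)) {
    chcdf_points(records, profiles, boundary = boundary)
  }

  summary <- cohort_summary(rows = rows, masks = masks, points = points,
                            contents = contents, scheme = scheme,
                            min_len = config$min_len)

  per <- if (!is.null(records)) {
    out <- tibble(accession = records$accession, length = records$length)
    if (!is.null(contents)) {
      out <- left_join(out, contents, by = "accession")
      out$content_class <- as.character(classify_content(out$content, scheme))
    }
    if (!is.null(points)) {
      out <- left_join(out, mutate(points, quadrant = as.character(.data$quadrant)),
                       by = "accession")
    }
    out
  } else if (!is.null(rows)) {
    tibble(accession = rows$accession, protein_name = rows$protein_name,
           complex_group = as.character(rows$complex_group),
           length = rows$length,
           n_morfs = map_int(rows$morfs, nrow),
           n_aibs = map_int(rows$aibs, nrow))
  } else {
    abort("configuration provides no inputs", class = "idp_config_error")
  }

  per_path <- file.path(config$out_dir, "per_protein.tsv")
  tmp <- tempfile(tmpdir = config$out_dir)
  readr::write_tsv(per, tmp, progress = FALSE)
  file.rename(tmp, per_path)

  json_path <- file.path(config$out_dir, "cohort.json")
  payload <- list(n = summary$n, statistics = tidy(summary))
  if (!is.null(summary$flagged)) payload$flagged <- summary$flagged
  write_atomic(jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                                auto_unbox = TRUE, pretty = TRUE),
               json_path)

  log_path <- file.path(config$out_dir, "params.log")
  params <- config[c("window_width", "threshold", "min_len", "content_low",
                     "content_high", "seed")]
  params$boundary <- config$boundary %||% "default"
  params$inputs <- paste(c(
    if (!is.null(config$fasta)) "fasta",
    if (!is.null(config$annotation)) "annotation",
    if (!is.null(config$scores_dir)) "scores"), collapse = ",")
  write_atomic(sprintf("%s: %s", names(params),
                       map_chr(params, function(x) paste(x, collapse = " "))),
               log_path)

  attr(summary, "files") <- c(per_protein = per_path, cohort = json_path,
                              params = log_path)
  invisible(summary)
}
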