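#' Sliding-window specification
#'
#' Windows are symmetric and centered; the only edge policy is `"shrink"`:
#' near the termini the window is truncated to the residues that exist, so
#' a profile always has exactly one score per residue.
#'
#' @param width odd integer >= 3 (default 21, the conventional width for
#'   order/disorder propensity smoothing).
#' @param edge_policy only `"shrink"` is supported.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 21, edge_policy = "shrink") {
  if (!is.numeric(width) || length(width) != 1 || width < 3 || width %% 2 != 1) {
    abort("`width` must be an odd integer >= 3", class = "idp_config_error")
  }
  if (!identical(edge_policy, "shrink")) {
    abort("only the 'shrink' edge policy is supported",
          class = "idp_config_error")
  }
  structure(list(width = as.integer(width), edge_policy = edge_policy),
            class = "window_spec")
}

# shrunken symmetric window means with NA (ambiguity) exclusion.
# positions whose window holds only NA get the whole-sequence mean of the
# non-NA values; errors if the whole sequence is NA.
window_means <- function(values, width) {
  n <- length(values)
  half <- (width - 1L) %/% 2L
  ok <- !is.na(values)
  if (!any(ok)) {
    abort("sequence contains only ambiguity codes", class = "idp_data_error")
  }
  v0 <- ifelse(ok, values, 0)
  cs <- c(0, cumsum(v0))
  cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  k <- cn[hi + 1L] - cn[lo]
  s <- cs[hi + 1L] - cs[lo]
  out <- ifelse(k > 0, s / k, mean(values[ok]))
  out
}

profile_tibble <- function(accession, predictor, calibrated, scores) {
  tibble(accession = accession, predictor = predictor,
         calibrated = calibrated, scores = scores)
}

#' Windowed per-residue propensity profile
#'
#' The score at position i is the mean of the scale values over the
#' shrunken symmetric window centered at i. Ambiguity codes (X, B, Z, U, O)
#' are excluded from window means; a position whose window contains only
#' ambiguity codes receives the whole-sequence mean. The profile is marked
#' calibrated only when the scale's declared range is `[0, 1]`.
#'
#' @param records a tibble with columns `accession` and `sequence`
#'   (e.g. from [read_fasta()]).
#' @param scale a [residue_scale()].
#' @param window a [window_spec()].
#' @return A profile tibble: one row per protein with columns `accession`,
#'   `predictor`, `calibrated`, and list-column `scores` (one value per
#'   residue).
#' @export
#' @examples
#' rec <- tibble::tibble(accession = "P1", sequence = "MKLVEEDD")
#' windowed_profile(rec, scale_top_idp(), window_spec(5))
windowed_profile <- function(records, scale, window = window_spec()) {
  if (!inherits(scale, "residue_scale")) {
    abort("`scale` must be a residue_scale", class = "idp_config_error")
  }
  if (!inherits(window, "window_spec")) window <- window_spec(window)
  calibrated <- !is.null(scale$declared_range) &&
    isTRUE(all.equal(scale$declared_range, c(0, 1)))
  scores <- map(records$sequence, function(sq) {
    if (nchar(sq) == 0) {
      abort("empty sequence", class = "idp_data_error")
    }
    vals <- unname(scale$values[seq_chars(sq)])  # NA for ambiguity codes
    window_means(vals, window$width)
  })
  profile_tibble(records$accession, scale$name, calibrated, scores)
}

#' Sliding-window charge-hydropathy unfoldability profile
#'
#' For each residue the raw unfoldability over its window w is
#' `slope * <H>_w - |<R>_w| - intercept`, with `<H>_w` the mean normalized
#' hydropathy and `<R>_w` the mean net charge per residue (ambiguity codes
#' excluded from both). Negative raw values indicate disorder. The returned
#' profile stores the *negated* raw value so that, as in every other
#' profile here, higher means more disordered; the raw values and the
#' derived disorder mask (`raw < 0`) ride along as list-columns.
#'
#' @inheritParams windowed_profile
#' @param params a [ch_boundary_params()].
#' @return A profile tibble (`calibrated = FALSE`) with extra list-columns
#'   `raw` (signed unfoldability) and `mask` (logical, TRUE = disordered).
#' @export
#' @examples
#' rec <- tibble::tibble(accession = "polyE", sequence = strrep("E", 30))
#' p <- foldindex_profile(rec, window = window_spec(9))
#' p$scores[[1]][15]
foldindex_profile <- function(records, params = ch_boundary_params(),
                              window = window_spec()) {
  if (!inherits(params, "ch_boundary_params")) {
    abort("`params` must be ch_boundary_params", class = "idp_config_error")
  }
  if (!inherits(window, "window_spec")) window <- window_spec(window)
  hv <- params$hydropathy_scale$values
  cv <- params$charge_map
  raw <- map(records$sequence, function(sq) {
    if (nchar(sq) == 0) {
      abort("empty sequence", class = "idp_data_error")
    }
    chars <- seq_chars(sq)
    h <- window_means(unname(hv[chars]), window$width)
    r <- window_means(unname(cv[chars]), window$width)
    params$slope * h - abs(r) - params$intercept
  })
  out <- profile_tibble(records$accession, "foldindex", FALSE,
                        map(raw, function(x) -x))
  out$raw <- raw
  out$mask <- map(raw, function(x) x < 0)
  out
}

#' Import an externally computed per-residue score file
#'
#' Reads the de facto per-residue disorder score text layout:
#' whitespace-delimited lines `index residue score` (1-based, one line per
#' residue); blank lines and `#` comments are ignored. Scores must be
#' calibrated to `[0, 1]`.
#'
#' @param path path to the score file.
#' @param expected_length protein length the file must match.
#' @param accession accession recorded on the profile; defaults to the file
#'   name without extension.
#' @param predictor predictor label (default `"imported"`).
#' @return A one-row calibrated profile tibble.
#' @export
import_score_profile <- function(path, expected_length,
                                 accession = NULL, predictor = "imported") {
  if (!file.exists(path)) {
    abort(sprintf("score file not found: '%s'", path), class = "idp_io_error")
  }
  accession <- accession %||% sub("\\.[^.]*$", "", basename(path))
  ln_all <- readLines(path)
  keep <- !grepl("^[[:space:]]*(#|$)", ln_all)
  ln <- trimws(ln_all[keep])
  lineno <- which(keep)
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- which(map_int(parts, length) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed score line %d in '%s'", lineno[bad[1]], path),
          class = "idp_data_error")
  }
  scores <- as.numeric(map_chr(parts, 3))
  out_of_range <- which(is.na(scores) | scores < 0 | scores > 1)
  if (length(out_of_range) > 0) {
    abort(sprintf("score outside [0, 1] at line %d in '%s'",
                  lineno[out_of_range[1]], path),
          class = "idp_data_error")
  }
  if (length(scores) != expected_length) {
    abort(sprintf("score file '%s' has %d scores but expected length is %d",
                  path, length(scores), expected_length),
          class = "idp_data_error")
  }
  profile_tibble(accession, predictor, TRUE, list(scores))
}

#' Binarize calibrated profiles into disorder masks
#'
#' A residue is called disordered when its score is greater than or equal
#' to the threshold (the threshold itself counts as disordered). Only
#' calibrated profiles may be binarized against the 0.5 convention;
#' uncalibrated unfoldability profiles carry their own mask (see
#' [foldindex_profile()]), and signed propensity profiles can be binarized
#' at their natural threshold by setting `allow_uncalibrated = TRUE`.
#'
#' @param profiles a profile tibble.
#' @param threshold disorder threshold (default 0.5).
#' @param allow_uncalibrated permit binarizing uncalibrated profiles at a
#'   caller-chosen threshold (e.g. 0 for a signed scale).
#' @return A mask tibble: `accession`, `threshold`, list-column `mask`
#'   (logical, TRUE = disordered).
#' @export
#' @examples
#' prof <- tibble::tibble(accession = "P1", predictor = "demo",
#'                        calibrated = TRUE, scores = list(c(0.4, 0.5, 0.6)))
#' binarize(prof)$mask[[1]]
binarize <- function(profiles, threshold = 0.5, allow_uncalibrated = FALSE) {
  if (!allow_uncalibrated && any(!profiles$calibrated)) {
    abort(paste("cannot binarize an uncalibrated profile at a [0, 1]",
                "threshold; use the mask from foldindex_profile(), or set",
                "allow_uncalibrated = TRUE with a suitable threshold"),
          class = "idp_input_error")
  }
  masks <- map(profiles$scores, function(s) s >= threshold)
  tibble(accession = profiles$accession, threshold = threshold, mask = masks)
}

#' Disorder content of masks
#'
#' @param masks a mask tibble (see [binarize()]).
#' @return A tibble `accession`, `content` (fraction of residues called
#'   disordered, in `[0, 1]`).
#' @export
disorder_content <- function(masks) {
  if (any(map_int(masks$mask, length) == 0)) {
    abort("empty disorder mask", class = "idp_input_error")
  }
  tibble(accession = masks$accession,
         content = map_dbl(masks$mask, mean))
}

#' Long disordered regions
#'
#' Maximal runs of disordered residues of at least `min_len` residues, as
#' 1-based inclusive intervals. A run of 30+ consecutive predicted
#' disordered residues is the conventional cohort-level disorder indicator.
#'
#' @param masks a mask tibble (see [binarize()]).
#' @param min_len minimum run length (default 30).
#' @return A tibble `accession`, `start`, `end`, one row per region,
#'   sorted within each protein. Proteins without qualifying runs
#'   contribute no rows.
#' @export
#' @examples
#' m <- tibble::tibble(accession = "P1", threshold = 0.5,
#'                     mask = list(c(rep(FALSE, 5), rep(TRUE, 35), FALSE)))
#' long_disordered_regions(m)
long_disordered_regions <- function(masks, min_len = 30) {
  if (!is.numeric(min_len) || min_len < 1) {
    abort("`min_len` must be >= 1", class = "idp_config_error")
  }
  per <- map2(masks$accession, masks$mask, function(acc, m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    tibble(accession = acc, start = starts[keep], end = ends[keep])
  })
  bind_rows(per)
}
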