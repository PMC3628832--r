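#' Disorder content class scheme
#'
#' Whole-protein disorder content is conventionally classed as highly
#' ordered (content below the low cutoff), moderately disordered (between
#' the cutoffs, both boundary values assigned to this middle class) and
#' highly disordered (above the high cutoff).
#'
#' @param low,high class cutoffs, `0 < low < high < 1` (defaults 0.10 and
#'   0.30).
#' @return An object of class `content_class_scheme`.
#' @export
content_class_scheme <- function(low = 0.10, high = 0.30) {
  if (!(low > 0 && low < high && high < 1)) {
    abort("need 0 < low < high < 1", class = "idp_config_error")
  }
  structure(list(low = low, high = high,
                 labels = c("highly_ordered", "moderately_disordered",
                            "highly_disordered")),
            class = "content_class_scheme")
}

#' Classify disorder content fractions
#'
#' @param fraction numeric vector of contents in `[0, 1]`.
#' @param scheme a [content_class_scheme()].
#' @return Factor with the scheme's three labels.
#' @export
#' @examples
#' classify_content(c(0.05, 0.10, 0.31))
classify_content <- function(fraction, scheme = content_class_scheme()) {
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1)) {
    abort("content fractions must lie in [0, 1]", class = "idp_input_error")
  }
  lab <- ifelse(fraction < scheme$low, scheme$labels[1],
                ifelse(fraction <= scheme$high, scheme$labels[2],
                       scheme$labels[3]))
  factor(lab, levels = scheme$labels)
}

#' Prevalence of long disordered regions in a cohort
#'
#' @param masks a mask tibble (see [binarize()]).
#' @param min_len minimum run length (default 30).
#' @return Percentage of proteins carrying at least one disordered run of
#'   `min_len`+ residues, rounded to one decimal.
#' @export
long_region_prevalence <- function(masks, min_len = 30) {
  if (nrow(masks) == 0) {
    abort("empty mask cohort", class = "idp_input_error")
  }
  regions <- long_disordered_regions(masks, min_len = min_len)
  carriers <- length(unique(regions$accession))
  round_half_up(100 * carriers / nrow(masks), 1)
}

#' Binding-site interval statistics for an annotated cohort
#'
#' Counts predicted disorder-based binding sites (MoRFs or
#' ANCHOR-indicated binding sites) over the valid intervals of a leniently
#' loaded annotation table; flagged (malformed) intervals are excluded.
#'
#' @param rows an annotation tibble (see [read_annotation_table()]).
#' @param which `"morfs"` or `"aibs"`.
#' @return A one-row tibble: `which`, `n` (cohort size), `n_with_any`,
#'   `total_intervals`, `mean_per_protein`, `mean_per_carrier` (NA when no
#'   carriers), `percent_with_any` (integer, rounded half away from zero).
#' @export
#' @examples
#' interval_stats(spliceosome_annotation(), "aibs")$n_with_any
interval_stats <- function(rows, which = c("morfs", "aibs")) {
  which <- match.arg(which)
  if (nrow(rows) == 0) {
    abort("empty cohort", class = "idp_input_error")
  }
  per <- map_int(rows[[which]], nrow)
  n <- nrow(rows)
  n_with <- sum(per > 0)
  total <- sum(per)
  tibble(which = which, n = n, n_with_any = n_with, total_intervals = total,
         mean_per_protein = total / n,
         mean_per_carrier = if (n_with > 0) total / n_with else NA_real_,
         percent_with_any = as.integer(round_half_up(100 * n_with / n)))
}

#' Quadrant occupancy fractions
#'
#' @param points a CH-CDF point tibble (see [chcdf_points()]).
#' @return A tibble `quadrant` (Q1-Q4), `n`, `fraction`; attribute
#'   `mostly_disordered` carries the combined Q3+Q4 fraction (CDF-called
#'   disorder, i.e. molten-globular plus extended disorder).
#' @export
quadrant_fractions <- function(points) {
  if (nrow(points) == 0) {
    abort("empty point set", class = "idp_input_error")
  }
  counts <- table(points$quadrant)
  out <- tibble(quadrant = factor(names(counts), levels = names(counts)),
                n = as.integer(counts),
                fraction = as.numeric(counts) / nrow(points))
  structure(out,
            mostly_disordered = sum(out$fraction[out$quadrant %in% c("Q3", "Q4")]))
}

#' Cohort-level disorder summary
#'
#' Aggregates the cohort statistics into one report: content class counts,
#' long-disordered-region prevalence, CH-CDF quadrant fractions, binding-
#' site interval statistics, and per-complex-group breakdowns. Any input
#' may be omitted; the dependent fields are then `NULL` (reported as
#' unavailable). All supplied per-protein inputs must agree on accessions.
#'
#' @param rows annotation tibble (drives interval stats and grouping), or
#'   `NULL`.
#' @param masks mask tibble (drives long-region prevalence), or `NULL`.
#' @param points CH-CDF point tibble, or `NULL`.
#' @param contents tibble `accession`, `content` (drives content classes),
#'   or `NULL`.
#' @param scheme a [content_class_scheme()].
#' @param min_len long-region cutoff (default 30).
#' @return An object of class `idp_cohort_summary`.
#' @export
cohort_summary <- function(rows = NULL, masks = NULL, points = NULL,
                           contents = NULL, scheme = content_class_scheme(),
                           min_len = 30) {
  inputs <- list(masks = masks, points = points, contents = contents)
  inputs <- inputs[!map_lgl(inputs, is.null)]
  if (length(inputs) >= 2) {
    accs <- map(inputs, function(x) sort(x$accession))
    for (i in seq_along(accs)[-1]) {
      if (!identical(accs[[1]], accs[[i]])) {
        off <- c(setdiff(accs[[1]], accs[[i]]), setdiff(accs[[i]], accs[[1]]))
        abort(sprintf("accession mismatch between %s and %s: %s",
                      names(accs)[1], names(accs)[i],
                      paste(off, collapse = ", ")),
              class = "idp_input_error")
      }
    }
  }
  n <- if (!is.null(rows)) nrow(rows) else if (length(inputs) > 0)
    nrow(inputs[[1]]) else
      abort("no inputs supplied", class = "idp_input_error")

  content_classes <- NULL
  if (!is.null(contents)) {
    cls <- classify_content(contents$content, scheme)
    tab <- table(cls)
    content_classes <- tibble(class = factor(names(tab), levels = names(tab)),
                              n = as.integer(tab),
                              fraction = as.integer(tab) / length(cls))
  }
  structure(list(
    n = n,
    content_classes = content_classes,
    long_region_prevalence =
      if (!is.null(masks)) long_region_prevalence(masks, min_len) else NULL,
    min_len = min_len,
    quadrants = if (!is.null(points)) quadrant_fractions(points) else NULL,
    mostly_disordered = if (!is.null(points))
      attr(quadrant_fractions(points), "mostly_disordered") else NULL,
    morf_stats = if (!is.null(rows)) interval_stats(rows, "morfs") else NULL,
    aibs_stats = if (!is.null(rows)) interval_stats(rows, "aibs") else NULL,
    by_complex = if (!is.null(rows)) {
      dplyr::count(rows, .data$complex_group, name = "n_proteins",
                   .drop = FALSE)
    } else NULL,
    flagged = if (!is.null(rows)) {
      tibble(morfs_flagged = sum(map_int(rows$morfs_flagged, length)),
             aibs_flagged = sum(map_int(rows$aibs_flagged, length)))
    } else NULL,
    scheme = scheme
  ), class = "idp_cohort_summary")
}

#' @export
print.idp_cohort_summary <- function(x, ...) {
  cat(sprintf("<idp_cohort_summary> %d proteins\n", x$n))
  if (!is.null(x$content_classes)) {
    cc <- x$content_classes
    cat("  content classes:",
        paste(sprintf("%s=%d", cc$class, cc$n), collapse = ", "), "\n")
  }
  if (!is.null(x$long_region_prevalence)) {
    cat(sprintf("  long (>=%d) disordered region carriers: %.1f%%\n",
                x$min_len, x$long_region_prevalence))
  }
  if (!is.null(x$quadrants)) {
    q <- x$quadrants
    cat("  CH-CDF quadrants:",
        paste(sprintf("%s=%.1f%%", q$quadrant, 100 * q$fraction),
              collapse = ", "),
        sprintf("(Q3+Q4 = %.1f%%)\n", 100 * x$mostly_disordered))
  }
  for (w in c("morf_stats", "aibs_stats")) {
    if (!is.null(x[[w]])) {
      s <- x[[w]]
      cat(sprintf("  %s: %d/%d carriers (%d%%), %d intervals\n",
                  s$which, s$n_with_any, s$n, s$percent_with_any,
                  s$total_intervals))
    }
  }
  invisible(x)
}

#' @method tidy idp_cohort_summary
#' @export
tidy.idp_cohort_summary <- function(x, ...) {
  parts <- list()
  if (!is.null(x$content_classes)) {
    parts[[1]] <- tibble(statistic = paste0("content_", x$content_classes$class),
                         value = as.numeric(x$content_classes$n))
  }
  if (!is.null(x$long_region_prevalence)) {
    parts[[length(parts) + 1]] <-
      tibble(statistic = "long_region_prevalence_pct",
             value = x$long_region_prevalence)
  }
  if (!is.null(x$quadrants)) {
    parts[[length(parts) + 1]] <-
      tibble(statistic = paste0("fraction_", x$quadrants$quadrant),
             value = x$quadrants$fraction)
  }
  for (w in c("morf_stats", "aibs_stats")) {
    if (!is.null(x[[w]])) {
      s <- x[[w]]
      parts[[length(parts) + 1]] <- tibble(
        statistic = paste0(s$which, c("_carriers", "_total", "_percent")),
        value = c(s$n_with_any, s$total_intervals, s$percent_with_any))
    }
  }
  bind_rows(parts)
}

#' @method glance idp_cohort_summary
#' @export
glance.idp_cohort_summary <- function(x, ...) {
  tibble(n = x$n,
         morf_percent = if (is.null(x$morf_stats)) NA_integer_ else
           x$morf_stats$percent_with_any,
         aibs_percent = if (is.null(x$aibs_stats)) NA_integer_ else
           x$aibs_stats$percent_with_any,
         long_region_prevalence = x$long_region_prevalence %||% NA_real_,
         mostly_disordered = x$mostly_disordered %||% NA_real_)
}
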