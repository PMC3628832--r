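#' Pooled amino-acid composition of a protein set
#'
#' Residue counts are pooled over all sequences (the set, not each protein,
#' is the unit) and normalized. Ambiguity codes are excluded from counts.
#'
#' @param records a tibble with a `sequence` column.
#' @return A tibble of class `idp_composition`: `residue` (factor over the
#'   20 standard residues), `count`, `fraction`; attribute `total` holds
#'   the pooled residue count.
#' @export
#' @examples
#' composition(tibble::tibble(sequence = c("AAAA", "ACDE")))
composition <- function(records) {
  if (nrow(records) == 0) {
    abort("need at least one protein record", class = "idp_input_error")
  }
  chars <- unlist(strsplit(records$sequence, "", fixed = TRUE))
  chars <- chars[chars %in% AA_STANDARD]
  if (length(chars) == 0) {
    abort("no standard residues in the record set", class = "idp_data_error")
  }
  counts <- table(factor(chars, levels = AA_STANDARD))
  out <- tibble(residue = factor(AA_STANDARD, levels = AA_STANDARD),
                count = as.integer(counts),
                fraction = as.numeric(counts) / sum(counts))
  structure(out, class = c("idp_composition", class(out)),
            total = length(chars))
}

as_composition <- function(x, what) {
  if (inherits(x, "idp_composition")) return(x)
  if (is.data.frame(x) && "sequence" %in% names(x)) return(composition(x))
  abort(sprintf("`%s` must be an idp_composition or a record tibble", what),
        class = "idp_input_error")
}

#' Fractional-difference composition profile
#'
#' For each residue X, the fractional difference between a query set and a
#' reference set is `(C_X - C_ref) / C_ref`, where `C_X` is the residue's
#' fraction in the query and `C_ref` its fraction in the reference.
#' The difference is 0 when the fractions match and exactly -1 when the
#' residue is absent from the query; residues with zero reference fraction
#' are reported as `NA` with a warning rather than as infinities.
#'
#' @param query,reference `idp_composition` objects (or record tibbles,
#'   which are pooled first).
#' @param order residue display order (a permutation of the 20 standard
#'   residues; default the packaged disorder-propensity ranking).
#' @return A tibble of class `idp_comp_profile`: `residue` (factor in
#'   display order), `query_fraction`, `reference_fraction`, `difference`.
#' @export
#' @examples
#' q <- composition(tibble::tibble(sequence = "ACDEFGHIKLMNPQRSTVWY"))
#' fractional_difference(q, q)$difference
fractional_difference <- function(query, reference, order = residue_order()) {
  q <- as_composition(query, "query")
  r <- as_composition(reference, "reference")
  qf <- setNames(q$fraction, as.character(q$residue))[AA_STANDARD]
  rf <- setNames(r$fraction, as.character(r$residue))[AA_STANDARD]
  diff <- ifelse(rf > 0, (qf - rf) / rf, NA_real_)
  if (any(rf == 0)) {
    warn(sprintf("zero reference fraction for %s: difference undefined",
                 paste(AA_STANDARD[rf == 0], collapse = ", ")))
  }
  out <- tibble(residue = factor(AA_STANDARD, levels = order),
                query_fraction = unname(qf),
                reference_fraction = unname(rf),
                difference = unname(diff))
  out <- arrange(out, .data$residue)
  structure(out, class = c("idp_comp_profile", class(out)),
            n_query = attr(q, "total"), n_boot = NA_integer_)
}

# per-protein residue count matrix (proteins x 20)
count_matrix <- function(records) {
  t(vapply(records$sequence, function(sq) {
    chars <- seq_chars(sq)
    chars <- chars[chars %in% AA_STANDARD]
    as.integer(table(factor(chars, levels = AA_STANDARD)))
  }, integer(20L), USE.NAMES = FALSE))
}

#' Bootstrap composition profile with confidence intervals
#'
#' Resamples *proteins* (not residues) with replacement within the query
#' set, recomputes the pooled fractional-difference profile per replicate,
#' and attaches percentile confidence intervals per residue. The protein is
#' the sampling unit because cohort membership, not residue identity, is
#' what varies between studies. Deterministic given `seed`.
#'
#' @param query_records a record tibble with >= 2 proteins.
#' @param reference an `idp_composition` (or record tibble).
#' @param n_boot number of bootstrap replicates (default 10000; a warning
#'   is issued below 100).
#' @param seed integer seed (required).
#' @param conf confidence level (default 0.95).
#' @inheritParams fractional_difference
#' @return An `idp_comp_profile` tibble with extra columns `ci_lo`, `ci_hi`.
#' @export
bootstrap_profile <- function(query_records, reference, n_boot = 10000,
                              seed, conf = 0.95, order = residue_order()) {
  if (nrow(query_records) < 2) {
    abort("bootstrap needs at least 2 query proteins",
          class = "idp_input_error")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is required for a reproducible bootstrap",
          class = "idp_input_error")
  }
  if (n_boot < 100) {
    warn(sprintf("n_boot = %d is very small; intervals will be unstable",
                 n_boot))
  }
  r <- as_composition(reference, "reference")
  rf <- setNames(r$fraction, as.character(r$residue))[AA_STANDARD]
  point <- fractional_difference(query_records, r, order = order)

  m <- count_matrix(query_records)
  n <- nrow(m)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      q <- colSums(m[idx, , drop = FALSE])
      q <- q / sum(q)
      ifelse(rf > 0, (q - rf) / rf, NA_real_)
    }, numeric(20L))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(reps, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = FALSE,
              names = FALSE)
  key <- match(AA_STANDARD, as.character(point$residue))
  point$ci_lo <- NA_real_
  point$ci_hi <- NA_real_
  point$ci_lo[key] <- ci[1, ]
  point$ci_hi[key] <- ci[2, ]
  attr(point, "n_boot") <- as.integer(n_boot)
  attr(point, "seed") <- as.integer(seed)
  attr(point, "conf") <- conf
  point
}

#' @method tidy idp_comp_profile
#' @export
tidy.idp_comp_profile <- function(x, ...) {
  as_tibble(x)
}

#' @method glance idp_comp_profile
#' @export
glance.idp_comp_profile <- function(x, ...) {
  tibble(n_query_residues = attr(x, "n_query") %||% NA_integer_,
         n_boot = attr(x, "n_boot") %||% NA_integer_,
         n_enriched = sum(x$difference > 0, na.rm = TRUE),
         n_depleted = sum(x$difference < 0, na.rm = TRUE))
}
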