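#' Whole-protein charge-hydropathy (CH-plot) classification
#'
#' Places each protein on the charge-hydropathy plane: mean normalized
#' hydropathy `<H>` against mean absolute net charge per residue `|<R>|`,
#' both over the full sequence with ambiguity codes excluded. The signed
#' vertical distance to the boundary line,
#' `dch = |<R>| - (slope * <H> - intercept)`, is positive on the
#' natively-unfolded (disordered) side. `dch` equals the negated
#' single-window unfoldability of [foldindex_profile()] for the same
#' sequence, which the test-suite exploits as an exact cross-check.
#'
#' @param records a tibble with columns `accession` and `sequence`.
#' @param params a [ch_boundary_params()].
#' @return A tibble `accession`, `mean_hydropathy`, `mean_abs_net_charge`,
#'   `dch`, `ch_call` (`"disordered"` iff `dch > 0`).
#' @export
#' @examples
#' ch_point(tibble::tibble(accession = "polyK", sequence = strrep("K", 50)))
ch_point <- function(records, params = ch_boundary_params()) {
  if (!inherits(params, "ch_boundary_params")) {
    abort("`params` must be ch_boundary_params", class = "idp_config_error")
  }
  hv <- params$hydropathy_scale$values
  cv <- params$charge_map
  stats <- map(records$sequence, function(sq) {
    chars <- seq_chars(sq)
    chars <- chars[chars %in% AA_STANDARD]
    if (length(chars) == 0) {
      abort("sequence contains only ambiguity codes", class = "idp_data_error")
    }
    c(h = mean(hv[chars]), r = mean(cv[chars]))
  })
  h <- map_dbl(stats, "h")
  r <- map_dbl(stats, "r")
  dch <- abs(r) - (params$slope * h - params$intercept)
  tibble(accession = records$accession,
         mean_hydropathy = h,
         mean_abs_net_charge = abs(r),
         dch = dch,
         ch_call = ifelse(dch > 0, "disordered", "ordered"))
}

#' Cumulative distribution function (CDF) classification
#'
#' For each calibrated profile, the cumulative fraction
#' `F(t) = fraction of residues with score <= t` is evaluated at the
#' boundary thresholds. `dcdf` is the unweighted mean of the signed
#' vertical distances `F(t) - boundary_fraction(t)`; positive `dcdf` means
#' the curve runs above the boundary, i.e. the ordered side. The binary
#' call is by strict majority of boundary points (`F(t) >
#' boundary_fraction(t)` at more than half of the points = ordered); near
#' the boundary the majority call and the sign of `dcdf` can disagree,
#' which is why both are reported.
#'
#' @param profiles a calibrated profile tibble.
#' @param boundary a [cdf_boundary()].
#' @return A tibble `accession`, `dcdf`, `majority_call`, and list-column
#'   `curve` (per-threshold tibble of `threshold`, `fraction`,
#'   `boundary_fraction`).
#' @export
#' @examples
#' prof <- tibble::tibble(accession = "P1", predictor = "demo",
#'                        calibrated = TRUE, scores = list(rep(0, 10)))
#' cdf_curve(prof)$dcdf > 0
cdf_curve <- function(profiles, boundary = default_cdf_boundary()) {
  if (!inherits(boundary, "cdf_boundary")) {
    abort("`boundary` must be a cdf_boundary", class = "idp_config_error")
  }
  if (any(!profiles$calibrated)) {
    abort("CDF analysis needs calibrated profiles (scores in [0, 1])",
          class = "idp_input_error")
  }
  th <- boundary$threshold
  bf <- boundary$boundary_fraction
  res <- map(profiles$scores, function(s) {
    f <- map_dbl(th, function(t) mean(s <= t))
    list(curve = tibble(threshold = th, fraction = f, boundary_fraction = bf),
         dcdf = mean(f - bf),
         call = if (sum(f > bf) > length(th) / 2) "ordered" else "disordered")
  })
  tibble(accession = profiles$accession,
         dcdf = map_dbl(res, "dcdf"),
         majority_call = map_chr(res, "call"),
         curve = map(res, "curve"))
}

#' CH-CDF quadrant assignment
#'
#' The CH-CDF phase space plots `dcdf` (x, positive = ordered by CDF)
#' against `dch` (y, positive = disordered by CH-plot). Quadrants:
#' Q1 disordered by CH only (y > 0, x > 0); Q2 ordered by both
#' (y <= 0, x > 0); Q3 disordered by CDF only -- putative molten globules
#' or mixed proteins (y <= 0, x <= 0); Q4 disordered by both -- extended
#' disorder (y > 0, x <= 0). Exact zeros fall to the ordered side of each
#' axis, so (0, +) is Q2 and (0, 0) is Q3.
#'
#' @param dch,dcdf finite numeric vectors (recycled to a common length).
#' @return Factor with levels Q1-Q4.
#' @export
#' @examples
#' quadrant(dch = c(0.2, -0.2), dcdf = c(-0.1, 0.1))
quadrant <- function(dch, dcdf) {
  n <- max(length(dch), length(dcdf))
  dch <- rep_len(dch, n)
  dcdf <- rep_len(dcdf, n)
  if (any(!is.finite(dch)) || any(!is.finite(dcdf))) {
    abort("quadrant() needs finite dch and dcdf", class = "idp_input_error")
  }
  q <- ifelse(dcdf > 0,
              ifelse(dch > 0, "Q1", "Q2"),
              ifelse(dch > 0, "Q4", "Q3"))
  factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Combined CH-CDF points for a cohort
#'
#' Joins the CH-plot coordinates of the sequences with the CDF distances of
#' their calibrated score profiles and assigns each protein its quadrant.
#'
#' @param records a tibble with `accession` and `sequence`.
#' @param profiles a calibrated profile tibble matching the records by
#'   accession.
#' @param params a [ch_boundary_params()].
#' @param boundary a [cdf_boundary()].
#' @return A tibble `accession`, `dcdf`, `dch`, `quadrant`.
#' @export
chcdf_points <- function(records, profiles, params = ch_boundary_params(),
                         boundary = default_cdf_boundary()) {
  ch <- ch_point(records, params)
  cdf <- cdf_curve(profiles, boundary)
  missing_acc <- setdiff(records$accession, profiles$accession)
  if (length(missing_acc) > 0) {
    abort(sprintf("no profile for: %s", paste(missing_acc, collapse = ", ")),
          class = "idp_input_error")
  }
  pts <- left_join(select(ch, "accession", "dch"),
                   select(cdf, "accession", "dcdf"), by = "accession")
  mutate(select(pts, "accession", "dcdf", "dch"),
         quadrant = quadrant(.data$dch, .data$dcdf))
}
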