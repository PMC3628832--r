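#' Amino-acid propensity scales and classifier boundary parameters
#'
#' A residue scale assigns one real number to each of the 20 standard amino
#' acids. Scales drive windowed per-residue profiles and the
#' charge-hydropathy math; they are deliberately plain lists so that every
#' number is visible and swappable from a config file.
#'
#' @param name scale label carried into profiles built from it.
#' @param values named numeric vector covering all 20 standard residues.
#' @param declared_range length-2 numeric `(min, max)` bracketing the values,
#'   or `NULL` for an unbounded scale. A `[0, 1]` declared range marks
#'   profiles built from the scale as calibrated.
#' @param higher_means `"order"` or `"disorder"`: the direction of the scale.
#' @return An object of class `residue_scale`.
#' @export
#' @examples
#' sc <- residue_scale("toy", setNames(seq(0, 1, length.out = 20),
#'                                     idpcohort:::AA_STANDARD),
#'                     declared_range = c(0, 1), higher_means = "disorder")
#' sc$values[["A"]]
residue_scale <- function(name, values, declared_range = NULL,
                          higher_means = c("disorder", "order")) {
  higher_means <- match.arg(higher_means)
  stopifnot_scalar_chr(name, "name")
  missing_res <- setdiff(AA_STANDARD, names(values))
  if (length(missing_res) > 0) {
    abort(sprintf("scale '%s' is missing standard residues: %s",
                  name, paste(missing_res, collapse = ", ")),
          class = "idp_config_error")
  }
  values <- values[AA_STANDARD]
  if (!is.null(declared_range)) {
    if (length(declared_range) != 2 || declared_range[1] > declared_range[2]) {
      abort("`declared_range` must be (min, max) with min <= max",
            class = "idp_config_error")
    }
    if (any(values < declared_range[1] - 1e-12) ||
        any(values > declared_range[2] + 1e-12)) {
      abort(sprintf("scale '%s' has values outside its declared range", name),
            class = "idp_config_error")
    }
  }
  structure(list(name = name, values = values,
                 declared_range = declared_range, higher_means = higher_means),
            class = "residue_scale")
}

#' @export
print.residue_scale <- function(x, ...) {
  rng <- if (is.null(x$declared_range)) "unbounded" else
    sprintf("[%g, %g]", x$declared_range[1], x$declared_range[2])
  cat(sprintf("<residue_scale> %s (higher = %s, range %s)\n",
              x$name, x$higher_means, rng))
  invisible(x)
}

#' Read a residue scale from a YAML config file
#'
#' Config layout: keys `name`, `higher_means`, optional `declared_range`
#' (2-element list) and a `values` map of residue -> number.
#'
#' @param path path to the YAML file.
#' @return A [residue_scale()].
#' @export
read_residue_scale <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scale config not found: '%s'", path), class = "idp_io_error")
  }
  cfg <- yaml::read_yaml(path)
  rng <- if (is.null(cfg$declared_range)) NULL else as.numeric(unlist(cfg$declared_range))
  residue_scale(cfg$name, unlist(cfg$values), declared_range = rng,
                higher_means = cfg$higher_means)
}

#' Built-in scales
#'
#' `scale_kyte_doolittle()` is the Kyte-Doolittle hydropathy scale min-max
#' normalized to `[0, 1]` (raw value + 4.5, divided by 9); higher = more
#' hydrophobic, i.e. order-prone. `scale_top_idp()` is the signed TOP-IDP
#' order-disorder propensity scale; higher = more disorder-prone, with 0 the
#' natural threshold.
#'
#' @return A [residue_scale()].
#' @export
scale_kyte_doolittle <- function() {
  read_residue_scale(idp_file("config", "scale_kyte_doolittle.yml"))
}

#' @rdname scale_kyte_doolittle
#' @export
scale_top_idp <- function() {
  read_residue_scale(idp_file("config", "scale_top_idp.yml"))
}

#' Charge-hydropathy boundary parameters
#'
#' The CH-plot boundary is the line `|<R>| = slope * <H> - intercept` in
#' (mean normalized hydropathy, mean absolute net charge) space; proteins
#' above the line are predicted natively unfolded. The same constants drive
#' the sliding-window unfoldability profile ([foldindex_profile()]).
#'
#' @param slope,intercept boundary line coefficients (defaults 2.785, 1.151).
#' @param hydropathy_scale a [residue_scale()] with values in `[0, 1]`.
#' @param charge_map named numeric vector of per-residue formal charges;
#'   residues absent from the map count as 0.
#' @return An object of class `ch_boundary_params`.
#' @export
#' @examples
#' p <- ch_boundary_params()
#' p$slope
ch_boundary_params <- function(slope = NULL, intercept = NULL,
                               hydropathy_scale = NULL, charge_map = NULL) {
  cfg <- yaml::read_yaml(idp_file("config", "ch_boundary.yml"))
  slope <- slope %||% cfg$slope
  intercept <- intercept %||% cfg$intercept
  hydropathy_scale <- hydropathy_scale %||% scale_kyte_doolittle()
  charge_map <- charge_map %||% unlist(cfg$charge)
  if (!is.numeric(slope) || slope <= 0) {
    abort("`slope` must be a positive number", class = "idp_config_error")
  }
  if (!inherits(hydropathy_scale, "residue_scale")) {
    abort("`hydropathy_scale` must be a residue_scale", class = "idp_config_error")
  }
  hv <- hydropathy_scale$values
  if (any(hv < -1e-12) || any(hv > 1 + 1e-12)) {
    abort("hydropathy scale must be normalized to [0, 1]",
          class = "idp_config_error")
  }
  charge <- setNames(rep(0, length(AA_STANDARD)), AA_STANDARD)
  charge[names(charge_map)] <- charge_map
  structure(list(slope = slope, intercept = intercept,
                 hydropathy_scale = hydropathy_scale, charge_map = charge),
            class = "ch_boundary_params")
}

#' Cumulative distribution function (CDF) boundary
#'
#' A CDF boundary is an increasing set of (score threshold, boundary
#' fraction) points. A protein whose per-residue score CDF runs above the
#' boundary at most points is called ordered; below, disordered.
#'
#' @param thresholds strictly increasing score thresholds in `[0, 1]`
#'   (at least 3).
#' @param fractions boundary fractions in `[0, 1]`, one per threshold.
#' @param source label recorded on the object.
#' @return An object of class `cdf_boundary`: a tibble with columns
#'   `threshold` and `boundary_fraction`.
#' @export
#' @examples
#' cdf_boundary(c(0.2, 0.5, 0.8), c(0.3, 0.5, 0.7))
cdf_boundary <- function(thresholds, fractions, source = "custom") {
  if (length(thresholds) < 3) {
    abort("a CDF boundary needs at least 3 points", class = "idp_config_error")
  }
  if (any(diff(thresholds) <= 0)) {
    abort("CDF boundary thresholds must be strictly increasing",
          class = "idp_config_error")
  }
  if (length(fractions) != length(thresholds)) {
    abort("`fractions` must match `thresholds` in length",
          class = "idp_config_error")
  }
  if (any(thresholds < 0 | thresholds > 1) || any(fractions < 0 | fractions > 1)) {
    abort("CDF boundary points must lie in [0, 1]", class = "idp_config_error")
  }
  out <- tibble(threshold = as.numeric(thresholds),
                boundary_fraction = as.numeric(fractions))
  structure(out, class = c("cdf_boundary", class(out)), source = source)
}

#' Read a CDF boundary from a config file
#'
#' Plain-text layout: lines `threshold boundary_fraction`; blank lines and
#' `#` comments ignored.
#'
#' @param path path to the boundary file.
#' @return A [cdf_boundary()].
#' @export
read_cdf_boundary <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("CDF boundary file not found: '%s'", path),
          class = "idp_io_error")
  }
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- which(map_int(parts, length) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("malformed boundary line %d in '%s'", bad[1], path),
          class = "idp_io_error")
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  cdf_boundary(m[, 1], m[, 2], source = basename(path))
}

#' @rdname read_cdf_boundary
#' @export
default_cdf_boundary <- function() {
  read_cdf_boundary(idp_file("config", "cdf_boundary_default.txt"))
}

#' Packaged reference amino-acid compositions
#'
#' Synthetic stand-ins for curated ordered (folded, PDB-like) and disordered
#' (IDP-database-like) reference sets: average proteome frequencies biased
#' toward order-promoting residues (C, W, I, Y, F, L, H, V, N, M) for the
#' ordered reference and toward disorder-promoting residues
#' (A, G, R, T, S, K, Q, E, P, D) for the disordered one. They are config
#' files, so a curated reference can be dropped in without code changes.
#'
#' @param which `"ordered"` or `"disordered"`.
#' @return A composition tibble as returned by [composition()].
#' @export
reference_composition <- function(which = c("ordered", "disordered")) {
  which <- match.arg(which)
  read_composition_file(
    idp_file("config", sprintf("composition_%s_synthetic.txt", which)))
}

#' Read a composition file
#'
#' Layout: 20 lines `residue fraction`; `#` comments and blank lines ignored.
#'
#' @param path path to the composition file.
#' @return A composition tibble (columns `residue`, `fraction`) normalized
#'   to sum to 1, with attribute `total = NA` (counts unknown).
#' @export
read_composition_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("composition file not found: '%s'", path),
          class = "idp_io_error")
  }
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[[:space:]]+")
  res <- map_chr(parts, 1)
  frac <- as.numeric(map_chr(parts, 2))
  missing_res <- setdiff(AA_STANDARD, res)
  if (length(missing_res) > 0) {
    abort(sprintf("composition file '%s' missing residues: %s", path,
                  paste(missing_res, collapse = ", ")),
          class = "idp_config_error")
  }
  frac <- setNames(frac, res)[AA_STANDARD]
  frac <- frac / sum(frac)
  out <- tibble(residue = factor(AA_STANDARD, levels = AA_STANDARD),
                fraction = as.numeric(frac))
  structure(out, class = c("idp_composition", class(out)), total = NA_integer_)
}

#' Residue display order for composition profiles
#'
#' The packaged default ranks the 20 residues by increasing
#' disorder-promoting potential (TOP-IDP ordering), so composition profiles
#' read order-promoting left to disorder-promoting right.
#'
#' @param path optional path to a file with one residue per line
#'   (`#` comments ignored); default uses the packaged ordering.
#' @return Character vector: a permutation of the 20 standard residues.
#' @export
residue_order <- function(path = NULL) {
  path <- path %||% idp_file("config", "residue_order.txt")
  ln <- trimws(sub("#.*$", "", readLines(path)))
  ln <- ln[nzchar(ln)]
  if (!setequal(ln, AA_STANDARD) || length(ln) != 20) {
    abort("residue order must be a permutation of the 20 standard residues",
          class = "idp_config_error")
  }
  ln
}
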