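#' Specification for a synthetic two-state protein cohort
#'
#' The generator emulates the statistical structure that cohort-level
#' disorder analysis assumes: proteins are alternating ordered/disordered
#' segments (geometric segment lengths, i.e. memoryless per-residue
#' switching), residues are drawn from a state-dependent composition, and
#' each protein carries a calibrated per-residue score built from its true
#' state labels (smoothed, noised, clipped to `[0, 1]`). Every residue
#' keeps its ground-truth label, so recovery by the analysis pipeline can
#' be measured exactly.
#'
#' With mean segment lengths `Lo` (ordered) and `Ld` (disordered), the
#' stationary disordered fraction is `theta = Ld / (Lo + Ld)`; the
#' constructor enforces that identity, deriving whichever of `Lo` / `theta`
#' is omitted.
#'
#' @param n_proteins cohort size (default 200).
#' @param length_range `c(min, max)` residue lengths, sampled uniformly
#'   (default fixed at 500).
#' @param theta target disordered fraction in `[0, 1]` (default 0.5).
#' @param mean_seg_disordered mean disordered segment length `Ld`
#'   (default 40).
#' @param mean_seg_ordered mean ordered segment length `Lo`; derived from
#'   `theta` and `Ld` when `NULL`.
#' @param composition_ordered,composition_disordered state compositions
#'   (`idp_composition`); defaults are the packaged ordered/disordered
#'   reference compositions, so composition profiling of the generated
#'   states reproduces the planted bias by construction.
#' @param noise_sd Gaussian score noise standard deviation (default 0.1).
#' @param smooth_window moving-average window for the score (odd; 0 or 1
#'   disables smoothing; default 5).
#' @param seed integer seed carried by the spec (may be overridden at
#'   sampling time).
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(n_proteins = 5, seed = 1)
#' sp$mean_seg_ordered
synthetic_spec <- function(n_proteins = 200, length_range = c(500, 500),
                           theta = 0.5, mean_seg_disordered = 40,
                           mean_seg_ordered = NULL,
                           composition_ordered = reference_composition("ordered"),
                           composition_disordered = reference_composition("disordered"),
                           noise_sd = 0.1, smooth_window = 5, seed = NULL) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) {
    abort("`theta` must lie in [0, 1]", class = "idp_config_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "idp_config_error")
  }
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be c(min, max) with 1 <= min <= max",
          class = "idp_config_error")
  }
  if (smooth_window != 0 && smooth_window != 1 &&
      (smooth_window < 3 || smooth_window %% 2 != 1)) {
    abort("`smooth_window` must be 0, 1, or an odd integer >= 3",
          class = "idp_config_error")
  }
  ld <- mean_seg_disordered
  if (theta > 0 && theta < 1) {
    if (ld < 1) abort("`mean_seg_disordered` must be >= 1",
                      class = "idp_config_error")
    lo <- mean_seg_ordered %||% (ld * (1 - theta) / theta)
    if (abs(theta - ld / (lo + ld)) > 1e-8) {
      abort(sprintf(
        "inconsistent spec: theta = %.4f but Ld/(Lo+Ld) = %.4f",
        theta, ld / (lo + ld)), class = "idp_config_error")
    }
  } else {
    lo <- mean_seg_ordered %||% ld  # unused in the degenerate cohorts
  }
  for (cc in list(composition_ordered, composition_disordered)) {
    if (!inherits(cc, "idp_composition")) {
      abort("state compositions must be idp_composition objects",
            class = "idp_config_error")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 theta = theta,
                 mean_seg_disordered = ld, mean_seg_ordered = lo,
                 composition_ordered = composition_ordered,
                 composition_disordered = composition_disordered,
                 noise_sd = noise_sd, smooth_window = as.integer(smooth_window),
                 seed = seed),
            class = "synthetic_spec")
}

# alternating geometric segments covering n residues; returns 0/1 state vector
sample_states <- function(n, spec) {
  if (spec$theta == 0) return(integer(n))
  if (spec$theta == 1) return(rep(1L, n))
  state <- if (stats::runif(1) < spec$theta) 1L else 0L
  out <- integer(0)
  while (length(out) < n) {
    len_mean <- if (state == 1L) spec$mean_seg_disordered else spec$mean_seg_ordered
    run <- stats::rgeom(1, prob = 1 / len_mean) + 1L
    out <- c(out, rep(state, run))
    state <- 1L - state
  }
  out[seq_len(n)]
}

sample_one <- function(spec, len) {
  state <- sample_states(len, spec)
  co <- spec$composition_ordered$fraction
  cd <- spec$composition_disordered$fraction
  res <- character(len)
  n_dis <- sum(state == 1L)
  if (n_dis < len) {
    res[state == 0L] <- sample(AA_STANDARD, len - n_dis, replace = TRUE,
                               prob = co)
  }
  if (n_dis > 0) {
    res[state == 1L] <- sample(AA_STANDARD, n_dis, replace = TRUE, prob = cd)
  }
  ind <- as.numeric(state)
  sm <- if (spec$smooth_window >= 3) {
    window_means(ind, spec$smooth_window)
  } else {
    ind
  }
  sc <- if (spec$noise_sd > 0) sm + rnorm(len, 0, spec$noise_sd) else sm
  list(sequence = paste(res, collapse = ""), state = state,
       scores = pmin(1, pmax(0, sc)))
}

#' Sample a synthetic cohort (or a single protein)
#'
#' Draws `n_proteins` independent proteins under the spec. Fully
#' reproducible: the same seed gives an identical cohort.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to the spec's seed (one of the two
#'   must be set).
#' @return A tibble of class `idp_synthetic_cohort`, one row per protein:
#'   `accession`, `name`, `sequence`, `length`, list-columns `state`
#'   (0/1 ground truth per residue) and `scores` (calibrated noisy score
#'   per residue).
#' @export
#' @examples
#' coh <- sample_cohort(synthetic_spec(n_proteins = 3, seed = 7))
#' coh$accession
sample_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec", class = "idp_config_error")
  }
  if (is.null(seed)) {
    abort("a seed is required: set it in the spec or pass `seed`",
          class = "idp_input_error")
  }
  out <- withr::with_seed(as.integer(seed), {
    lens <- if (spec$length_range[1] == spec$length_range[2]) {
      rep(spec$length_range[1], spec$n_proteins)
    } else {
      sample(seq(spec$length_range[1], spec$length_range[2]),
             spec$n_proteins, replace = TRUE)
    }
    drawn <- map(lens, function(l) sample_one(spec, l))
    tibble(accession = sprintf("SYN%04d", seq_len(spec$n_proteins)),
           name = sprintf("synthetic protein %d", seq_len(spec$n_proteins)),
           sequence = map_chr(drawn, "sequence"),
           length = lens,
           state = map(drawn, "state"),
           scores = map(drawn, "scores"))
  })
  structure(out, class = c("idp_synthetic_cohort", class(out)), spec = spec)
}

#' @rdname sample_cohort
#' @export
sample_protein <- function(spec, seed = spec$seed) {
  spec$n_proteins <- 1L
  sample_cohort(spec, seed = seed)
}

#' Views of a synthetic cohort for the analysis pipeline
#'
#' `cohort_records()` extracts the sequence records, `cohort_profiles()`
#' the emitted calibrated score profiles, and `cohort_truth_masks()` the
#' ground-truth disorder masks.
#'
#' @param cohort a tibble from [sample_cohort()].
#' @return Tibbles in the shapes consumed by [windowed_profile()],
#'   [cdf_curve()] and [disorder_content()] respectively.
#' @export
cohort_records <- function(cohort) {
  as_tibble(cohort[c("accession", "name", "sequence", "length")])
}

#' @rdname cohort_records
#' @export
cohort_profiles <- function(cohort) {
  profile_tibble(cohort$accession, "synthetic", TRUE, cohort$scores)
}

#' @rdname cohort_records
#' @export
cohort_truth_masks <- function(cohort) {
  tibble(accession = cohort$accession, threshold = NA_real_,
         mask = map(cohort$state, function(s) s == 1L))
}

#' Ground-truth cohort statistics
#'
#' The same statistics as the prediction pipeline, computed from the true
#' per-residue labels: contents and long regions from the labels, CH-plot
#' coordinates from the actual sequences, and CDF distances from the exact
#' (noiseless) label indicator profiles. This is the recovery target the
#' noisy pipeline is compared against.
#'
#' @param cohort a tibble from [sample_cohort()].
#' @param scheme a [content_class_scheme()].
#' @param min_len long-region cutoff (default 30).
#' @param params,boundary classifier settings (see [chcdf_points()]).
#' @return An `idp_cohort_summary`.
#' @export
true_statistics <- function(cohort, scheme = content_class_scheme(),
                            min_len = 30, params = ch_boundary_params(),
                            boundary = default_cdf_boundary()) {
  if (nrow(cohort) == 0) {
    abort("empty cohort", class = "idp_input_error")
  }
  masks <- cohort_truth_masks(cohort)
  truth_profiles <- profile_tibble(cohort$accession, "truth", TRUE,
                                   map(cohort$state, as.numeric))
  points <- chcdf_points(cohort_records(cohort), truth_profiles,
                         params = params, boundary = boundary)
  cohort_summary(masks = masks, points = points,
                 contents = disorder_content(masks),
                 scheme = scheme, min_len = min_len)
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.fasta`, one per-residue score file per protein under
#' `scores/` (the `index residue score` layout read back by
#' [import_score_profile()]), and `truth.tsv` with the ground-truth labels
#' as run-length intervals plus the true content.
#'
#' @param cohort a tibble from [sample_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "scores"), recursive = TRUE, showWarnings = FALSE)
  writeLines(unlist(map2(cohort$accession, cohort$sequence, function(a, s) {
    c(paste0(">", a), s)
  })), file.path(dir, "cohort.fasta"))
  purrr::pwalk(list(cohort$accession, cohort$sequence, cohort$scores),
               function(acc, sq, sc) {
    writeLines(sprintf("%d %s %.6f", seq_along(sc), seq_chars(sq), sc),
               file.path(dir, "scores", paste0(acc, ".txt")))
  })
  truth <- tibble(accession = cohort$accession,
                  length = cohort$length,
                  true_content = map_dbl(cohort$state, mean),
                  disordered_segments = map_chr(cohort$state, function(s) {
                    r <- rle(s == 1L)
                    ends <- cumsum(r$lengths)
                    starts <- ends - r$lengths + 1L
                    paste(sprintf("%d-%d", starts[r$values], ends[r$values]),
                          collapse = ";")
                  }))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
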