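test_that("content classes partition [0,1] with boundaries in the middle class", {
  expect_equal(as.character(classify_content(0.05)), "highly_ordered")
  expect_equal(as.character(classify_content(0.31)), "highly_disordered")
  expect_equal(as.character(classify_content(0.10)), "moderately_disordered")
  expect_equal(as.character(classify_content(0.30)), "moderately_disordered")
  expect_error(classify_content(1.2), class = "idp_input_error")
  expect_error(classify_content(-0.1), class = "idp_input_error")

  set.seed(701)
  cls <- classify_content(runif(500))
  expect_false(any(is.na(cls)))          # every value maps to exactly one class
  expect_equal(length(levels(cls)), 3L)
})

test_that("long-region prevalence counts carriers as percentages", {
  allF <- tibble::tibble(accession = c("a", "b"), threshold = 0.5,
                         mask = list(rep(FALSE, 50), rep(FALSE, 80)))
  expect_equal(long_region_prevalence(allF), 0)

  two_of_four <- tibble::tibble(
    accession = letters[1:4], threshold = 0.5,
    mask = list(rep(TRUE, 30), rep(TRUE, 30),
                rep(FALSE, 50), c(rep(TRUE, 29), rep(FALSE, 10))))
  expect_equal(long_region_prevalence(two_of_four), 50.0)

  # monotone non-increasing in min_len
  set.seed(702)
  masks <- tibble::tibble(accession = sprintf("m%d", 1:30), threshold = 0.5,
                          mask = purrr::map(1:30, ~ runif(200) < 0.6))
  prev <- vapply(c(5, 10, 20, 30, 50), function(L) {
    long_region_prevalence(masks, L)
  }, numeric(1))
  expect_true(all(diff(prev) <= 0))

  # direct enumeration oracle
  carriers <- sum(vapply(masks$mask, function(m) {
    nrow(oracle_long_regions(m, 20)) > 0
  }, logical(1)))
  expect_equal(long_region_prevalence(masks, 20),
               round(100 * carriers / 30, 1))
})

test_that("interval statistics count carriers and totals over valid intervals", {
  rows <- spliceosome_annotation()
  aibs <- interval_stats(rows, "aibs")
  expect_equal(aibs$n_with_any, 77L)
  expect_equal(aibs$percent_with_any, 71L)

  morfs <- interval_stats(rows, "morfs")
  prp3 <- nrow(rows$morfs[[which(rows$accession == "Q03338")]])
  expect_equal(prp3, 7L)
  expect_gte(morfs$total_intervals, prp3)
  expect_equal(morfs$mean_per_protein, morfs$total_intervals / 109)
  expect_equal(morfs$mean_per_carrier,
               morfs$total_intervals / morfs$n_with_any)

  none <- rows[purrr::map_int(rows$morfs, nrow) == 0, ]
  st <- interval_stats(none, "morfs")
  expect_equal(st$n_with_any, 0L)
  expect_true(is.na(st$mean_per_carrier))

  # carrier percentages round half away from zero (1/8 = 12.5 -> 13)
  eight <- rows[1:8, ]
  eight$morfs <- c(list(tibble::tibble(start = 1L, end = 20L)),
                   replicate(7, tibble::tibble(start = integer(0),
                                               end = integer(0)),
                             simplify = FALSE))
  expect_equal(interval_stats(eight, "morfs")$percent_with_any, 13L)
})

test_that("quadrant fractions count occupancy and the disordered half", {
  all2 <- tibble::tibble(accession = letters[1:4],
                         dcdf = 0.1, dch = -0.1,
                         quadrant = quadrant(rep(-0.1, 4), rep(0.1, 4)))
  qf <- quadrant_fractions(all2)
  expect_equal(qf$fraction[qf$quadrant == "Q2"], 1)
  expect_equal(sum(qf$fraction), 1, tolerance = 1e-9)

  one_each <- tibble::tibble(
    accession = letters[1:4],
    dcdf = c(0.1, 0.1, -0.1, -0.1), dch = c(0.1, -0.1, -0.1, 0.1),
    quadrant = quadrant(c(0.1, -0.1, -0.1, 0.1), c(0.1, 0.1, -0.1, -0.1)))
  qf2 <- quadrant_fractions(one_each)
  expect_equal(qf2$fraction, rep(0.25, 4))
  expect_equal(attr(qf2, "mostly_disordered"), 0.5)

  set.seed(703)
  y <- rnorm(100); x <- rnorm(100)
  pts <- tibble::tibble(accession = sprintf("p%d", 1:100), dcdf = x, dch = y,
                        quadrant = quadrant(y, x))
  qf3 <- quadrant_fractions(pts)
  expect_equal(qf3$n[qf3$quadrant == "Q4"], sum(y > 0 & x <= 0))
  expect_equal(qf3$n[qf3$quadrant == "Q3"], sum(y <= 0 & x <= 0))
})

test_that("cohort summary degrades gracefully and stays internally consistent", {
  rows <- spliceosome_annotation()
  fixture_only <- cohort_summary(rows = rows)
  expect_equal(fixture_only$aibs_stats$n_with_any, 77L)
  expect_null(fixture_only$content_classes)
  expect_null(fixture_only$quadrants)
  expect_equal(sum(fixture_only$by_complex$n_proteins), 109L)
  expect_equal(fixture_only$flagged$aibs_flagged, 2L)

  coh <- sample_cohort(synthetic_spec(n_proteins = 25,
                                      length_range = c(200, 200), seed = 41))
  masks <- binarize(cohort_profiles(coh))
  pts <- chcdf_points(cohort_records(coh), cohort_profiles(coh))
  full <- cohort_summary(masks = masks, points = pts,
                         contents = disorder_content(masks))
  expect_equal(sum(full$content_classes$n), 25L)
  expect_equal(sum(full$quadrants$fraction), 1, tolerance = 1e-9)

  single <- cohort_summary(masks = masks[1, ], points = pts[1, ],
                           contents = disorder_content(masks[1, ]))
  expect_true(all(single$quadrants$fraction %in% c(0, 1)))
  expect_true(all(single$content_classes$fraction %in% c(0, 1)))

  bad_masks <- masks
  bad_masks$accession[1] <- "INTRUDER"
  expect_error(cohort_summary(masks = bad_masks, points = pts),
               "INTRUDER", class = "idp_input_error")
})

test_that("summary accessors expose tidy statistics", {
  rows <- spliceosome_annotation()
  s <- cohort_summary(rows = rows)
  td <- tidy(s)
  expect_true("aibs_carriers" %in% td$statistic)
  expect_equal(td$value[td$statistic == "aibs_carriers"], 77)
  g <- glance(s)
  expect_equal(g$morf_percent, 61L)
  expect_equal(g$aibs_percent, 71L)
})
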