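test_that("composition pools residue counts over the whole set", {
  mono <- composition(tibble::tibble(sequence = "AAAA"))
  expect_equal(mono$fraction[mono$residue == "A"], 1)
  expect_equal(sum(mono$fraction), 1)

  one <- composition(tibble::tibble(sequence = "ACDE"))
  two <- composition(tibble::tibble(sequence = c("ACDE", "ACDE")))
  expect_equal(one$fraction, two$fraction)

  # hand-tallied mixed sequences
  mixed <- composition(tibble::tibble(sequence = c("AAK", "KKWX")))
  expect_equal(mixed$count[mixed$residue == "A"], 2L)
  expect_equal(mixed$count[mixed$residue == "K"], 3L)
  expect_equal(mixed$count[mixed$residue == "W"], 1L)
  expect_equal(attr(mixed, "total"), 6L)  # X excluded
  expect_equal(mixed$fraction[mixed$residue == "K"], 0.5)

  expect_error(composition(tibble::tibble(sequence = character(0))),
               class = "idp_input_error")
  expect_error(composition(tibble::tibble(sequence = "XXX")),
               class = "idp_data_error")
})

test_that("fractional difference is zero at identity and bounded at absence", {
  q <- composition(tibble::tibble(
    sequence = paste0(paste(AA20, collapse = ""), "MKLVEDRAG")))
  self <- fractional_difference(q, q)
  expect_equal(self$difference, rep(0, 20))

  # all-A query against the uniform reference: +19 for A, -1 elsewhere
  allA <- composition(tibble::tibble(sequence = strrep("A", 30)))
  prof <- fractional_difference(allA, uniform_composition())
  expect_equal(prof$difference[prof$residue == "A"], 19)
  expect_equal(prof$difference[prof$residue != "A"], rep(-1, 19))

  # residue absent from the query but present in the reference
  noW <- composition(tibble::tibble(sequence = "ACDE"))
  p2 <- fractional_difference(noW, uniform_composition())
  expect_equal(p2$difference[p2$residue == "W"], -1)
})

test_that("zero reference fractions are undefined, not infinite", {
  ref <- composition(tibble::tibble(sequence = "ACDE"))   # most residues 0
  q <- uniform_composition()
  expect_warning(prof <- fractional_difference(q, ref), "undefined")
  expect_true(is.na(prof$difference[prof$residue == "W"]))
  expect_false(any(is.infinite(prof$difference), na.rm = TRUE))
})

test_that("the reference-weighted sum rule holds", {
  set.seed(601)
  q <- composition(random_records(5, c(100, 200)))
  r <- composition(random_records(5, c(100, 200)))
  prof <- fractional_difference(q, r)
  expect_equal(sum(prof$reference_fraction * (1 + prof$difference)), 1,
               tolerance = 1e-9)
})

test_that("duplicating every query protein leaves the estimate unchanged", {
  set.seed(602)
  recs <- random_records(4, c(50, 80))
  a <- fractional_difference(composition(recs), uniform_composition())
  b <- fractional_difference(composition(rbind(recs, recs)),
                             uniform_composition())
  expect_equal(a$difference, b$difference)
})

test_that("bootstrap profiles are seeded, centred and size-sensitive", {
  set.seed(603)
  recs <- random_records(12, c(80, 120))
  ref <- composition(recs)

  # same seed twice: identical intervals; identical query/reference: CIs
  # straddle zero
  b1 <- bootstrap_profile(recs, ref, n_boot = 300, seed = 9)
  b2 <- bootstrap_profile(recs, ref, n_boot = 300, seed = 9)
  expect_identical(b1$ci_lo, b2$ci_lo)
  expect_identical(b1$ci_hi, b2$ci_hi)
  expect_true(all(b1$ci_lo <= 0 & b1$ci_hi >= 0))

  b3 <- bootstrap_profile(recs, ref, n_boot = 300, seed = 10)
  expect_false(identical(b1$ci_lo, b3$ci_lo))

  expect_error(bootstrap_profile(recs[1, ], ref, seed = 1),
               class = "idp_input_error")
  expect_error(bootstrap_profile(recs, ref, n_boot = 100),
               class = "idp_input_error")  # missing seed
  expect_warning(bootstrap_profile(recs, ref, n_boot = 50, seed = 1),
                 "small")
})

test_that("bootstrap intervals shrink with query size", {
  spec10 <- synthetic_spec(n_proteins = 10, length_range = c(300, 300),
                           seed = 21)
  spec100 <- synthetic_spec(n_proteins = 100, length_range = c(300, 300),
                            seed = 22)
  ref <- reference_composition("ordered")
  w10 <- bootstrap_profile(cohort_records(sample_cohort(spec10)), ref,
                           n_boot = 300, seed = 5)
  w100 <- bootstrap_profile(cohort_records(sample_cohort(spec100)), ref,
                            n_boot = 300, seed = 5)
  expect_lt(mean(w100$ci_hi - w100$ci_lo), mean(w10$ci_hi - w10$ci_lo))
})

test_that("disordered-vs-ordered state residues reproduce the planted bias", {
  coh <- sample_cohort(synthetic_spec(n_proteins = 40,
                                      length_range = c(400, 400), seed = 31))
  split_seq <- function(state_val) {
    tibble::tibble(sequence = purrr::map2_chr(coh$sequence, coh$state,
      function(sq, st) {
        paste(strsplit(sq, "")[[1]][st == state_val], collapse = "")
      }))
  }
  observed <- fractional_difference(composition(split_seq(1L)),
                                    composition(split_seq(0L)))
  planted <- fractional_difference(reference_composition("disordered"),
                                   reference_composition("ordered"))
  strong <- !is.na(planted$difference) & abs(planted$difference) > 0.2
  expect_true(all(sign(observed$difference[strong]) ==
                    sign(planted$difference[strong])))
})

test_that("tidy and glance expose the profile as rectangular data", {
  q <- composition(tibble::tibble(sequence = "MKLVEDRAG"))
  prof <- fractional_difference(q, uniform_composition())
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20L)
  g <- glance(prof)
  expect_equal(g$n_enriched + g$n_depleted <= 20, TRUE)
})
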