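test_that("windowed profiles are constant on homopolymers and short sequences", {
  sc <- scale_top_idp()
  rec <- tibble::tibble(accession = "polyA", sequence = strrep("A", 40))
  prof <- windowed_profile(rec, sc, window_spec(21))
  expect_equal(prof$scores[[1]], rep(sc$values[["A"]], 40))
  expect_false(prof$calibrated)

  # shorter than the window: every position sees the whole sequence
  short <- tibble::tibble(accession = "s", sequence = "MKLVED")
  p2 <- windowed_profile(short, sc, window_spec(21))
  whole <- mean(sc$values[c("M", "K", "L", "V", "E", "D")])
  expect_equal(p2$scores[[1]], rep(whole, 6))
})

test_that("windowed profiles match the explicit brute-force window oracle", {
  sc <- scale_top_idp()
  set.seed(401)
  for (rep in 1:10) {
    sq <- random_sequence(40)
    prof <- windowed_profile(tibble::tibble(accession = "x", sequence = sq),
                             sc, window_spec(5))
    vals <- unname(sc$values[strsplit(sq, "")[[1]]])
    expect_equal(prof$scores[[1]], oracle_window_means(vals, 5))
  }
})

test_that("ambiguity codes are excluded from window means", {
  sc <- scale_top_idp()
  v <- sc$values
  prof <- windowed_profile(tibble::tibble(accession = "x", sequence = "ARX"),
                           sc, window_spec(3))
  expect_equal(prof$scores[[1]],
               c(mean(v[c("A", "R")]), mean(v[c("A", "R")]), v[["R"]]),
               ignore_attr = TRUE)

  # a window holding only ambiguity codes falls back to the sequence mean
  prof2 <- windowed_profile(
    tibble::tibble(accession = "x", sequence = "AXXXE"), sc, window_spec(3))
  expect_equal(prof2$scores[[1]][3], mean(v[c("A", "E")]), ignore_attr = TRUE)

  expect_error(
    windowed_profile(tibble::tibble(accession = "x", sequence = "XXXX"),
                     sc, window_spec(3)),
    class = "idp_data_error")
})

test_that("windowed profiles are invariant to permutations inside the window", {
  sc <- scale_top_idp()
  set.seed(402)
  sq <- strsplit(random_sequence(30), "")[[1]]
  center <- 15
  perm <- sq
  perm[13:17] <- sample(sq[13:17])
  p1 <- windowed_profile(tibble::tibble(accession = "a",
                                        sequence = paste(sq, collapse = "")),
                         sc, window_spec(5))
  p2 <- windowed_profile(tibble::tibble(accession = "a",
                                        sequence = paste(perm, collapse = "")),
                         sc, window_spec(5))
  expect_equal(p1$scores[[1]][center], p2$scores[[1]][center])
})

test_that("unfoldability profile evaluates the boundary formula", {
  w <- window_spec(9)
  pe <- foldindex_profile(tibble::tibble(accession = "pe",
                                         sequence = strrep("E", 30)),
                          window = w)
  expect_equal(pe$raw[[1]][15], 2.785 * (1 / 9) - 1 - 1.151, tolerance = 1e-12)
  expect_true(pe$mask[[1]][15])            # negative raw = disordered
  expect_equal(pe$scores[[1]][15], -pe$raw[[1]][15])  # stored negated

  pi_ <- foldindex_profile(tibble::tibble(accession = "pi",
                                          sequence = strrep("I", 30)),
                           window = w)
  expect_equal(pi_$raw[[1]][15], 2.785 - 1.151, tolerance = 1e-12)
  expect_false(pi_$mask[[1]][15])

  # balanced charge cancels the |<R>| term entirely
  kd <- foldindex_profile(tibble::tibble(accession = "kd", sequence = "KKDD"),
                          window = window_spec(9))
  h <- mean(ch_boundary_params()$hydropathy_scale$values[c("K", "K", "D", "D")])
  expect_equal(kd$raw[[1]], rep(2.785 * h - 1.151, 4), tolerance = 1e-12)
})

test_that("imported score files are parsed and validated", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# predictor output", "", "1 M 0.10", "2 K 0.90",
               "3 L 0.50", "4 V 0.00"), f)
  prof <- import_score_profile(f, 4, accession = "P1")
  expect_equal(prof$scores[[1]], c(0.10, 0.90, 0.50, 0.00))
  expect_true(prof$calibrated)

  expect_error(import_score_profile(f, 5), "4 scores.*5",
               class = "idp_data_error")

  bad <- tempfile(fileext = ".txt")
  writeLines(c("1 M 0.10", "2 K 1.50"), bad)
  expect_error(import_score_profile(bad, 2), "line 2",
               class = "idp_data_error")
})

test_that("binarize uses the >= threshold convention on calibrated profiles", {
  prof <- tibble::tibble(accession = "P1", predictor = "demo",
                         calibrated = TRUE,
                         scores = list(c(0.4, 0.5, 0.6)))
  expect_equal(binarize(prof)$mask[[1]], c(FALSE, TRUE, TRUE))
  expect_equal(binarize(tibble::tibble(accession = "z", predictor = "demo",
                                       calibrated = TRUE,
                                       scores = list(rep(0, 5))))$mask[[1]],
               rep(FALSE, 5))

  set.seed(403)
  s <- runif(200)
  m <- binarize(tibble::tibble(accession = "r", predictor = "demo",
                               calibrated = TRUE, scores = list(s)))$mask[[1]]
  oracle <- vapply(seq_along(s), function(i) s[i] >= 0.5, logical(1))
  expect_equal(m, oracle)

  uncal <- tibble::tibble(accession = "u", predictor = "fi",
                          calibrated = FALSE, scores = list(c(-1, 1)))
  expect_error(binarize(uncal), class = "idp_input_error")
  expect_equal(binarize(uncal, threshold = 0,
                        allow_uncalibrated = TRUE)$mask[[1]],
               c(FALSE, TRUE))
})

test_that("disorder content is the fraction of disordered labels", {
  masks <- tibble::tibble(accession = c("a", "b"), threshold = 0.5,
                          mask = list(c(TRUE, TRUE, FALSE, FALSE),
                                      rep(TRUE, 4)))
  expect_equal(disorder_content(masks)$content, c(0.5, 1.0))

  planted <- c(rep(TRUE, 300), rep(FALSE, 700))
  m <- tibble::tibble(accession = "p", threshold = 0.5, mask = list(planted))
  expect_identical(disorder_content(m)$content, 0.3)
})

test_that("lowering the threshold never decreases disorder content", {
  set.seed(404)
  prof <- tibble::tibble(accession = "m", predictor = "demo",
                         calibrated = TRUE, scores = list(runif(300)))
  contents <- vapply(seq(0.9, 0.1, by = -0.1), function(th) {
    disorder_content(binarize(prof, th))$content
  }, numeric(1))
  expect_true(all(diff(contents) >= 0))
})

test_that("long disordered regions are maximal runs above the cutoff", {
  m35 <- c(rep(FALSE, 5), rep(TRUE, 35), rep(FALSE, 3))
  out <- long_disordered_regions(
    tibble::tibble(accession = "a", threshold = 0.5, mask = list(m35)))
  expect_equal(out, tibble::tibble(accession = "a", start = 6L, end = 40L))

  m29 <- c(rep(TRUE, 29), FALSE)
  expect_equal(nrow(long_disordered_regions(
    tibble::tibble(accession = "a", threshold = 0.5, mask = list(m29)))), 0L)

  expect_error(long_disordered_regions(
    tibble::tibble(accession = "a", threshold = 0.5, mask = list(m35)),
    min_len = 0), class = "idp_config_error")
})

test_that("long regions match the RLE oracle and its structural properties", {
  set.seed(405)
  for (rep in 1:20) {
    mask <- runif(300) < 0.7
    got <- long_disordered_regions(
      tibble::tibble(accession = "x", threshold = 0.5, mask = list(mask)),
      min_len = 10)
    want <- oracle_long_regions(mask, 10)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] - got$end[-nrow(got)] >= 2))  # gap >= 1
    }
    expect_true(all(got$end - got$start + 1 >= 10))
  }
})
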