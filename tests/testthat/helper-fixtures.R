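# shared fixture builders: everything is generated in code at test time

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(20, 80)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  tibble::tibble(accession = sprintf("T%04d", seq_len(n)),
                 name = "",
                 sequence = vapply(lens, random_sequence, ""),
                 length = lens)
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", records$accession),
                             records$sequence)), path)
  path
}

# each of the 20 residues once: the uniform (0.05 each) composition
uniform_composition <- function() {
  composition(tibble::tibble(sequence = paste(AA20, collapse = "")))
}

# explicit boundary used wherever exact CDF numbers are asserted
toy_boundary <- function() {
  cdf_boundary(c(0.2, 0.4, 0.6, 0.8), c(0.3, 0.45, 0.6, 0.75),
               source = "toy")
}

# brute-force oracle: shrunken-window mean by explicit loops, NA excluded,
# all-NA windows replaced by the whole-sequence mean
oracle_window_means <- function(values, width) {
  n <- length(values)
  half <- (width - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- values[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    out[i] <- if (length(w) == 0) mean(values, na.rm = TRUE) else mean(w)
  }
  out
}

# run-length-encoding oracle for long disordered regions
oracle_long_regions <- function(mask, min_len) {
  out <- list()
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out[[length(out) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    tibble::tibble(start = integer(0), end = integer(0))
  } else {
    m <- do.call(rbind, out)
    tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }
}
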