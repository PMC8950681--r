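test_that("zero-padded window average matches hand evaluation", {
  x <- rep(2, 7)
  out <- windowed_average_track(x, 3)
  expect_equal(out[1], 4 / 3)              # (0 + 2 + 2) / 3
  expect_equal(out[7], 4 / 3)
  expect_equal(out[2:6], rep(2, 5))        # interior untouched
  expect_equal(windowed_average_track(rep(0, 9), 5), rep(0, 9))
  expect_error(windowed_average_track(1:4, 5), "smaller")
  expect_error(windowed_average_track(1:9, 4), "odd")
})

test_that("window average agrees with a naive padded loop", {
  withr::with_seed(11, x <- rnorm(40))
  n <- 7; half <- 3
  padded <- c(rep(0, half), x, rep(0, half))
  naive <- vapply(seq_along(x), function(j) mean(padded[j:(j + n - 1)]),
                  numeric(1))
  expect_equal(windowed_average_track(x, n), naive)
})

test_that("Shannon entropy track matches closed forms", {
  homo <- paste(rep("A", 30), collapse = "")
  expect_equal(shannon_entropy_track(homo, 5), rep(0, 30))
  # uniform window over all 20 residues
  seq20 <- paste(rep(paste(aa_alphabet, collapse = ""), 3), collapse = "")
  tr <- shannon_entropy_track(seq20, 21)
  expect_true(all(tr <= log2(20) + 1e-12))
  # hand: window AAR (position 3 of AAAR with window 3)
  tr2 <- shannon_entropy_track("AAAR", 3)
  expect_equal(tr2[3], -(2/3) * log2(2/3) - (1/3) * log2(1/3),
               tolerance = 1e-9)
  expect_equal(tr2[3], 0.918296, tolerance = 1e-6)
})

test_that("topological entropy uses the calibrated subword length", {
  homo <- paste(rep("A", 60), collapse = "")
  expect_equal(topological_entropy_track(homo, 33), rep(0, 60))
  # N = 33 -> n = 1: distinct residues among the first 20 window chars
  block <- paste(c(rep(aa_alphabet[1:10], 2), rep("A", 40)), collapse = "")
  tr <- topological_entropy_track(block, 33)
  expect_equal(tr[17], log(10, base = 20), tolerance = 1e-9)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_error(topological_entropy_track(homo, 19), "too small")
})

test_that("the packaged scales are complete and the loader round-trips", {
  sc <- default_scales()
  expect_length(sc, 10)
  expect_true(all(vapply(sc, length, integer(1)) == 20))
  expect_true(all(vapply(sc, function(v) identical(names(v), aa_alphabet),
                         logical(1))))
  long <- default_scales(tidy = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(long, f)
  back <- load_scales(f)
  expect_equal(back, lapply(sc, identity), ignore_attr = TRUE)
})

test_that("feature matrix has the documented shape and row semantics", {
  seqs <- withr::with_seed(21, vapply(1:3, function(i) {
    paste(sample(aa_alphabet, 60, replace = TRUE), collapse = "")
  }, character(1)))
  k2 <- build_kmer_table(seqs, 2); k3 <- build_kmer_table(seqs, 3)
  s <- seqs[1]
  pssm <- matrix(0, nchar(s), 20, dimnames = list(NULL, aa_alphabet))
  F <- assemble_feature_matrix(s, pssm, k2, k3, window = 33)
  expect_equal(dim(F), c(35L, nchar(s)))
  expect_equal(rownames(F), feature_row_names())
  expect_true(all(is.finite(F)))
  # rows 34-35 are the PCAA tracks, in [0,1]
  expect_equal(unname(F["pcaa2", ]), pcaa_track(s, k2))
  expect_equal(unname(F["pcaa3", ]), pcaa_track(s, k3))
  expect_true(all(F[34:35, ] >= 0 & F[34:35, ] <= 1))
  # entropy rows non-negative
  expect_true(all(F[31:33, ] >= 0))
  # scale rows bounded by scale range (zero-padded averages)
  sc <- default_scales()
  for (i in seq_along(sc)) {
    expect_true(all(F[20 + i, ] >= min(c(sc[[i]], 0)) - 1e-9))
    expect_true(all(F[20 + i, ] <= max(c(sc[[i]], 0)) + 1e-9))
  }
  # column j stacks the channels of residue j
  expect_equal(unname(F[1:20, 5]),
               unname(apply(pssm, 2, windowed_average_track, window = 33)[5, ]))
})

test_that("homopolymer with constant PSSM gives interior-constant rows", {
  s <- paste(rep("A", 80), collapse = "")
  pssm <- matrix(1, 80, 20)
  k2 <- build_kmer_table(s, 2); k3 <- build_kmer_table(s, 3)
  F <- assemble_feature_matrix(s, pssm, k2, k3, window = 33)
  interior <- 17:64
  for (r in seq_len(35)) {
    expect_equal(diff(range(F[r, interior])), 0)
  }
})

test_that("feature columns respond only locally to a residue change", {
  withr::with_seed(33, {
    chars <- sample(aa_alphabet, 101, replace = TRUE)
  })
  s1 <- paste(chars, collapse = "")
  chars2 <- chars
  p <- 50L
  chars2[p] <- if (chars[p] == "A") "V" else "A"
  s2 <- paste(chars2, collapse = "")
  refs <- c(s1, s2)
  k2 <- build_kmer_table(refs, 2); k3 <- build_kmer_table(refs, 3)
  pssm <- matrix(0, 101, 20)
  n <- 33
  F1 <- assemble_feature_matrix(s1, pssm, k2, k3, window = n)
  F2 <- assemble_feature_matrix(s2, pssm, k2, k3, window = n)
  changed <- which(colSums(abs(F1 - F2)) > 1e-12)
  expect_true(all(changed >= p - n + 1 & changed <= p + n - 1))
  # distant columns identical
  expect_equal(F1[, 1:10], F2[, 1:10])
  expect_equal(F1[, 92:101], F2[, 92:101])
})

test_that("feature assembly is deterministic and validates inputs", {
  s <- paste(rep(c("A", "R", "N", "D"), 15), collapse = "")
  k2 <- build_kmer_table(s, 2); k3 <- build_kmer_table(s, 3)
  pssm <- matrix(0, 60, 20)
  F1 <- assemble_feature_matrix(s, pssm, k2, k3, window = 21)
  F2 <- assemble_feature_matrix(s, pssm, k2, k3, window = 21)
  expect_identical(F1, F2)
  expect_error(assemble_feature_matrix(s, pssm[1:10, ], k2, k3, window = 21),
               "row count")
  expect_error(assemble_feature_matrix(s, NULL, k2, k3, window = 21),
               "blosum62")
})

test_that("BLOSUM62 pseudo-profile fallback produces a valid profile", {
  skip_if_not_installed("Biostrings")
  s <- "ARNDVKLPW"
  p <- blosum_pseudo_pssm(s)
  expect_equal(dim(p), c(9L, 20L))
  # diagonal dominance: A row scores highest at column A
  expect_equal(unname(which.max(p[1, ])), 1L)
  k2 <- build_kmer_table(s, 2); k3 <- build_kmer_table(s, 3)
  s_long <- paste(rep(s, 6), collapse = "")
  F <- assemble_feature_matrix(s_long, NULL, k2, k3, window = 33,
                               pssm_missing = "blosum62")
  expect_equal(dim(F), c(35L, nchar(s_long)))
})

test_that("feature matrices round-trip through TSV", {
  s <- paste(rep(c("A", "R", "N", "D", "V"), 10), collapse = "")
  k2 <- build_kmer_table(s, 2); k3 <- build_kmer_table(s, 3)
  F <- assemble_feature_matrix(s, matrix(0, 50, 20), k2, k3, window = 21)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(F, f)
  back <- read_feature_matrix(f)
  expect_equal(back, F, tolerance = 1e-9)
  long <- tidy_feature_matrix(F)
  expect_equal(nrow(long), 35 * 50)
})
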