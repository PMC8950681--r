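test_that("k-mer indices enumerate the alphabet in mixed-radix order", {
  expect_equal(kmer_index("AA"), 1L)
  expect_equal(kmer_index("VV"), 400L)
  expect_equal(kmer_index("RA"), 21L)
  expect_equal(kmer_index("AAA"), 1L)
  expect_equal(kmer_index("VVV"), 8000L)
  expect_equal(kmer_index(c("AR", "AN")), c(2L, 3L))
  expect_true(is.na(kmer_index("AX")))
  expect_equal(kmer_unindex(21L, 2), "RA")
})

test_that("kmer_index and kmer_unindex are inverse over the full range", {
  idx2 <- seq_len(400)
  expect_equal(kmer_index(kmer_unindex(idx2, 2)), idx2)
  idx3 <- sample(8000, 200)
  expect_equal(kmer_index(kmer_unindex(idx3, 3)), idx3)
})

test_that("counting follows the sliding-window definition", {
  t1 <- count_kmers("AAA", k = 2)
  expect_equal(t1$count[1], 2L)          # "AA" twice
  expect_equal(sum(t1$count), 2L)        # L - 1

  t2 <- count_kmers("ARN", k = 2)
  expect_equal(t2$count[2], 1L)          # AR at index 2
  expect_equal(t2$count[23], 1L)         # RN at index 23
  expect_equal(sum(t2$count), 2L)

  # additivity over the corpus
  t3 <- count_kmers(c("ARN", "ARN"), k = 2)
  expect_equal(t3$count, 2L * t2$count)
})

test_that("corpus total equals sum of L_p - k + 1 and matches a naive recount", {
  withr::with_seed(9, {
    seqs <- vapply(1:5, function(i) {
      paste(sample(aa_alphabet, sample(3:12, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
  for (k in 2:3) {
    tab <- count_kmers(seqs, k)
    expect_equal(sum(tab$count), sum(pmax(nchar(seqs) - k + 1, 0)))
    expect_equal(tab$count, oracle_kmer_counts(seqs, k))
  }
})

test_that("k-mers with nonstandard residues are skipped in counting", {
  expect_warning(tab <- count_kmers("AXA", k = 2), "no k-mers")
  expect_equal(sum(tab$count), 0L)
  tab2 <- count_kmers("AAXAA", k = 2)
  expect_equal(sum(tab2$count), 2L)      # AA twice, AX/XA skipped
})

test_that("probabilities normalise and min-max scaling follows the zero-range rule", {
  tab <- finalize_kmer_table(count_kmers("AAA", k = 2))
  expect_equal(tab$probability[1], 1)
  expect_equal(sum(tab$probability), 1)
  expect_equal(tab$scaled[1], 1)
  expect_equal(tab$scaled[2], 0)

  # hand-worked: counts {3, 1} -> P {0.75, 0.25}, N {1, 1/3}
  raw <- count_kmers("AAA", k = 2)
  raw$count[1] <- 3L; raw$count[2] <- 1L
  fin <- finalize_kmer_table(raw)
  expect_equal(fin$probability[1:2], c(0.75, 0.25))
  expect_equal(fin$scaled[1:2], c(1, 1/3))

  # all counts equal -> zero range -> all scaled values 1
  eq <- count_kmers("AAA", k = 2)
  eq$count <- rep(2L, 400)
  expect_equal(finalize_kmer_table(eq)$scaled, rep(1, 400))

  empty <- count_kmers("AAA", k = 2)
  empty$count <- rep(0L, 400)
  expect_error(finalize_kmer_table(empty), "empty corpus")
})

test_that("normalisation holds on random corpora", {
  for (s in 1:5) {
    seqs <- withr::with_seed(s, vapply(1:4, function(i) {
      paste(sample(aa_alphabet, 30, replace = TRUE), collapse = "")
    }, character(1)))
    expect_equal(sum(build_kmer_table(seqs, 2)$probability), 1,
                 tolerance = 1e-12)
    expect_equal(sum(build_kmer_table(seqs, 3)$probability), 1,
                 tolerance = 1e-12)
  }
})

test_that("PCAA tracks follow the positional averaging rule", {
  tab <- build_kmer_table("AAA", k = 2)
  expect_equal(pcaa_track("AAA", tab), c(1, 1, 1))

  # hand-worked dipeptide case with two distinct scaled values
  tab2 <- tab
  tab2$scaled[kmer_index("AR")] <- 0.4
  tab2$scaled[kmer_index("RA")] <- 0.8
  expect_equal(pcaa_track("ARA", tab2), c(0.4, 0.6, 0.8))

  # tripeptide branch structure for a length-5 sequence
  seqs <- c("ARNDV")
  tab3 <- build_kmer_table(seqs, k = 3)
  n3 <- tab3$scaled
  i <- kmer_index(c("ARN", "RND", "NDV"))
  h3 <- pcaa_track("ARNDV", tab3)
  expect_equal(h3[1], n3[i[1]])
  expect_equal(h3[2], mean(n3[i[1:2]]))
  expect_equal(h3[3], mean(n3[i[1:3]]))
  expect_equal(h3[4], mean(n3[i[2:3]]))
  expect_equal(h3[5], n3[i[3]])
})

test_that("PCAA values stay in [0,1]; homopolymers give the single k-mer value", {
  seqs <- withr::with_seed(4, vapply(1:6, function(i) {
    paste(sample(aa_alphabet, 25, replace = TRUE), collapse = "")
  }, character(1)))
  k2 <- build_kmer_table(seqs, 2); k3 <- build_kmer_table(seqs, 3)
  for (s in seqs) {
    expect_true(all(pcaa_track(s, k2) >= 0 & pcaa_track(s, k2) <= 1))
    expect_true(all(pcaa_track(s, k3) >= 0 & pcaa_track(s, k3) <= 1))
  }
  homo <- paste(rep("L", 10), collapse = "")
  expect_equal(pcaa_track(homo, k2),
               rep(k2$scaled[kmer_index("LL")], 10))
})

test_that("nonstandard k-mers contribute zero to PCAA averages", {
  tab <- build_kmer_table("AAAA", k = 2)   # N2(AA) = 1
  h <- pcaa_track("AXA", tab)              # both dipeptides nonstandard
  expect_equal(h, c(0, 0, 0))
  h2 <- pcaa_track("AAX", tab)             # AA valid, AX -> 0
  expect_equal(h2, c(1, 0.5, 0))
})

test_that("k-mer tables round-trip through TSV", {
  tab <- build_kmer_table(c("ARNDV", "VVAA"), k = 2, corpus_id = "demo")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_table(tab, f)
  back <- read_kmer_table(f)
  expect_equal(attr(back, "k"), 2L)
  expect_equal(attr(back, "corpus_id"), "demo")
  expect_equal(back$count, tab$count)
  expect_equal(back$scaled, tab$scaled)
})
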