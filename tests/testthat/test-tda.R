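test_that("window embedding follows the cylindrical coordinates", {
  cl <- embed_window("ARV")   # N = 3
  # first residue A (index 1) at height 0
  expect_equal(cl$x[1], cos(2 * pi / 20), tolerance = 1e-9)
  expect_equal(cl$y[1], sin(2 * pi / 20), tolerance = 1e-9)
  expect_equal(cl$x[1], 0.951057, tolerance = 1e-6)
  expect_equal(cl$y[1], 0.309017, tolerance = 1e-6)
  expect_equal(cl$z, c(0, 0.5, 1))
  # V has index 20: angle 2*pi
  expect_equal(cl$x[3], 1, tolerance = 1e-12)
  expect_equal(cl$y[3], 0, tolerance = 1e-12)
})

test_that("identical residues at different positions give distinct points", {
  cl <- embed_window("AAA")
  expect_equal(cl$x, rep(cl$x[1], 3))
  expect_equal(length(unique(cl$z)), 3)
})

test_that("embedding rejects nonstandard residues and short windows", {
  expect_error(embed_window("AXA"), "nonstandard")
  expect_error(embed_window("A"), "at least 2")
})

test_that("two-point cloud yields two equal dim-0 bars and 1 bit of entropy", {
  cl <- rbind(c(0, 0, 0), c(0.8, 0, 0.6))   # distance 1
  d <- rips_persistence(cl, max_dim = 1)
  expect_equal(nrow(d), 2)
  expect_equal(d$dimension, c(0L, 0L))
  expect_equal(d$death - d$birth, c(0.5, 0.5))  # merge at d/2, elder truncated
  expect_equal(persistent_entropy(d), 1.0)
})

test_that("dim-0 bar count before zero-length drop equals the point count", {
  for (n in c(1, 2, 5, 9)) {
    d <- rips_persistence(random_cloud(n, seed = 100 + n))
    expect_equal(attr(d, "n_dim0_raw"), n)
  }
})

test_that("single point with auto cap gives one unit dim-0 bar", {
  d <- rips_persistence(matrix(0, 1, 3))
  expect_equal(nrow(d), 1)
  expect_equal(d$death, 1)
  expect_equal(attr(d, "cap"), 1)
})

test_that("diagrams match the brute-force reduction oracle on random clouds", {
  n_match <- 0L
  for (s in 1:100) {
    n <- 2L + (s %% 5L)              # 2..6 points
    cl <- random_cloud(n, seed = s)
    fast <- sort_diagram(rips_persistence(cl, max_dim = 1))
    slow <- sort_diagram(oracle_rips(cl, max_dim = 1))
    slow <- slow[slow$death > slow$birth, ]
    expect_equal(fast$dimension, slow$dimension)
    expect_equal(fast$birth, slow$birth, tolerance = 1e-9)
    expect_equal(fast$death, slow$death, tolerance = 1e-9)
    n_match <- n_match + 1L
  }
  expect_equal(n_match, 100L)
})

test_that("oracle agreement extends to dimension 2 and fixed caps", {
  for (s in 1:20) {
    cl <- random_cloud(6, seed = 1000 + s)
    fast <- sort_diagram(rips_persistence(cl, max_dim = 2, cap = 0.9))
    slow <- sort_diagram(oracle_rips(cl, max_dim = 2, cap = 0.9))
    slow <- slow[slow$death > slow$birth, ]
    expect_equal(fast$dimension, slow$dimension)
    expect_equal(fast$birth, slow$birth, tolerance = 1e-9)
    expect_equal(fast$death, slow$death, tolerance = 1e-9)
  }
})

test_that("persistent entropy closed forms hold", {
  one <- tibble::tibble(dimension = 0L, birth = 0, death = 2)
  expect_equal(persistent_entropy(one), 0)
  four <- tibble::tibble(dimension = 0L, birth = 0, death = rep(0.7, 4))
  expect_equal(persistent_entropy(four), 2)
  for (n in c(2, 3, 8)) {
    eq <- tibble::tibble(dimension = 0L, birth = 1, death = 1 + rep(0.3, n))
    expect_equal(persistent_entropy(eq), log2(n))
  }
  two <- tibble::tibble(dimension = 0L, birth = 0, death = c(1, 3))
  expect_equal(persistent_entropy(two), 0.811278, tolerance = 1e-6)
  expect_equal(persistent_entropy(two[0, ]), 0)
})

test_that("entropy is bounded by log2 of the positive-length bar count", {
  for (s in 1:25) {
    d <- rips_persistence(random_cloud(3 + s %% 6, seed = 300 + s))
    expect_gte(persistent_entropy(d), 0)
    expect_lte(persistent_entropy(d), log2(nrow(d)) + 1e-12)
  }
})

test_that("diagrams are invariant under isometry and entropy under scaling", {
  withr::with_seed(42, {
    for (s in 1:10) {
      cl <- random_cloud(6, seed = 400 + s)
      # random rotation (QR of a random matrix) + translation
      qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
      moved <- cl %*% qr_r + matrix(rnorm(3), nrow(cl), 3, byrow = TRUE)
      d0 <- sort_diagram(rips_persistence(cl))
      d1 <- sort_diagram(rips_persistence(moved))
      expect_equal(d0$birth, d1$birth, tolerance = 1e-9)
      expect_equal(d0$death, d1$death, tolerance = 1e-9)
      # reflection (improper isometry) too
      refl <- cl %*% diag(c(-1, 1, 1))
      dr <- sort_diagram(rips_persistence(refl))
      expect_equal(d0$death, dr$death, tolerance = 1e-9)
      # scaling: bars scale, entropy unchanged
      c_scale <- 2.7
      ds <- sort_diagram(rips_persistence(cl * c_scale))
      expect_equal(ds$death, d0$death * c_scale, tolerance = 1e-9)
      expect_equal(persistent_entropy(ds), persistent_entropy(d0),
                   tolerance = 1e-9)
    }
  })
})

test_that("entropy track has length L, is non-negative, constant on homopolymers", {
  seq <- paste(rep("A", 40), collapse = "")
  tr <- persistent_entropy_track(seq, window = 9)
  expect_length(tr, 40)
  expect_true(all(tr >= 0))
  expect_equal(diff(range(tr)), 0)

  seq2 <- paste(rep(c("A", "R", "N", "D", "V"), 10), collapse = "")
  tr2 <- persistent_entropy_track(seq2, window = 11)
  expect_length(tr2, 50)
  expect_true(all(tr2 >= 0))
})

test_that("entropy track validates window size and handles nonstandard residues", {
  expect_error(persistent_entropy_track("ARNDV", window = 4), "odd")
  expect_error(persistent_entropy_track("ARNDV", window = 7), "smaller")
  # X substituted by most frequent standard residue: same as all-A window
  with_x <- persistent_entropy_track("AAXAAAAAAA", window = 5)
  no_x <- persistent_entropy_track("AAAAAAAAAA", window = 5)
  expect_equal(with_x, no_x)
})
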