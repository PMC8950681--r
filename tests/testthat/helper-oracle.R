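# Independent brute-force oracles used across the suite.

# Persistence of the Vietoris-Rips filtration by naive global
# boundary-matrix reduction over GF(2): enumerate every simplex up to
# dimension max_dim + 1, sort by (filtration value, dimension, lex
# vertex order), build the full boundary matrix and reduce columns
# left-to-right with mod-2 column additions. Ball-intersection scale
# (epsilon = max pairwise distance / 2); classes alive at the cap are
# truncated. Only usable for tiny clouds.
oracle_rips <- function(coords, max_dim = 1, cap = "auto") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  K <- if (identical(cap, "auto")) {
    if (n > 1 && max(D) > 0) max(D) / 2 else 1
  } else cap
  verts <- list(); fs <- numeric(0); dims <- integer(0)
  for (d in 0:min(max_dim + 1, n - 1)) {
    combs <- utils::combn(n, d + 1)
    for (ci in seq_len(ncol(combs))) {
      v <- combs[, ci]
      f <- if (d == 0) 0 else max(D[v, v]) / 2
      if (f <= K) {
        verts[[length(verts) + 1]] <- v
        fs <- c(fs, f); dims <- c(dims, d)
      }
    }
  }
  lex <- vapply(verts, function(v) paste(sprintf("%03d", v), collapse = ""),
                character(1))
  ord <- order(fs, dims, lex)
  verts <- verts[ord]; fs <- fs[ord]; dims <- dims[ord]
  m <- length(verts)
  key <- vapply(verts, function(v) paste(v, collapse = "-"), character(1))
  B <- matrix(0L, m, m)
  for (j in seq_len(m)) {
    if (dims[j] == 0) next
    for (omit in seq_along(verts[[j]])) {
      face <- verts[[j]][-omit]
      B[match(paste(face, collapse = "-"), key), j] <- 1L
    }
  }
  low_of <- function(col) if (any(col == 1L)) max(which(col == 1L)) else 0L
  pivot_col <- integer(m)                  # row -> owning column
  death <- rep(K, m); creator <- logical(m)
  for (j in seq_len(m)) {
    repeat {
      lw <- low_of(B[, j])
      if (lw == 0L || pivot_col[lw] == 0L) break
      B[, j] <- (B[, j] + B[, pivot_col[lw]]) %% 2L
    }
    lw <- low_of(B[, j])
    if (lw == 0L) {
      creator[j] <- TRUE
    } else {
      pivot_col[lw] <- j
      death[lw] <- fs[j]
    }
  }
  keep <- creator & dims <= max_dim
  tibble::tibble(dimension = dims[keep], birth = fs[keep],
                 death = death[keep])
}

# canonical sort for diagram comparison
sort_diagram <- function(d) {
  d <- d[order(d$dimension, d$birth, d$death), c("dimension", "birth", "death")]
  tibble::as_tibble(d)
}

# naive double-loop k-mer recount
oracle_kmer_counts <- function(seqs, k) {
  counts <- integer(20^k)
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    if (L < k) next
    for (j in seq_len(L - k + 1)) {
      kmer <- paste(chars[j:(j + k - 1)], collapse = "")
      idx <- idpred::kmer_index(kmer)
      if (!is.na(idx)) counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

# random small point cloud, seeded
random_cloud <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(n * 3, -1, 1), n, 3))
}
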