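#' Embed a residue window as a 3-D point cloud
#'
#' Each residue of the window is mapped to a point on the unit cylinder:
#' the residue identity sets the angle (`2*pi*i/20` with `i` its 1-based
#' index in [aa_alphabet]) and the position along the window sets the
#' height, `z_m = (m - 1)/(N - 1)`. Identical residues at different
#' positions therefore share `(x, y)` but are separated in `z`, so the
#' cloud always has `N` distinct points.
#'
#' @param window Residue string of length `N >= 2`; all residues must be
#'   standard (callers substitute nonstandard letters first, see
#'   [persistent_entropy_track()]).
#' @return A tibble with `N` rows and columns `x`, `y`, `z`.
#' @examples
#' embed_window("ARV")
#' @export
embed_window <- function(window) {
  idx <- aa_index(seq_chars(window))
  n <- length(idx)
  if (n < 2) abort("window must contain at least 2 residues")
  if (anyNA(idx)) {
    abort(paste0("nonstandard residue at window position ",
                 which(is.na(idx))[1],
                 "; substitute before embedding"))
  }
  theta <- 2 * pi * idx / 20
  tibble::tibble(x = cos(theta), y = sin(theta),
                 z = (seq_len(n) - 1) / (n - 1))
}

#' Persistence diagram of the Vietoris-Rips filtration of a point cloud
#'
#' Builds the Rips filtration in the ball-intersection convention: a
#' simplex enters at scale `epsilon` equal to half the maximum pairwise
#' Euclidean distance among its vertices (balls of radius `epsilon`
#' pairwise intersect iff centres are within `2*epsilon`). Homology
#' classes alive at the filtration cap are truncated to die at the cap;
#' bars of zero length are dropped from the returned diagram but counted
#' in the `n_dim0_raw` attribute.
#'
#' @param cloud Tibble/data frame with columns `x`, `y`, `z` (or any
#'   numeric matrix of point coordinates, one row per point).
#' @param max_dim Highest homology dimension computed (0, 1 or 2;
#'   default 1).
#' @param cap Filtration cap `K > 0`, or `"auto"` (the default) for half
#'   the cloud diameter, under which the full dimension-0 merge tree is
#'   observed and exactly one dimension-0 class is truncated. A
#'   single-point cloud with `cap = "auto"` uses `K = 1`.
#' @return A tibble with columns `dimension`, `birth`, `death`
#'   (`birth < death`), with attributes `cap`, `n_points`, and
#'   `n_dim0_raw` (number of dimension-0 bars before dropping zero-length
#'   ones; always equals the number of points).
#' @examples
#' rips_persistence(embed_window("ARNDV"))
#' @export
rips_persistence <- function(cloud, max_dim = 1, cap = "auto") {
  m <- as.matrix(as.data.frame(cloud)[, intersect(c("x", "y", "z"),
                                                  names(as.data.frame(cloud)))])
  if (ncol(m) == 0) m <- as.matrix(cloud)
  storage.mode(m) <- "double"
  cap_val <- if (identical(cap, "auto")) -1 else {
    if (!is.numeric(cap) || cap <= 0) abort("cap must be positive or \"auto\"")
    as.numeric(cap)
  }
  res <- .rips_pairs_cpp(m, as.integer(max_dim), cap_val)
  d <- tibble::tibble(dimension = res$dimension,
                      birth = res$birth, death = res$death)
  n0_raw <- sum(d$dimension == 0L)
  d <- d[d$death > d$birth, ]
  attr(d, "cap") <- res$cap
  attr(d, "n_points") <- res$n_points
  attr(d, "n_dim0_raw") <- n0_raw
  d
}

#' Persistent entropy of a persistence diagram
#'
#' Shannon entropy (base 2) of the normalised bar lengths: with
#' `l_i = death_i - birth_i` and `S = sum(l_i)`,
#' `E = -sum(p_i * log2(p_i))`, `p_i = l_i / S`. The value lies in
#' `[0, log2(n)]` for `n` positive-length bars. An empty diagram has
#' entropy 0 by convention.
#'
#' @param diagram Tibble with `birth` and `death` columns (e.g. from
#'   [rips_persistence()]); zero-length bars contribute nothing.
#' @return A single non-negative number (bits).
#' @examples
#' persistent_entropy(tibble::tibble(dimension = 0, birth = 0, death = c(1, 3)))
#' @export
persistent_entropy <- function(diagram) {
  l <- diagram$death - diagram$birth
  l <- l[l > 0]
  if (length(l) == 0) return(0)
  p <- l / sum(l)
  -sum(p * log2(p))
}

#' Per-residue persistent-entropy track
#'
#' Slides an odd window along the sequence (padded at both ends with
#' copies of the terminal residues), embeds each window on the cylinder
#' ([embed_window()]), computes Rips persistence and assigns the
#' persistent entropy of the window's diagram to its central residue.
#' Nonstandard residues are replaced, within each window, by the window's
#' most frequent standard residue (ties broken toward the lowest
#' [aa_alphabet] index); a window with no standard residue at all gets
#' entropy from an all-alanine surrogate.
#'
#' @param sequence Sequence string of length `L`.
#' @param window Odd window size `N < L` (default 33).
#' @param max_dim Homology dimensions pooled into the entropy (default 1:
#'   dimensions 0 and 1 enter one diagram; on the cylindrical embedding
#'   the loops are the informative signal beyond clustering).
#' @param cap Filtration cap policy, as in [rips_persistence()].
#' @return Numeric vector of length `L` of non-negative entropies.
#' @export
persistent_entropy_track <- function(sequence, window = 33, max_dim = 1,
                                     cap = "auto") {
  L <- nchar(sequence)
  check_window(window, L)
  chars <- seq_chars(sequence)
  half <- (window - 1L) %/% 2L
  padded <- c(rep(chars[1L], half), chars, rep(chars[L], half))
  idx <- aa_index(padded)
  vapply(seq_len(L), function(j) {
    wi <- idx[j:(j + window - 1L)]
    if (anyNA(wi)) {
      std <- wi[!is.na(wi)]
      sub <- if (length(std) == 0) 1L else {
        tab <- tabulate(std, nbins = 20L)
        which.max(tab)               # ties -> lowest alphabet index
      }
      wi[is.na(wi)] <- sub
    }
    theta <- 2 * pi * wi / 20
    cloud <- cbind(cos(theta), sin(theta),
                   (seq_along(wi) - 1) / (length(wi) - 1))
    persistent_entropy(rips_persistence(cloud, max_dim = max_dim, cap = cap))
  }, numeric(1))
}

check_window <- function(window, L) {
  if (window %% 2L == 0L) abort("window size must be odd")
  if (window >= L) abort(paste0("window size ", window,
                                " must be smaller than sequence length ", L))
  invisible(window)
}
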