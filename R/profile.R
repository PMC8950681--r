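#' Zero-padded sliding-window average of a per-residue track
#'
#' Pads the track with `(N-1)/2` zeros at each end and assigns to every
#' residue the mean of the `N` padded values centred on it. This is the
#' smoothing applied to the 30 scalar channels (PSSM columns and residue
#' scales); the entropy channels use their own windows and are not
#' re-averaged.
#'
#' @param values Numeric vector of length `L`.
#' @param window Odd window size `N < L`.
#' @return Numeric vector of length `L`.
#' @examples
#' windowed_average_track(rep(1, 5), 3)  # 2/3 at the ends
#' @export
windowed_average_track <- function(values, window) {
  L <- length(values)
  check_window(window, L)
  half <- (window - 1L) %/% 2L
  padded <- c(rep(0, half), values, rep(0, half))
  cs <- cumsum(c(0, padded))
  (cs[(window + 1L):(L + window)] - cs[1L:L]) / window
}

#' Per-residue Shannon entropy track
#'
#' Residue-composition entropy (base 2) of the odd window centred on each
#' position, with terminal-residue padding at the ends (the same padding
#' as the other entropy windows). Values lie in `[0, log2(20)]` for
#' standard-alphabet sequences.
#'
#' @param sequence Sequence string.
#' @param window Odd window size `N < L`.
#' @return Numeric vector of length `L`.
#' @export
shannon_entropy_track <- function(sequence, window) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  check_window(window, L)
  half <- (window - 1L) %/% 2L
  padded <- c(rep(chars[1L], half), chars, rep(chars[L], half))
  vapply(seq_len(L), function(j) {
    f <- table(padded[j:(j + window - 1L)]) / window
    -sum(f * log2(f))
  }, numeric(1))
}

#' Per-residue topological entropy track
#'
#' Subword-complexity entropy of each window: for the largest word length
#' `n` with `20^n + n - 1 <= N`, the value is
#' `log20(number of distinct n-subwords of the first 20^n + n - 1 window
#' characters) / n`, which lies in `[0, 1]`. With the default window
#' `N = 33` this calibration gives `n = 1` (single-residue subwords of
#' the first 20 characters). Windows use terminal-residue padding.
#'
#' @param sequence Sequence string.
#' @param window Odd window size, `20 <= N < L`.
#' @return Numeric vector of length `L` with values in `[0, 1]`.
#' @export
topological_entropy_track <- function(sequence, window) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  check_window(window, L)
  n_word <- 0L
  while (20^(n_word + 1L) + n_word <= window) n_word <- n_word + 1L
  if (n_word == 0L) {
    abort(paste0("window too small for topological entropy (need >= 20, got ",
                 window, ")"))
  }
  prefix_len <- as.integer(20^n_word + n_word - 1L)
  half <- (window - 1L) %/% 2L
  padded <- c(rep(chars[1L], half), chars, rep(chars[L], half))
  vapply(seq_len(L), function(j) {
    w <- padded[j:(j + prefix_len - 1L)]
    subwords <- vapply(seq_len(prefix_len - n_word + 1L), function(t) {
      paste(w[t:(t + n_word - 1L)], collapse = "")
    }, character(1))
    log(length(unique(subwords)), base = 20) / n_word
  }, numeric(1))
}

#' BLOSUM62 pseudo-profile for a sequence
#'
#' Fallback evolutionary profile when no PSI-BLAST PSSM is available:
#' each residue's row is its BLOSUM62 substitution-score row, giving a
#' composition-only stand-in for a true search-derived profile. Requires
#' the Biostrings package (for its BLOSUM62 matrix).
#'
#' @param sequence Sequence string.
#' @return An `L x 20` matrix, columns in [aa_alphabet] order.
#' @export
blosum_pseudo_pssm <- function(sequence) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("blosum_pseudo_pssm() needs the Biostrings package")
  }
  blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                            envir = environment()))
  chars <- seq_chars(sequence)
  known <- intersect(rownames(blosum), c(chars, "X"))
  rows <- ifelse(chars %in% rownames(blosum), chars,
                 ifelse("X" %in% rownames(blosum), "X", NA))
  m <- matrix(0, nrow = length(chars), ncol = 20,
              dimnames = list(NULL, aa_alphabet))
  ok <- !is.na(rows)
  m[ok, ] <- blosum[rows[ok], aa_alphabet, drop = FALSE]
  m
}

#' Names of the 35 feature channels, in matrix row order
#' @return Character vector of length 35.
#' @export
feature_row_names <- function() {
  c(paste0("pssm_", aa_alphabet), names(.scale_values),
    "shannon_entropy", "topological_entropy", "persistent_entropy",
    "pcaa2", "pcaa3")
}

#' Assemble the 35 x L per-residue feature matrix
#'
#' Stacks, for each residue, 20 window-averaged PSSM channels, 10
#' window-averaged residue-scale channels, the Shannon, topological and
#' persistent entropy tracks, and the PCAA2/PCAA3 tracks. The 30 scalar
#' channels are smoothed with the zero-padded window average
#' ([windowed_average_track()]); the entropy tracks are computed on
#' their own terminal-padded windows and not re-averaged; PCAA tracks
#' are local to `k` residues. Nonstandard residues contribute 0 to the
#' scale channels.
#'
#' @param sequence Sequence string of length `L > window`.
#' @param pssm `L x 20` profile matrix (see [read_pssm()]), or `NULL`.
#' @param kmer2,kmer3 Finalized k-mer tables (k = 2 and 3).
#' @param scales Scale tables as from [default_scales()].
#' @param window Odd window size (default 33).
#' @param max_dim,cap Passed to [persistent_entropy_track()].
#' @param pssm_missing What to do when `pssm` is `NULL`: `"error"`
#'   (default) or `"blosum62"` for the [blosum_pseudo_pssm()] fallback.
#' @return A `35 x L` numeric matrix with rownames
#'   [feature_row_names()].
#' @export
assemble_feature_matrix <- function(sequence, pssm, kmer2, kmer3,
                                    scales = default_scales(), window = 33,
                                    max_dim = 1, cap = "auto",
                                    pssm_missing = c("error", "blosum62")) {
  pssm_missing <- match.arg(pssm_missing)
  L <- nchar(sequence)
  check_window(window, L)
  if (is.null(pssm)) {
    if (pssm_missing == "error") {
      abort("no PSSM supplied; pass pssm_missing = \"blosum62\" for the fallback profile")
    }
    pssm <- blosum_pseudo_pssm(sequence)
  }
  if (nrow(pssm) != L) abort("PSSM row count != sequence length")
  chars <- seq_chars(sequence)
  idx <- aa_index(chars)

  pssm_rows <- apply(pssm, 2, windowed_average_track, window = window)
  scale_rows <- vapply(scales, function(v) {
    raw <- ifelse(is.na(idx), 0, v[idx])
    windowed_average_track(raw, window)
  }, numeric(L))

  F <- rbind(t(pssm_rows), t(scale_rows),
             shannon_entropy_track(sequence, window),
             topological_entropy_track(sequence, window),
             persistent_entropy_track(sequence, window, max_dim = max_dim,
                                      cap = cap),
             pcaa_track(sequence, kmer2),
             pcaa_track(sequence, kmer3))
  rownames(F) <- feature_row_names()
  if (any(!is.finite(F))) abort("feature matrix contains non-finite values")
  F
}

#' Feature matrices for a whole corpus
#'
#' @param records Tibble with `id` and `sequence` (and optionally a
#'   `labels` list-column).
#' @param pssms Named list of `L x 20` matrices keyed by record id, or
#'   `NULL` (then `pssm_missing` applies to every record).
#' @param ... Passed to [assemble_feature_matrix()].
#' @return Named list of `35 x L` matrices, one per record.
#' @export
featurize_corpus <- function(records, pssms = NULL, ...) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    assemble_feature_matrix(records$sequence[i],
                            pssm = pssms[[records$id[i]]], ...)
  })
  names(out) <- records$id
  out
}

#' Pool per-protein feature matrices into a residue-level design matrix
#'
#' @param features Named list of `35 x L` matrices (see
#'   [featurize_corpus()]).
#' @param records Matching records tibble; if it has a `labels`
#'   list-column the pooled label vector is returned too.
#' @return List with `x` (n_residues x 35 matrix), `y` (integer labels or
#'   `NULL`) and `meta` (tibble `id`, `pos`, `residue`).
#' @export
pool_features <- function(features, records) {
  stopifnot(all(records$id %in% names(features)))
  xs <- lapply(records$id, function(id) t(features[[id]]))
  meta <- tibble::tibble(
    id = rep(records$id, vapply(xs, nrow, integer(1))),
    pos = unlist(lapply(xs, function(m) seq_len(nrow(m)))),
    residue = unlist(lapply(records$sequence, seq_chars))
  )
  y <- if ("labels" %in% names(records) &&
           all(lengths(records$labels) == nchar(records$sequence))) {
    as.integer(unlist(records$labels))
  }
  list(x = do.call(rbind, xs), y = y, meta = meta)
}

#' Write a feature matrix as TSV (one column per residue)
#' @param feature_matrix `35 x L` matrix from [assemble_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(feature_matrix, path) {
  df <- tibble::as_tibble(feature_matrix, .name_repair = function(x) {
    paste0("res", seq_along(x))
  })
  df <- dplyr::bind_cols(tibble::tibble(feature = rownames(feature_matrix)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Path to the TSV.
#' @return A `35 x L` numeric matrix with feature rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$feature
  colnames(m) <- NULL
  m
}

#' Long-format view of a feature matrix
#' @param x A `35 x L` feature matrix.
#' @return Tibble with columns `feature`, `pos`, `value`.
#' @export
tidy_feature_matrix <- function(x) {
  tibble::tibble(
    feature = rep(rownames(x), times = ncol(x)),
    pos = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.numeric(x)
  )
}
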