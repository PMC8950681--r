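#' Mixed-radix index of a di- or tripeptide
#'
#' Enumerates all `20^k` k-mers in the alphabetical order induced by
#' [aa_alphabet]: `AA, AR, AN, ..., VY, VV` for `k = 2` and
#' `AAA, AAR, ..., VVV` for `k = 3`. The index of a k-mer with residue
#' indices `i_1..i_k` is `sum(20^(k-t) * (i_t - 1)) + i_k`.
#'
#' @param kmers Character vector of k-mer strings, all of one length
#'   `k` in `{2, 3}`.
#' @return Integer vector of 1-based indices in `1..20^k`; `NA` for
#'   k-mers containing nonstandard residues.
#' @examples
#' kmer_index(c("AA", "RA", "VV"))
#' @export
kmer_index <- function(kmers) {
  k <- unique(nchar(kmers))
  if (length(k) == 0) return(integer())
  if (length(k) != 1 || !k %in% c(2L, 3L)) {
    abort("all k-mers must have the same length, 2 or 3")
  }
  idx <- aa_index(unlist(strsplit(kmers, "", fixed = TRUE)))
  m <- matrix(idx, nrow = k)
  out <- rep(0L, ncol(m))
  for (t in seq_len(k)) out <- out + as.integer(20^(k - t)) * (m[t, ] - 1L)
  as.integer(out + 1L)
}

#' Inverse of [kmer_index()]
#' @param index Integer vector in `1..20^k`.
#' @param k K-mer length (2 or 3).
#' @return Character vector of k-mer strings.
#' @export
kmer_unindex <- function(index, k) {
  i0 <- index - 1L
  chars <- matrix("", nrow = k, ncol = length(index))
  for (t in rev(seq_len(k))) {
    chars[t, ] <- aa_alphabet[(i0 %% 20L) + 1L]
    i0 <- i0 %/% 20L
  }
  apply(chars, 2, paste, collapse = "")
}

#' Count k-mers over a sequence corpus
#'
#' Slides by one residue over every sequence and tallies each standard
#' k-mer; k-mers containing nonstandard residues are skipped, so the
#' total count over a standard-alphabet corpus equals
#' `sum(L_p - k + 1)`.
#'
#' @param corpus Tibble with a `sequence` column (e.g. from
#'   [read_fasta()]), or a character vector of sequences.
#' @param k K-mer length (2 or 3).
#' @param corpus_id Identifier stored with the table.
#' @return A k-mer table: tibble with one row per possible k-mer and
#'   columns `index`, `kmer`, `count`, plus attributes `k` and
#'   `corpus_id`. Pass through [finalize_kmer_table()] before use in
#'   [pcaa_track()].
#' @examples
#' count_kmers(c("ARN", "ARN"), k = 2)
#' @export
count_kmers <- function(corpus, k, corpus_id = "corpus") {
  seqs <- if (is.data.frame(corpus)) corpus$sequence else as.character(corpus)
  if (length(seqs) == 0) abort("corpus is empty")
  if (!k %in% c(2L, 3L)) abort("k must be 2 or 3")
  nbins <- as.integer(20^k)
  counts <- integer(nbins)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    idx <- sliding_kmer_index(s, k)
    counts <- counts + tabulate(idx[!is.na(idx)], nbins = nbins)
  }
  if (sum(counts) == 0) {
    warn("no k-mers counted (all sequences shorter than k?)")
  }
  tbl <- tibble::tibble(index = seq_len(nbins),
                        kmer = kmer_unindex(seq_len(nbins), k),
                        count = counts)
  attr(tbl, "k") <- as.integer(k)
  attr(tbl, "corpus_id") <- corpus_id
  tbl
}

# indices of the k-mers starting at positions 1..L-k+1 (NA where any
# residue is nonstandard)
sliding_kmer_index <- function(sequence, k) {
  idx <- aa_index(seq_chars(sequence))
  L <- length(idx)
  n <- L - k + 1L
  if (n < 1L) return(integer())
  out <- rep(0L, n)
  for (t in seq_len(k)) {
    out <- out + as.integer(20^(k - t)) * (idx[t:(t + n - 1L)] - 1L)
  }
  out + 1L
}

#' Fill probabilities and min-max scaled values of a k-mer table
#'
#' `probability = count / sum(count)`; `scaled` is the min-max rescaling
#' of the probabilities to `[0, 1]`. When all probabilities are equal
#' (range zero) every scaled value is defined to be 1.
#'
#' @param table K-mer table from [count_kmers()].
#' @return The table with `probability` and `scaled` columns added.
#' @export
finalize_kmer_table <- function(table) {
  total <- sum(table$count)
  if (total == 0) abort("empty corpus statistics: total k-mer count is zero")
  p <- table$count / total
  delta <- max(p) - min(p)
  table$probability <- p
  table$scaled <- if (delta == 0) rep(1, length(p)) else (p - min(p)) / delta
  table
}

#' Build a finalized k-mer table in one call
#' @inheritParams count_kmers
#' @return A finalized k-mer table (see [finalize_kmer_table()]).
#' @export
build_kmer_table <- function(corpus, k, corpus_id = "corpus") {
  finalize_kmer_table(count_kmers(corpus, k, corpus_id))
}

#' Per-residue PCAA track from a k-mer table
#'
#' The scaled corpus probability of every k-mer starting in the sequence
#' is spread back onto residues: residue `j` receives the mean of the
#' scaled values of the (at most `k`) k-mers covering it, i.e. those
#' starting at positions `max(1, j-k+1)..min(j, L-k+1)`. At the termini
#' fewer k-mers cover the residue and the mean runs over the existing
#' ones only. K-mers containing nonstandard residues contribute value 0
#' to their averages. The sequence need not be part of the table's
#' corpus.
#'
#' @param sequence Sequence string with `nchar(sequence) >= k`.
#' @param table Finalized k-mer table.
#' @return Numeric vector of length `L` with values in `[0, 1]`.
#' @examples
#' tab <- build_kmer_table("AAA", k = 2)
#' pcaa_track("AAA", tab)
#' @export
pcaa_track <- function(sequence, table) {
  k <- attr(table, "k")
  if (is.null(k)) abort("table lacks a k attribute; build it with count_kmers()")
  if (!"scaled" %in% names(table)) {
    abort("table is not finalized; call finalize_kmer_table()")
  }
  L <- nchar(sequence)
  if (L < k) abort(paste0("sequence shorter than k = ", k))
  idx <- sliding_kmer_index(sequence, k)
  vals <- ifelse(is.na(idx), 0, table$scaled[idx])
  n <- length(vals)                       # L - k + 1
  vapply(seq_len(L), function(j) {
    lo <- max(1L, j - k + 1L)
    hi <- min(j, n)
    mean(vals[lo:hi])
  }, numeric(1))
}

#' Write a k-mer table to TSV
#' @param table Finalized k-mer table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  out <- table
  out$k <- attr(table, "k")
  out$corpus_id <- attr(table, "corpus_id") %||% NA_character_
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a k-mer table written by [write_kmer_table()]
#' @param path Path to the TSV.
#' @return A finalized k-mer table.
#' @export
read_kmer_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl <- tibble::as_tibble(raw[, c("index", "kmer", "count",
                                   intersect(c("probability", "scaled"),
                                             names(raw)))])
  attr(tbl, "k") <- as.integer(raw$k[1])
  attr(tbl, "corpus_id") <- as.character(raw$corpus_id[1])
  tbl
}
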