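#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and returned in file order. Nonstandard
#' residue letters are kept in the sequence and reported in the
#' `nonstandard` list-column (1-based positions), so downstream feature
#' modules can apply their documented substitution rules.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `sequence`, and `nonstandard` (list of integer
#'   positions).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ARN", ">p2", "vv"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble::tibble(id = character(), sequence = character(),
                          nonstandard = list()))
  }
  header <- startsWith(lines, ">")
  if (!header[1L]) {
    abort(paste0("malformed FASTA: line 1 of ", path,
                 " does not start with '>'"))
  }
  grp <- cumsum(header)
  ids <- vapply(lines[header], function(h) {
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort(paste0("malformed FASTA header (empty id) at line ",
                 which(header)[which(!nzchar(ids) | is.na(ids))[1]],
                 " of ", path))
  }
  seqs <- vapply(split(lines[!header], grp[!header]),
                 function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                 character(1))
  # headers with no sequence lines yield empty strings
  full <- setNames(character(length(ids)), seq_along(ids))
  full[names(seqs)] <- seqs
  tibble::tibble(
    id = ids,
    sequence = unname(full),
    nonstandard = lapply(unname(full), nonstandard_positions)
  )
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  writeLines(rbind(paste0(">", records$id), records$sequence), path)
  invisible(path)
}

#' Read per-residue disorder labels
#'
#' The label file uses a simple three-line dialect: a `>id` header, the
#' sequence, then a line of `0`/`1` characters of equal length
#' (`1` = disordered).
#'
#' @param path Path to a label file.
#' @return A tibble with columns `id`, `sequence`, and `labels` (list of
#'   integer 0/1 vectors).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c(">p1", "ARN", "011"), f)
#' read_labels(f)
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L) {
    abort(paste0("label file ", path,
                 ": expected groups of 3 lines (>id / sequence / labels)"))
  }
  n <- length(lines) %/% 3L
  ids <- character(n); seqs <- character(n); labs <- vector("list", n)
  for (i in seq_len(n)) {
    h <- lines[3L * i - 2L]
    if (!startsWith(h, ">")) {
      abort(paste0("label file ", path, ": expected '>' header at entry ", i))
    }
    ids[i] <- strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1]
    seqs[i] <- toupper(trimws(lines[3L * i - 1L]))
    lab <- trimws(lines[3L * i])
    if (nchar(lab) != nchar(seqs[i])) {
      abort(paste0("label length ", nchar(lab), " != sequence length ",
                   nchar(seqs[i]), " for id '", ids[i], "'"))
    }
    if (grepl("[^01]", lab)) {
      abort(paste0("labels for id '", ids[i], "' contain characters other than 0/1"))
    }
    labs[[i]] <- as.integer(seq_chars(lab))
  }
  tibble::tibble(id = ids, sequence = seqs, labels = labs)
}

#' Write per-residue disorder labels
#'
#' Inverse of [read_labels()] (three-line dialect).
#'
#' @param records Tibble with columns `id`, `sequence`, `labels`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  stopifnot(all(c("id", "sequence", "labels") %in% names(records)))
  lab <- vapply(records$labels, function(l) paste(l, collapse = ""), character(1))
  writeLines(rbind(paste0(">", records$id), records$sequence, lab), path)
  invisible(path)
}

#' Attach labels to sequence records
#'
#' Joins a label table onto FASTA records by `id`, checking that sequences
#' agree where both are present.
#'
#' @param records Tibble from [read_fasta()].
#' @param labels Tibble from [read_labels()].
#' @return `records` with a `labels` list-column (`NULL` entries where no
#'   labels exist).
#' @export
attach_labels <- function(records, labels) {
  idx <- match(records$id, labels$id)
  both <- !is.na(idx)
  if (any(both)) {
    bad <- records$id[both][records$sequence[both] != labels$sequence[idx[both]]]
    if (length(bad) > 0) {
      abort(paste0("sequence mismatch between FASTA and label file for id(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  out <- vector("list", nrow(records))
  out[both] <- labels$labels[idx[both]]
  records$labels <- out
  records
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue whose first 20 numeric columns (after the position and residue
#' letter) are the log-odds scores. Only those 20 columns are retained;
#' they are in the same residue order as [aa_alphabet].
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional sequence string to validate row count and
#'   residue letters against.
#' @return An `L x 20` numeric matrix with `colnames` [aa_alphabet] and a
#'   `residue` attribute holding the residue letters of the rows.
#' @export
read_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path)
  rows <- list(); res <- character(); started <- FALSE
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    is_row <- length(tok) >= 22 && grepl("^[0-9]+$", tok[1]) &&
      grepl("^[A-Za-z]$", tok[2])
    if (!is_row) {
      if (started && nzchar(trimws(lines[i])) &&
          grepl("^[0-9]", trimws(lines[i]))) {
        abort(paste0("unparseable PSSM row at line ", i, " of ", path))
      }
      next
    }
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      abort(paste0("unparseable PSSM row at line ", i, " of ", path))
    }
    started <- TRUE
    rows[[length(rows) + 1L]] <- scores
    res[length(res) + 1L] <- toupper(tok[2])
  }
  if (length(rows) == 0L) abort(paste0("no PSSM rows found in ", path))
  m <- do.call(rbind, rows)
  colnames(m) <- aa_alphabet
  attr(m, "residue") <- res
  if (!is.null(sequence) && nrow(m) != nchar(sequence)) {
    abort(paste0("PSSM has ", nrow(m), " rows but sequence has ",
                 nchar(sequence), " residues (", path, ")"))
  }
  m
}

#' Write a PSSM in PSI-BLAST ASCII format
#'
#' Writes the dialect read back by [read_pssm()]: two header lines, a
#' column-letter line, then one row per residue with the 20 log-odds
#' scores (a second block of 20 zero columns pads the row to the width of
#' genuine PSI-BLAST output).
#'
#' @param pssm `L x 20` numeric matrix, columns in [aa_alphabet] order.
#' @param sequence Sequence string of length `L` (row residue letters).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, sequence, path) {
  L <- nchar(sequence)
  if (nrow(pssm) != L) abort("PSSM row count != sequence length")
  chars <- seq_chars(sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", aa_alphabet), collapse = " "),
                      " ", paste(sprintf("%3s", aa_alphabet), collapse = " "))),
             con)
  for (j in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s  ", j, chars[j]),
                      paste(sprintf("%3d", round(pssm[j, ])), collapse = " "),
                      " ",
                      paste(sprintf("%3d", rep(0L, 20)), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Write per-residue predictions as TSV
#'
#' @param predictions Tibble with columns `id`, `pos` (1-based residue
#'   index), `residue`, `probability`, `call`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("id", "pos", "residue", "probability", "call")
  if (!all(need %in% names(predictions))) {
    abort(paste0("predictions must have columns: ", paste(need, collapse = ", ")))
  }
  readr::write_tsv(predictions[need], path, progress = FALSE)
  invisible(path)
}

#' Read a per-residue prediction TSV written by [write_predictions()]
#' @param path Path to the TSV.
#' @return A tibble with columns `id`, `pos`, `residue`, `probability`, `call`.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    pos = readr::col_integer(),
                    residue = readr::col_character(),
                    probability = readr::col_double(),
                    call = readr::col_integer()))
}

#' Summarise a labelled corpus
#'
#' Counts proteins and ordered/disordered residues, the summary used to
#' sanity-check corpus loaders.
#'
#' @param records Tibble with `id`, `sequence` and a `labels` list-column.
#' @return One-row tibble: `n_proteins`, `n_residues`, `n_disordered`,
#'   `n_ordered`, `disordered_fraction`.
#' @export
corpus_summary <- function(records) {
  lab <- unlist(records$labels)
  tibble::tibble(
    n_proteins = nrow(records),
    n_residues = sum(nchar(records$sequence)),
    n_disordered = sum(lab == 1L),
    n_ordered = sum(lab == 0L),
    disordered_fraction = sum(lab == 1L) / length(lab)
  )
}
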