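#' Per-residue confusion counts
#'
#' The positive class is disordered (label 1).
#'
#' @param calls Integer/logical vector of predicted classes (0/1).
#' @param truth Integer/logical vector of reference labels (0/1), same
#'   length.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' confusion_counts(c(1, 0), c(0, 1))
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    abort(paste0("calls (", length(calls), ") and truth (", length(truth),
                 ") differ in length"))
  }
  calls <- as.integer(calls); truth <- as.integer(truth)
  if (any(!calls %in% 0:1) || any(!truth %in% 0:1)) {
    abort("calls and truth must be 0/1")
  }
  c(tp = sum(calls == 1L & truth == 1L),
    fp = sum(calls == 1L & truth == 0L),
    tn = sum(calls == 0L & truth == 0L),
    fn = sum(calls == 0L & truth == 1L))
}

#' Sensitivity, specificity, balanced accuracy and MCC from counts
#'
#' `Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, `BACC = (Sens+Spec)/2`, and
#' the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any MCC marginal is empty the coefficient is defined as 0 (the
#' usual convention for constant predictions); an undefined sensitivity
#' or specificity (empty class) is reported as `NaN` with a warning.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts. `tp` may also be
#'   the named vector returned by [confusion_counts()].
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sens`, `spec`,
#'   `bacc`, `mcc`.
#' @examples
#' compute_metrics(3, 1, 5, 1)
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4L && is.null(fp)) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  if (sum(counts) == 0) abort("all confusion counts are zero")
  sens <- if (tp + fn == 0) {
    warn("no positive residues in truth; sensitivity undefined (NaN)")
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warn("no negative residues in truth; specificity undefined (NaN)")
    NaN
  } else tn / (tn + fp)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sens = sens, spec = spec, bacc = (sens + spec) / 2,
                 mcc = mcc)
}

#' Evaluate per-residue predictions against labels
#'
#' Counts are pooled over all residues of all proteins before the
#' metrics are computed (residue-level evaluation); `per_protein = TRUE`
#' instead returns one metrics row per protein.
#'
#' @param predictions Prediction tibble with `id` and `call` columns
#'   (e.g. from [predict_corpus()]).
#' @param records Records tibble with `id` and a `labels` list-column.
#' @param per_protein Evaluate each protein separately (default `FALSE`).
#' @return Metrics tibble (one row, or one per protein with an `id`
#'   column).
#' @export
evaluate_predictions <- function(predictions, records, per_protein = FALSE) {
  truth_tbl <- tibble::tibble(
    id = rep(records$id, lengths(records$labels)),
    pos = unlist(lapply(records$labels, seq_along)),
    truth = as.integer(unlist(records$labels))
  )
  joined <- dplyr::inner_join(predictions, truth_tbl, by = c("id", "pos"))
  if (nrow(joined) == 0) abort("no residues shared between predictions and labels")
  if (per_protein) {
    joined |>
      dplyr::group_by(.data$id) |>
      dplyr::group_modify(function(d, g) {
        compute_metrics(confusion_counts(d$call, d$truth))
      }) |>
      dplyr::ungroup()
  } else {
    compute_metrics(confusion_counts(joined$call, joined$truth))
  }
}

#' Seeded protein-level fold assignment for cross-validation
#'
#' Folds are assigned at the protein level (all residues of a protein
#' stay in one fold) and depend only on the ids and the seed.
#'
#' @param ids Character vector of protein ids.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Tibble `id`, `fold`.
#' @export
cv_assign_folds <- function(ids, folds, seed = 1L) {
  if (folds < 2) abort("folds must be >= 2")
  if (length(ids) < folds) {
    abort(paste0("fewer proteins (", length(ids), ") than folds (", folds, ")"))
  }
  sorted <- sort(ids)                    # independent of input order
  perm <- withr::with_seed(seed, sample(sorted))
  fold_map <- setNames(rep_len(seq_len(folds), length(perm)), perm)
  tibble::tibble(id = ids, fold = unname(fold_map[ids]))
}
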