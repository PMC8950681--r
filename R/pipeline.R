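#' Train a disorder predictor end-to-end on a labelled corpus
#'
#' Builds the di-/tripeptide tables from the corpus (the k-mer scope),
#' assembles the 35 x L feature matrix of every protein, pools residues
#' and trains the classifier. The returned predictor bundles everything
#' needed to featurize and score new proteins consistently.
#'
#' @param records Tibble with `id`, `sequence` and a `labels`
#'   list-column.
#' @param pssms Named list of `L x 20` profile matrices keyed by id, or
#'   `NULL` with `pssm_missing = "blosum62"`.
#' @param window Odd sliding-window size (default 33).
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param kmer_records Corpus used for the k-mer tables; defaults to
#'   `records` (the training set). Pass a larger corpus to emulate
#'   table construction on training + test material.
#' @param scales Residue scale tables (default [default_scales()]).
#' @param pssm_missing Passed to [assemble_feature_matrix()].
#' @return An `idpred_predictor` with elements `fit`, `kmer2`, `kmer3`,
#'   `window`, `scales`, `config`.
#' @export
train_predictor <- function(records, pssms, window = 33,
                            config = model_config("small"),
                            tc = train_config(),
                            kmer_records = records,
                            scales = default_scales(),
                            pssm_missing = c("error", "blosum62")) {
  pssm_missing <- match.arg(pssm_missing)
  if (!"labels" %in% names(records) || any(lengths(records$labels) == 0)) {
    abort("all records need per-residue labels for training")
  }
  kmer2 <- build_kmer_table(kmer_records, 2, "train")
  kmer3 <- build_kmer_table(kmer_records, 3, "train")
  feats <- featurize_corpus(records, pssms, kmer2 = kmer2, kmer3 = kmer3,
                            scales = scales, window = window,
                            pssm_missing = pssm_missing)
  pooled <- pool_features(feats, records)
  model <- build_model(config, seed = tc$seed)
  fit <- train_network(model, pooled$x, pooled$y, tc)
  structure(list(fit = fit, kmer2 = kmer2, kmer3 = kmer3, window = window,
                 scales = scales, config = config,
                 pssm_missing = pssm_missing),
            class = "idpred_predictor")
}

#' Score every protein of a corpus with a trained predictor
#'
#' @param predictor An `idpred_predictor` from [train_predictor()].
#' @param records Tibble with `id` and `sequence`.
#' @param pssms Named list of profile matrices, or `NULL`.
#' @param threshold Call threshold; defaults to the model config's.
#' @return Prediction tibble: `id`, `pos`, `residue`, `probability`,
#'   `call`.
#' @export
predict_corpus <- function(predictor, records, pssms = NULL,
                           threshold = NULL) {
  stopifnot(inherits(predictor, "idpred_predictor"))
  feats <- featurize_corpus(records, pssms,
                            kmer2 = predictor$kmer2, kmer3 = predictor$kmer3,
                            scales = predictor$scales,
                            window = predictor$window,
                            pssm_missing = predictor$pssm_missing)
  purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    pr <- predict_protein(predictor$fit, feats[[id]], threshold)
    tibble::tibble(id = id, pos = pr$pos, residue = seq_chars(seq),
                   probability = pr$probability, call = pr$call)
  })
}

#' @export
predict.idpred_predictor <- function(object, records, pssms = NULL,
                                     threshold = NULL, ...) {
  predict_corpus(object, records, pssms, threshold)
}

#' Protein-level k-fold cross-validation
#'
#' Folds are assigned at the protein level with [cv_assign_folds()]; for
#' each fold a predictor is trained on the remaining folds and evaluated
#' on the held-out proteins. Metrics are reported per fold and pooled
#' over all held-out residues.
#'
#' @inheritParams train_predictor
#' @param folds Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param kmer_scope `"train"` (default): k-mer tables are built from
#'   each fold's training proteins only; `"all"`: from the full corpus,
#'   emulating table construction on the complete dataset.
#' @return List with `per_fold` (metrics tibble, one row per fold) and
#'   `pooled` (one-row metrics tibble over all held-out residues).
#' @export
cross_validate <- function(records, pssms, folds = 10, window = 33,
                           config = model_config("small"),
                           tc = train_config(), seed = 1L,
                           kmer_scope = c("train", "all"),
                           scales = default_scales(),
                           pssm_missing = c("error", "blosum62")) {
  kmer_scope <- match.arg(kmer_scope)
  pssm_missing <- match.arg(pssm_missing)
  assign <- cv_assign_folds(records$id, folds, seed)
  per_fold <- vector("list", folds)
  pooled_counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (f in seq_len(folds)) {
    test_ids <- assign$id[assign$fold == f]
    train_rec <- records[!records$id %in% test_ids, ]
    test_rec <- records[records$id %in% test_ids, ]
    pred <- train_predictor(
      train_rec, pssms, window = window, config = config, tc = tc,
      kmer_records = if (kmer_scope == "all") records else train_rec,
      scales = scales, pssm_missing = pssm_missing)
    preds <- predict_corpus(pred, test_rec, pssms)
    truth <- as.integer(unlist(test_rec$labels))
    counts <- confusion_counts(preds$call, truth)
    pooled_counts <- pooled_counts + counts
    per_fold[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f),
                                      compute_metrics(counts))
  }
  list(per_fold = dplyr::bind_rows(per_fold),
       pooled = compute_metrics(pooled_counts))
}

#' @export
print.idpred_predictor <- function(x, ...) {
  cat("idpred predictor: window", x$window, "|", x$config$scale,
      "scale model |", nrow(x$fit$history), "training epochs\n")
  invisible(x)
}
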