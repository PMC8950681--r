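# Synthetic labelled corpora with a planted compositional disorder
# signal: proteins alternate ordered and disordered blocks; disordered
# blocks are enriched in disorder-promoting residues (P, E, S, Q, K, G)
# and depleted in order-promoting ones (W, C, F, I, Y, V, L), mirroring
# the compositional bias real disordered regions show. Fabricated PSSMs
# carry the same signal as integer log-odds of the generating
# composition against the background, plus seeded noise.

.biased_simplex <- function(up, weight = 3) {
  w <- rep(1, 20)
  w[match(up, aa_alphabet)] <- weight
  w / sum(w)
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer `c(min, max)` sequence length; `min` must
#'   exceed the window size used downstream.
#' @param disorder_fraction Target fraction of disordered residues
#'   (strictly between 0 and 1; default 0.2, roughly the share seen in
#'   curated disorder corpora).
#' @param mean_block_length Mean length of a disordered block (geometric
#'   distribution; default 30). Ordered blocks get mean
#'   `mean_block_length * (1 - f) / f` so the target fraction is met in
#'   expectation.
#' @param disorder_composition,order_composition Probability vectors over
#'   [aa_alphabet] (must sum to 1). Defaults up-weight the
#'   disorder-promoting and order-promoting residue sets by a factor of 3
#'   over a uniform background.
#' @param pssm_noise Standard deviation of the Gaussian noise added to
#'   fabricated PSSM log-odds before integer rounding (default 0.5).
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins, length_range,
                         disorder_fraction = 0.2,
                         mean_block_length = 30,
                         disorder_composition = .biased_simplex(
                           c("P", "E", "S", "Q", "K", "G")),
                         order_composition = .biased_simplex(
                           c("W", "C", "F", "I", "Y", "V", "L")),
                         pssm_noise = 0.5, seed = 1L) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] >= 2, length_range[1] <= length_range[2],
            mean_block_length >= 1, pssm_noise >= 0)
  if (disorder_fraction <= 0 || disorder_fraction >= 1) {
    abort("disorder_fraction must be strictly between 0 and 1")
  }
  for (p in list(disorder_composition, order_composition)) {
    if (length(p) != 20 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort("compositions must be length-20 probability vectors summing to 1")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 disorder_fraction = disorder_fraction,
                 mean_block_length = mean_block_length,
                 disorder_composition = disorder_composition,
                 order_composition = order_composition,
                 pssm_noise = pssm_noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' Documented planted-signal configurations
#'
#' The fixed study conditions used by the package's own evaluation:
#' `"small"` gives 60 proteins of length 120-200 (desk-scale training and
#' held-out evaluation), `"standard"` 400 proteins of length 100-600.
#' Both use a 20% disorder fraction and mean disordered-block length 30.
#'
#' @param scale `"small"` or `"standard"`.
#' @param seed Integer seed (default 1).
#' @return A [synth_config()].
#' @export
default_planted_config <- function(scale = c("small", "standard"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "small") {
    synth_config(60, c(120L, 200L), seed = seed)
  } else {
    synth_config(400, c(100L, 600L), seed = seed)
  }
}

#' Generate a synthetic labelled corpus with fabricated PSSMs
#'
#' Each protein is grown as alternating ordered/disordered blocks
#' (geometric block lengths; the starting state is disordered with
#' probability `disorder_fraction`), residues drawn from the
#' state-specific composition, labels equal to the state. The PSSM row
#' of every residue is `round(2 * log2(p_state / background) + noise)`
#' where the background is the corpus-level mixture composition.
#'
#' @param config A [synth_config()].
#' @return List with `records` (tibble `id`, `sequence`, `labels`) and
#'   `pssms` (named list of `L x 20` integer matrices).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  f <- config$disorder_fraction
  mean_dis <- config$mean_block_length
  mean_ord <- mean_dis * (1 - f) / f
  background <- f * config$disorder_composition +
    (1 - f) * config$order_composition
  logodds <- rbind(
    ordered = 2 * log2(config$order_composition / background),
    disordered = 2 * log2(config$disorder_composition / background)
  )
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    ids <- sprintf("synth%04d", seq_len(n))
    seqs <- character(n); labs <- vector("list", n)
    pssms <- vector("list", n)
    for (i in seq_len(n)) {
      L <- lens[i]
      state <- integer(0); pos <- 0L
      cur <- as.integer(runif(1) < f)            # 1 = disordered
      while (pos < L) {
        mu <- if (cur == 1L) mean_dis else mean_ord
        block <- rgeom(1, 1 / mu) + 1L
        state <- c(state, rep(cur, block))
        pos <- pos + block
        cur <- 1L - cur
      }
      state <- state[seq_len(L)]
      comp <- rbind(config$order_composition, config$disorder_composition)
      res_idx <- vapply(state, function(s) {
        sample.int(20L, 1L, prob = comp[s + 1L, ])
      }, integer(1))
      seqs[i] <- paste(aa_alphabet[res_idx], collapse = "")
      labs[[i]] <- state
      noise <- matrix(rnorm(L * 20, sd = config$pssm_noise), nrow = L)
      pssms[[i]] <- round(logodds[state + 1L, , drop = FALSE] + noise)
      dimnames(pssms[[i]]) <- list(NULL, aa_alphabet)
    }
    names(pssms) <- ids
    list(records = tibble::tibble(id = ids, sequence = seqs, labels = labs),
         pssms = pssms)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits a FASTA file, a three-line label file, and one PSI-BLAST-style
#' ASCII PSSM per protein (through [write_pssm()], so the real parser is
#' exercised on the fabricated profiles).
#'
#' @param corpus List from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  write_fasta(corpus$records, file.path(dir, "sequences.fasta"))
  write_labels(corpus$records, file.path(dir, "labels.txt"))
  for (id in corpus$records$id) {
    write_pssm(corpus$pssms[[id]],
               corpus$records$sequence[corpus$records$id == id],
               file.path(dir, "pssm", paste0(id, ".pssm")))
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#' @param dir Corpus directory.
#' @return List with `records` and `pssms`, as [generate_corpus()].
#' @export
read_corpus <- function(dir) {
  records <- read_labels(file.path(dir, "labels.txt"))
  pssms <- lapply(seq_len(nrow(records)), function(i) {
    read_pssm(file.path(dir, "pssm", paste0(records$id[i], ".pssm")),
              sequence = records$sequence[i])
  })
  names(pssms) <- records$id
  list(records = records, pssms = pssms)
}
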