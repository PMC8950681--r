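# The per-residue classifier: a first MLP lifts each 35-vector of
# features to 3675 values, which are reshaped to a 35 x 35 x 3 image and
# passed through a VGG19-style convolutional backbone (the sixteen 3x3
# conv layers and five 2x2 max-pools of VGG19, no fully connected
# stages). The flattened backbone output is linearly projected back to
# width 3675 and summed with the first MLP's output (skip connection);
# a second MLP (one 3675-unit ReLU hidden layer with dropout) and a
# single sigmoid unit produce the disorder probability. Forward and
# backward passes are explicit; 3x3 convolution and pooling use the
# compiled kernels in src/convnet.cpp, dense algebra uses BLAS.

.vgg19_channels <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L,
                     512L, 512L, 512L, 512L, 512L, 512L, 512L, 512L)
.vgg19_pool_after <- c(2L, 4L, 8L, 12L, 16L)

#' Classifier architecture configuration
#'
#' The architecture is fixed by the feature width: the first MLP has
#' hidden widths 35 and 3675 (= 35 x 35 x 3, the backbone's input image),
#' the projection and second MLP are 3675 wide. `scale` divides the
#' backbone's channel widths: `"full"` uses the published VGG19 widths
#' (64..512), `"small"` divides them by 8 for desk-scale training.
#'
#' @param scale `"small"` (default) or `"full"`.
#' @param dropout Dropout probability in the second MLP (default 0.5).
#' @param threshold Probability at or above which a residue is called
#'   disordered (default 0.5).
#' @param pretrained_backbone Initialise conv weights from published
#'   VGG19 weights. No weight file ships with the package, so `TRUE`
#'   requires `backbone_weights` in [build_model()]; the default `FALSE`
#'   uses seeded random (He) initialisation.
#' @return A `model_config` list.
#' @export
model_config <- function(scale = c("small", "full"), dropout = 0.5,
                         threshold = 0.5, pretrained_backbone = FALSE) {
  scale <- match.arg(scale)
  div <- if (scale == "full") 1L else 8L
  stopifnot(dropout >= 0, dropout < 1, threshold > 0, threshold < 1)
  structure(list(
    input_width = 35L,
    mlp1_hidden = c(35L, 3675L),
    image_shape = c(35L, 35L, 3L),
    conv_channels = .vgg19_channels %/% div,
    pool_after = .vgg19_pool_after,
    projection_width = 3675L,
    mlp2_hidden = 3675L,
    dropout = dropout,
    threshold = threshold,
    pretrained_backbone = pretrained_backbone,
    scale = scale
  ), class = "model_config")
}

#' Training configuration
#'
#' @param package_size Mini-batch ("package") size in residues
#'   (default 128).
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param max_epochs Maximum number of epochs (default 10).
#' @param convergence_tol Training stops early once the absolute change
#'   in mean epoch loss falls below this (default 1e-4).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(package_size = 128L, learning_rate = 1e-4,
                         max_epochs = 10L, convergence_tol = 1e-4,
                         seed = 1L) {
  stopifnot(package_size >= 1, learning_rate >= 0, max_epochs >= 1,
            convergence_tol >= 0)
  structure(list(package_size = as.integer(package_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

.he_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Build an untrained classifier
#'
#' All weights are drawn from seeded He-normal initialisation, so two
#' builds with the same config and seed are identical. Conv weights can
#' instead be supplied (e.g. published VGG19 conv weights) via
#' `backbone_weights`, a list with elements `w` and `b` per conv layer.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @param backbone_weights Optional list of conv-layer weights.
#' @return An `idpred_model` object.
#' @export
build_model <- function(config = model_config(), seed = 1L,
                        backbone_weights = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$pretrained_backbone && is.null(backbone_weights)) {
    abort(paste0("pretrained_backbone = TRUE but no backbone_weights given; ",
                 "no weight file ships with the package (offline). Pass the ",
                 "conv weights explicitly or use pretrained_backbone = FALSE."))
  }
  withr::with_seed(seed, {
    p <- list()
    p$norm_center <- rep(0, config$input_width)
    p$norm_scale <- rep(1, config$input_width)
    p$mlp1_w1 <- .he_mat(config$input_width, config$mlp1_hidden[1])
    p$mlp1_b1 <- rep(0, config$mlp1_hidden[1])
    p$mlp1_w2 <- .he_mat(config$mlp1_hidden[1], config$mlp1_hidden[2])
    p$mlp1_b2 <- rep(0, config$mlp1_hidden[2])
    chans <- c(config$image_shape[3], config$conv_channels)
    p$conv_w <- vector("list", length(config$conv_channels))
    p$conv_b <- vector("list", length(config$conv_channels))
    for (i in seq_along(config$conv_channels)) {
      cin <- chans[i]; cout <- chans[i + 1]
      p$conv_w[[i]] <- array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                             dim = c(3, 3, cin, cout))
      p$conv_b[[i]] <- rep(0, cout)
    }
    if (!is.null(backbone_weights)) {
      stopifnot(length(backbone_weights$w) == length(p$conv_w))
      p$conv_w <- backbone_weights$w
      p$conv_b <- backbone_weights$b
    }
    cend <- tail(config$conv_channels, 1)
    p$proj_w <- .he_mat(cend, config$projection_width)
    p$proj_b <- rep(0, config$projection_width)
    p$mlp2_w1 <- .he_mat(config$projection_width, config$mlp2_hidden)
    p$mlp2_b1 <- rep(0, config$mlp2_hidden)
    p$out_w <- matrix(rnorm(config$mlp2_hidden, sd = sqrt(1 / config$mlp2_hidden)),
                      ncol = 1)
    p$out_b <- 0
    structure(list(config = config, params = p, init_seed = as.integer(seed)),
              class = "idpred_model")
  })
}

# forward pass on a residue batch x (m x 35). Returns probabilities and,
# if keep_cache, every intermediate needed by .backward().
.forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  p <- model$params; cfg <- model$config
  m <- nrow(x)
  xn <- sweep(sweep(x, 2, p$norm_center, "-"), 2, p$norm_scale, "/")
  z1 <- xn %*% p$mlp1_w1
  z1 <- sweep(z1, 2, p$mlp1_b1, "+")
  h1 <- z1 * (z1 > 0)
  z2 <- h1 %*% p$mlp1_w2
  z2 <- sweep(z2, 2, p$mlp1_b2, "+")
  h2 <- z2 * (z2 > 0)                              # m x 3675, skip source
  a <- array(t(h2), dim = c(cfg$image_shape, m))
  conv_in <- if (keep_cache) vector("list", length(p$conv_w))
  relu_mask <- if (keep_cache) vector("list", length(p$conv_w))
  pool_idx <- list(); pool_dim <- list()
  for (i in seq_along(p$conv_w)) {
    if (keep_cache) conv_in[[i]] <- a
    z <- .conv3x3_fwd_cpp(a, dim(a), p$conv_w[[i]], p$conv_b[[i]])
    a <- z * (z > 0)
    dim(a) <- dim(z)
    if (keep_cache) relu_mask[[i]] <- (z > 0)
    if (i %in% cfg$pool_after) {
      pd <- dim(a)
      pr <- .maxpool2_fwd_cpp(a, pd)
      a <- pr$y
      if (keep_cache) {
        pool_idx[[as.character(i)]] <- pr$idx
        pool_dim[[as.character(i)]] <- pd
      }
    }
  }
  cend <- dim(a)[3]
  flat <- t(matrix(a, nrow = cend))                 # m x cend
  v <- sweep(flat %*% p$proj_w, 2, p$proj_b, "+")
  s <- v + h2                                       # skip connection
  z3 <- sweep(s %*% p$mlp2_w1, 2, p$mlp2_b1, "+")
  h3 <- z3 * (z3 > 0)
  if (training && cfg$dropout > 0) {
    mask <- matrix((runif(length(h3)) >= cfg$dropout) / (1 - cfg$dropout),
                   nrow = m)
    h3d <- h3 * mask
  } else {
    mask <- NULL
    h3d <- h3
  }
  z <- drop(h3d %*% p$out_w) + p$out_b
  prob <- 1 / (1 + exp(-z))
  if (!keep_cache) return(list(prob = prob, logit = z))
  list(prob = prob, logit = z, xn = xn, z1 = z1, h1 = h1, z2 = z2, h2 = h2,
       conv_in = conv_in, relu_mask = relu_mask, pool_idx = pool_idx,
       pool_dim = pool_dim, flat = flat, s = s, z3 = z3, h3d = h3d,
       mask = mask)
}

# gradients of the mean binary cross-entropy w.r.t. every parameter
.backward <- function(model, cache, y) {
  p <- model$params; cfg <- model$config
  m <- length(y)
  g <- list()
  dz <- matrix((cache$prob - y) / m, ncol = 1)
  g$out_w <- crossprod(cache$h3d, dz)
  g$out_b <- sum(dz)
  dh3d <- tcrossprod(dz, p$out_w)
  if (!is.null(cache$mask)) dh3d <- dh3d * cache$mask
  dz3 <- dh3d * (cache$z3 > 0)
  g$mlp2_w1 <- crossprod(cache$s, dz3)
  g$mlp2_b1 <- colSums(dz3)
  ds <- tcrossprod(dz3, p$mlp2_w1)
  g$proj_w <- crossprod(cache$flat, ds)
  g$proj_b <- colSums(ds)
  dflat <- tcrossprod(ds, p$proj_w)
  cend <- ncol(cache$flat)
  da <- array(t(dflat), dim = c(1, 1, cend, m))
  g$conv_w <- vector("list", length(p$conv_w))
  g$conv_b <- vector("list", length(p$conv_w))
  for (i in rev(seq_along(p$conv_w))) {
    if (i %in% cfg$pool_after) {
      key <- as.character(i)
      da <- .maxpool2_bwd_cpp(da, cache$pool_idx[[key]],
                              cache$pool_dim[[key]])
    }
    dzc <- da * cache$relu_mask[[i]]
    dim(dzc) <- dim(cache$relu_mask[[i]])
    bw <- .conv3x3_bwd_cpp(cache$conv_in[[i]], dim(cache$conv_in[[i]]),
                           p$conv_w[[i]], dzc, length(p$conv_b[[i]]))
    g$conv_w[[i]] <- bw$dw
    g$conv_b[[i]] <- bw$db
    da <- bw$dx
  }
  dh2 <- ds + t(matrix(da, nrow = prod(cfg$image_shape)))   # skip + conv
  dz2 <- dh2 * (cache$z2 > 0)
  g$mlp1_w2 <- crossprod(cache$h1, dz2)
  g$mlp1_b2 <- colSums(dz2)
  dh1 <- tcrossprod(dz2, p$mlp1_w2)
  dz1 <- dh1 * (cache$z1 > 0)
  g$mlp1_w1 <- crossprod(cache$xn, dz1)
  g$mlp1_b1 <- colSums(dz1)
  g
}

.sgd_step <- function(params, grads, lr) {
  for (nm in setdiff(names(grads), c("conv_w", "conv_b"))) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  for (i in seq_along(grads$conv_w)) {
    params$conv_w[[i]] <- params$conv_w[[i]] - lr * grads$conv_w[[i]]
    params$conv_b[[i]] <- params$conv_b[[i]] - lr * grads$conv_b[[i]]
  }
  params
}

#' Mean binary cross-entropy of a package of residues
#'
#' `L = mean(-(y * log(a) + (1 - y) * log(1 - a)))` with natural
#' logarithms; probabilities are clipped to `[1e-7, 1 - 1e-7]` for
#' numerical safety.
#'
#' @param probabilities Predicted probabilities in `(0, 1)`.
#' @param labels 0/1 labels, same length.
#' @return A single non-negative number.
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    abort("probabilities and labels differ in length")
  }
  a <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  mean(-(labels * log(a) + (1 - labels) * log(1 - a)))
}

#' Train the classifier with mini-batch SGD
#'
#' Residues (rows of `x`) are shuffled and split into packages of
#' `package_size`; each package takes one SGD step on the mean binary
#' cross-entropy. Epochs repeat until the change in mean epoch loss
#' drops below `convergence_tol` or `max_epochs` is reached. Feature
#' standardisation statistics (per-channel mean/sd of `x`) are computed
#' here, stored in the model, and applied inside every forward pass.
#'
#' @param model An `idpred_model` from [build_model()].
#' @param x Numeric matrix, one row per residue, 35 columns.
#' @param y Integer 0/1 labels (1 = disordered), one per row of `x`.
#' @param tc A [train_config()].
#' @return An `idpred_fit`: the trained model plus a `history` tibble
#'   (`epoch`, `loss`) and a `converged` flag. Supports [tidy()],
#'   [glance()], `predict()` and [autoplot()].
#' @export
train_network <- function(model, x, y, tc = train_config()) {
  stopifnot(inherits(model, "idpred_model"), inherits(tc, "train_config"))
  if (nrow(x) == 0) abort("no training residues")
  if (nrow(x) != length(y)) abort("x and y differ in length")
  if (length(unique(y)) < 2) {
    warn("training labels contain a single class; MCC downstream is undefined")
  }
  ctr <- colMeans(x)
  sc <- apply(x, 2, sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  model$params$norm_center <- ctr
  model$params$norm_scale <- sc
  n <- nrow(x)
  history <- numeric(0)
  converged <- FALSE
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      perm <- sample(n)
      starts <- seq(1L, n, by = tc$package_size)
      losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        rows <- perm[starts[b]:min(starts[b] + tc$package_size - 1L, n)]
        xb <- x[rows, , drop = FALSE]
        yb <- y[rows]
        cache <- .forward(model, xb, training = TRUE, keep_cache = TRUE)
        losses[b] <- bce_loss(cache$prob, yb)
        if (tc$learning_rate > 0) {
          grads <- .backward(model, cache, yb)
          model$params <- .sgd_step(model$params, grads, tc$learning_rate)
        }
      }
      history[epoch] <- mean(losses)
      if (epoch > 1 &&
          abs(history[epoch] - history[epoch - 1]) < tc$convergence_tol) {
        converged <- TRUE
        break
      }
    }
  })
  structure(list(model = model,
                 history = tibble::tibble(epoch = seq_along(history),
                                          loss = history),
                 converged = converged,
                 train_config = tc),
            class = "idpred_fit")
}

# eval-mode probabilities for a residue matrix, chunked to bound memory
.predict_matrix <- function(model, x, chunk = 512L) {
  n <- nrow(x)
  out <- numeric(n); logit <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    fw <- .forward(model, x[rows, , drop = FALSE], training = FALSE)
    out[rows] <- fw$prob
    logit[rows] <- fw$logit
  }
  list(prob = out, logit = logit)
}

#' Predict per-residue disorder for one protein
#'
#' Runs the classifier (dropout off, deterministic) over every column of
#' a feature matrix. A residue is called disordered when its probability
#' is greater than or equal to the threshold.
#'
#' @param model An `idpred_model` or `idpred_fit`.
#' @param feature_matrix `35 x L` matrix from
#'   [assemble_feature_matrix()].
#' @param threshold Call threshold; defaults to the model config's.
#' @return Tibble with columns `pos`, `probability`, `logit`, `call`.
#' @export
predict_protein <- function(model, feature_matrix, threshold = NULL) {
  if (inherits(model, "idpred_fit")) model <- model$model
  stopifnot(inherits(model, "idpred_model"))
  if (nrow(feature_matrix) != model$config$input_width) {
    abort(paste0("feature matrix must have ", model$config$input_width,
                 " rows, got ", nrow(feature_matrix)))
  }
  threshold <- threshold %||% model$config$threshold
  pr <- .predict_matrix(model, t(feature_matrix))
  tibble::tibble(pos = seq_len(ncol(feature_matrix)),
                 probability = pr$prob,
                 logit = pr$logit,
                 call = as.integer(pr$prob >= threshold))
}

#' @export
predict.idpred_fit <- function(object, feature_matrix, threshold = NULL, ...) {
  predict_protein(object, feature_matrix, threshold)
}

#' @export
print.idpred_model <- function(x, ...) {
  cat("idpred classifier (", x$config$scale, " scale)\n", sep = "")
  cat("  backbone channels:", paste(x$config$conv_channels, collapse = " "),
      "\n")
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model An `idpred_model` or `idpred_fit`.
#' @return Integer count (excludes the fixed standardisation statistics).
#' @export
n_parameters <- function(model) {
  if (inherits(model, "idpred_fit")) model <- model$model
  p <- model$params
  sum(vapply(p[setdiff(names(p), c("norm_center", "norm_scale"))],
             function(q) if (is.list(q)) sum(lengths(q)) else length(q),
             numeric(1)))
}

#' @export
tidy.idpred_fit <- function(x, ...) {
  x$history
}

#' @export
glance.idpred_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    initial_loss = x$history$loss[1],
    final_loss = tail(x$history$loss, 1),
    converged = x$converged,
    n_parameters = n_parameters(x),
    learning_rate = x$train_config$learning_rate,
    package_size = x$train_config$package_size
  )
}

#' @export
print.idpred_fit <- function(x, ...) {
  g <- glance(x)
  cat("idpred fit:", g$epochs, "epochs, loss",
      sprintf("%.4f -> %.4f", g$initial_loss, g$final_loss),
      if (g$converged) "(converged)" else "(max epochs)", "\n")
  invisible(x)
}
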