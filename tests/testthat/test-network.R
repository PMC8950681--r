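# A shared tiny linearly separable feature set: class decides the mean of
# a handful of channels. Built once per file.
make_toy_data <- function(n = 384, seed = 17) {
  withr::with_seed(seed, {
    y <- sample(0:1, n, replace = TRUE)
    x <- matrix(rnorm(n * 35), n, 35)
    x[, 1:5] <- x[, 1:5] + 2 * y
    list(x = x, y = y)
  })
}

test_that("architecture widths satisfy the reshape constraint", {
  cfg <- model_config("small")
  expect_equal(cfg$mlp1_hidden[2], 3675L)
  expect_equal(prod(cfg$image_shape), 3675L)
  expect_equal(cfg$projection_width, 3675L)
  m <- build_model(cfg, seed = 1)
  expect_equal(dim(m$params$mlp1_w2), c(35L, 3675L))
  expect_equal(dim(m$params$mlp2_w1), c(3675L, 3675L))
  # full-scale config keeps published channel widths
  expect_equal(model_config("full")$conv_channels[c(1, 16)], c(64L, 512L))
  expect_equal(model_config("small")$conv_channels[c(1, 16)], c(8L, 64L))
})

test_that("forward pass produces probabilities in (0,1) for any batch size", {
  m <- build_model(model_config("small"), seed = 2)
  for (n in c(1L, 3L, 7L)) {
    fw <- idpred:::.forward(m, matrix(rnorm(n * 35), n, 35))
    expect_length(fw$prob, n)
    expect_true(all(fw$prob > 0 & fw$prob < 1))
  }
})

test_that("two builds with the same seed give identical predictions", {
  x <- matrix(rnorm(4 * 35), 4, 35)
  m1 <- build_model(model_config("small"), seed = 11)
  m2 <- build_model(model_config("small"), seed = 11)
  expect_identical(idpred:::.forward(m1, x)$prob,
                   idpred:::.forward(m2, x)$prob)
  m3 <- build_model(model_config("small"), seed = 12)
  expect_false(identical(idpred:::.forward(m1, x)$prob,
                         idpred:::.forward(m3, x)$prob))
})

test_that("pretrained backbone without weights errors with an offline hint", {
  expect_error(build_model(model_config("small", pretrained_backbone = TRUE)),
               "offline")
})

test_that("binary cross-entropy matches hand-worked values", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), 0.693147, tolerance = 1e-6)
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)     # perfect prediction -> ~0
  expect_error(bce_loss(c(0.5), c(1, 0)), "length")
})

test_that("training reduces loss on separable data and is seed-reproducible", {
  toy <- make_toy_data()
  cfg <- model_config("small", dropout = 0.5)
  tc <- train_config(max_epochs = 2, learning_rate = 1e-3, seed = 21)
  fit1 <- train_network(build_model(cfg, seed = 21), toy$x, toy$y, tc)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  fit2 <- train_network(build_model(cfg, seed = 21), toy$x, toy$y, tc)
  expect_identical(fit1$history, fit2$history)
})

test_that("zero learning rate leaves the loss history flat", {
  toy <- make_toy_data(n = 256)
  tc <- train_config(max_epochs = 2, learning_rate = 0, seed = 3,
                     convergence_tol = 0)
  fit <- train_network(build_model(model_config("small", dropout = 0),
                                   seed = 3),
                       toy$x, toy$y, tc)
  expect_equal(diff(range(fit$history$loss)), 0, tolerance = 1e-12)
})

test_that("prediction is deterministic in eval mode and respects thresholds", {
  toy <- make_toy_data(n = 200)
  m <- build_model(model_config("small"), seed = 4)
  F <- t(toy$x[1:30, ])
  p1 <- predict_protein(m, F)
  p2 <- predict_protein(m, F)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 30)
  expect_equal(p1$call, as.integer(p1$probability >= 0.5))
  # thresholding is >= : probabilities at the threshold are called positive
  p3 <- predict_protein(m, F, threshold = min(p1$probability))
  expect_true(all(p3$call == 1L))
  expect_error(predict_protein(m, F[1:10, ]), "35 rows")
})

test_that("single-column feature matrix predicts a single residue", {
  m <- build_model(model_config("small"), seed = 5)
  p <- predict_protein(m, matrix(rnorm(35), 35, 1))
  expect_equal(nrow(p), 1)
  expect_true(p$probability > 0 && p$probability < 1)
})

test_that("fit accessors expose history and parameter counts", {
  toy <- make_toy_data(n = 200)
  tc <- train_config(max_epochs = 2, learning_rate = 1e-3, seed = 6)
  fit <- train_network(build_model(model_config("small"), seed = 6),
                       toy$x, toy$y, tc)
  td <- tidy(fit)
  expect_equal(names(td), c("epoch", "loss"))
  expect_equal(nrow(td), 2)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_equal(g$package_size, 128L)
  expect_gt(g$n_parameters, 1e7)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("single-class training warns about undefined MCC", {
  toy <- make_toy_data(n = 150)
  expect_warning(
    train_network(build_model(model_config("small"), seed = 7),
                  toy$x, rep(1L, 150),
                  train_config(max_epochs = 1, seed = 7)),
    "single class")
})
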