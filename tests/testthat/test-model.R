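# a fast 6-hidden-layer configuration for unit tests (widths are a package
# design knob; the training recipe itself -- Adam, lr 1e-4, clipping -- is kept)
tiny_config <- function(epochs = 150, seed = 5, batch_size = 64) {
  model_config(hidden_sizes = c(64, 32, 16, 16, 8, 4), epochs = epochs,
               seed = seed, batch_size = batch_size)
}

# a linearly separable toy FeatureMatrix: two informative CF-width columns
toy_separable <- function(n = 200, seed = 3, flip = 0) {
  with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * 192, sd = 0.05), n, 192)
    x[, 1] <- x[, 1] + ifelse(y == 1, 1, -1)
    x[, 2] <- x[, 2] + ifelse(y == 1, 0.5, -0.5)
    if (flip > 0) y <- sample(y)   # negative control: labels shuffled
    list(fm = structure(list(x = x, pairs = data.frame(i = seq_len(n),
                                                       j = seq_len(n) + 300L),
                             kind = "CF", sequence_id = "toy", n_skipped = 0L,
                             scaled = FALSE), class = "FeatureMatrix"),
         y = y)
  })
}

test_that("static projection is a frozen bias-free linear map", {
  expect_equal(static_projection(rep(0, 40)), rep(0, 192))
  with_seed(4, {
    a <- rnorm(40); b <- rnorm(40)
    expect_equal(static_projection(a + b),
                 static_projection(a) + static_projection(b), tolerance = 1e-9)
  })
  v <- seq_len(40) / 40
  expect_identical(static_projection(v, 7L), static_projection(v, 7L))
  expect_false(isTRUE(all.equal(static_projection(v, 7L),
                                static_projection(v, 8L))))
  expect_error(static_projection(rep(0, 39)), "length 40")
  # matrix input projects 40 -> 192 columns
  expect_equal(dim(static_projection(matrix(0, 3, 40))), c(3, 192))
})

test_that("training learns a separable toy problem and logs finite losses", {
  toy <- toy_separable()
  m <- train_model(toy$fm, toy$y, tiny_config())
  expect_true(all(is.finite(m$training_log)))
  expect_lt(m$training_log[length(m$training_log)], 0.1)
  s <- predict_scores(m, toy$fm)
  expect_true(all(s > 0 & s < 1))
  expect_gt(average_precision(s, toy$y), 0.99)
  expect_gt(roc_auc(s, toy$y), 0.99)
})

test_that("shuffled labels leave no signal for the true labels (negative control)", {
  # an interpolating MLP can memorize shuffled training labels, so the sound
  # control is that such a model carries ~no signal for the TRUE labels
  truth <- toy_separable(flip = 0)
  shuffled <- toy_separable(flip = 1)
  m <- train_model(shuffled$fm, shuffled$y, tiny_config(epochs = 60))
  auc <- roc_auc(predict_scores(m, truth$fm), truth$y)
  expect_gt(auc, 0.3); expect_lt(auc, 0.7)
})

test_that("degenerate label sets and kind mismatches are rejected", {
  toy <- toy_separable()
  expect_error(train_model(toy$fm, rep(1, 200), tiny_config()),
               "degenerate training set")
  m <- train_model(toy$fm, toy$y, tiny_config(epochs = 2))
  sdf_fm <- structure(list(x = matrix(0, 2, 40), pairs = NULL, kind = "SDF",
                           sequence_id = "x", n_skipped = 0L, scaled = FALSE),
                      class = "FeatureMatrix")
  expect_error(predict_scores(m, sdf_fm), "does not match")
})

test_that("training is deterministic and rows score independently", {
  toy <- toy_separable()
  m1 <- train_model(toy$fm, toy$y, tiny_config(epochs = 10))
  m2 <- train_model(toy$fm, toy$y, tiny_config(epochs = 10))
  expect_identical(m1$weights, m2$weights)
  # duplicated input row gets an identical duplicated score
  fm2 <- toy$fm
  fm2$x <- rbind(fm2$x, fm2$x[1, , drop = FALSE])
  fm2$pairs <- rbind(fm2$pairs, fm2$pairs[1, ])
  s <- predict_scores(m1, fm2)
  expect_identical(s[1], s[201])
})

test_that("checkpoints reload to bitwise-identical predictions", {
  toy <- toy_separable()
  m <- train_model(toy$fm, toy$y, tiny_config(epochs = 5))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_scores(m2, toy$fm), predict_scores(m, toy$fm))
  expect_equal(m2$config$hidden_sizes, m$config$hidden_sizes)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(load_model(bad), "checkpoint")
})

test_that("SDF inputs pass through the projection; CF inputs bypass it", {
  b <- two_helix_chain()
  cp <- candidate_pairs(b$chain, b$annotation)
  fm <- build_feature_matrix(b$chain, b$annotation, cp, "SDF", "s")
  cm <- label_contacts(b$chain, cp)
  y <- cm$labels[fm$kept]
  m <- train_model(fm, y, tiny_config(epochs = 3))
  expect_identical(m$input_kind, "SDF")
  s <- predict_scores(m, fm)
  expect_length(s, nrow(fm$x))
  expect_true(all(s > 0 & s < 1))
  # first trainable layer consumes 192 dims in both cases
  expect_equal(nrow(m$weights$W[[1]]), 192)
})
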