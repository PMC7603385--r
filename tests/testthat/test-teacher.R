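test_that("default teacher is a 17-layer funnel through the code layer", {
  spec <- default_teacher_spec(4005)
  expect_length(spec$layer_sizes, 17)
  expect_identical(spec$layer_sizes[1], 4005L)
  expect_identical(spec$layer_sizes[17], 2L)
  expect_identical(sum(spec$layer_sizes[2:16] == 5L), 1L)
  expect_true(all(diff(spec$layer_sizes[1:spec$code_index]) <= 0))
  expect_true(all(diff(spec$dropout_schedule) <= 0)) # dropout fades to 0
  # small inputs still yield a legal funnel
  spec10 <- default_teacher_spec(10)
  expect_length(spec10$layer_sizes, 17)
  expect_identical(spec10$layer_sizes[1], 10L)
  expect_s3_class(spec10, "teacher_spec")
})

test_that("teacher_spec validates its invariants", {
  expect_error(teacher_spec(c(10, 5, 3)), "2 units")
  expect_error(teacher_spec(c(10, 4, 6, 5, 2)), "non-increasing")
  expect_error(teacher_spec(c(10, 5, 5, 2)), "exactly once")
  expect_error(teacher_spec(c(20, 10, 5, 2), dropout_schedule = c(0.5, 1)),
               "dropout")
})

test_that("teacher separates two Gaussian blobs at least as well as logistic regression", {
  blobs <- toy_blobs(n_per_class = 30, sep = 4, seed = 42)
  # independent oracle: plain logistic regression on the same data
  oracle <- suppressWarnings( # separable fit: glm warns, still converges
    glm(y ~ ., data = data.frame(y = blobs$y, blobs$X), family = binomial())
  )
  oracle_acc <- mean((fitted(oracle) > 0.5) == blobs$y)
  expect_gte(oracle_acc, 0.95)
  spec <- teacher_spec(c(2, 2, 2), code_layer_size = 2, epochs = 300,
                       learning_rate = 1, seed = 1)
  tm <- train_teacher(blobs$X, blobs$y, spec)
  acc <- mean(predict(tm, blobs$X) == blobs$y)
  expect_gte(acc, 0.95)
  expect_length(tm$loss_history, 300)
  expect_true(all(is.finite(tm$loss_history)))
})

test_that("training is symmetric under a global label flip", {
  blobs <- toy_blobs(n_per_class = 20, sep = 3, seed = 5)
  spec <- teacher_spec(c(2, 2, 2), code_layer_size = 2, epochs = 200,
                       learning_rate = 1, seed = 3)
  acc <- mean(predict(train_teacher(blobs$X, blobs$y, spec), blobs$X) == blobs$y)
  acc_flip <- mean(predict(train_teacher(blobs$X, 1 - blobs$y, spec), blobs$X) ==
                     (1 - blobs$y))
  expect_equal(acc, acc_flip, tolerance = 0.1)
})

test_that("degenerate training inputs error", {
  blobs <- toy_blobs(10)
  spec <- teacher_spec(c(2, 2, 2), code_layer_size = 2, epochs = 1)
  expect_error(train_teacher(blobs$X, rep(1L, nrow(blobs$X)), spec),
               "both classes")
  Xbad <- blobs$X
  Xbad[1, 1] <- NA
  expect_error(train_teacher(Xbad, blobs$y, spec), "non-finite")
  expect_error(train_teacher(blobs$X[, 1, drop = FALSE], blobs$y, spec),
               "input size")
})

test_that("softmax class scores sum to one for every subject", {
  blobs <- toy_blobs(15, seed = 8)
  spec <- teacher_spec(c(2, 2, 2), code_layer_size = 2, epochs = 20,
                       learning_rate = 0.1, seed = 2)
  tm <- train_teacher(blobs$X, blobs$y, spec)
  P <- predict(tm, blobs$X, type = "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
})

test_that("seeded training is reproducible", {
  blobs <- toy_blobs(15, seed = 9, dim = 4)
  spec <- teacher_spec(c(4, 3, 2, 2), code_layer_size = 3, epochs = 30,
                       dropout_schedule = c(0.2, 0), learning_rate = 0.1, seed = 7)
  a <- train_teacher(blobs$X, blobs$y, spec)
  b <- train_teacher(blobs$X, blobs$y, spec)
  expect_identical(a$net$W, b$net$W)
  expect_identical(a$loss_history, b$loss_history)
})

test_that("extract_codes returns code-layer activations matching a manual forward pass", {
  blobs <- toy_blobs(20, seed = 3, dim = 4)
  spec <- teacher_spec(c(4, 4, 3, 2, 2), code_layer_size = 3, epochs = 10,
                       learning_rate = 0.1, seed = 1)
  tm <- train_teacher(blobs$X, blobs$y, spec)
  codes <- extract_codes(tm, blobs$X)
  expect_equal(dim(codes), c(40, 3))
  # identical input rows give identical codes
  X2 <- blobs$X[c(1, 1), ]
  c2 <- extract_codes(tm, X2)
  expect_equal(c2[1, ], c2[2, ])
  # brute-force forward pass with the stored weights (tanh layers)
  A <- blobs$X
  for (l in 1:2) A <- tanh(sweep(A %*% tm$net$W[[l]], 2, tm$net$b[[l]], "+"))
  expect_equal(unclass(codes), A, tolerance = 1e-12, ignore_attr = TRUE)
  # pre-activation variant is the same up to the final tanh
  pre <- extract_codes(tm, blobs$X, pre_activation = TRUE)
  expect_equal(tanh(unclass(pre)), unclass(codes), ignore_attr = TRUE)
})

test_that("standardize_codes z-scores with the population sd and is idempotent", {
  codes <- structure(cbind(c(1, 2, 3), c(10, 20, 60)),
                     class = c("code_matrix", "matrix"), standardized = FALSE)
  z <- standardize_codes(codes)
  # population sd of (1,2,3) is sqrt(2/3)
  expect_equal(z[, 1], (c(1, 2, 3) - 2) / sqrt(2 / 3), ignore_attr = TRUE)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(sweep(unclass(z), 2, colMeans(z))^2)), c(1, 1),
               tolerance = 1e-12)
  z2 <- standardize_codes(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-9, ignore_attr = TRUE)
  # fitted parameters reapply to new rows
  z3 <- standardize_codes(codes, center = attr(z, "center"), scale = attr(z, "scale"))
  expect_equal(unclass(z3), unclass(z), ignore_attr = TRUE)
  expect_error(standardize_codes(codes[1, , drop = FALSE]), "m = 1")
  const <- structure(cbind(c(1, 1, 1), c(1, 2, 3)),
                     class = c("code_matrix", "matrix"))
  expect_error(standardize_codes(const), "zero-sd")
})
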