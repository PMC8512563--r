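test_that("the model table reproduces the published layer stack", {
  bm <- build_model(cnn_config())
  expect_equal(bm$layers$parameters,
               c(0, 896, 0, 9248, 0, 9248, 0, 921728, 903))
  expect_equal(bm$layers$output_shape[c(2, 3, 4, 5, 6, 7)],
               c("132x132x32", "66x66x32", "64x64x32", "32x32x32",
                 "30x30x32", "15x15x32"))
  expect_equal(bm$flat_size, 7200)
  expect_error(build_model(cnn_config(input_shape = c(64, 64, 3))),
               "134x134x3")
})

test_that("stratified splits partition each repetition with balanced classes", {
  labels <- rep(paste0("U", 1:7), each = 100)
  splits <- make_cv_splits(labels, k = 5, repetitions = 10, seed = 1)
  expect_length(splits, 50)
  for (r in c(1, 7)) {
    idx <- which(vapply(splits, function(s) s$repetition == r, TRUE))
    test_sets <- lapply(splits[idx], `[[`, "test")
    expect_equal(sort(unlist(test_sets)), seq_along(labels))
    for (ts in test_sets) {
      expect_length(ts, 140)
      expect_true(all(table(labels[ts]) == 20))
    }
  }
  # train and test are disjoint and cover everything
  s <- splits[[13]]
  expect_length(intersect(s$train, s$test), 0)
  expect_equal(sort(c(s$train, s$test)), seq_along(labels))
  expect_identical(splits, make_cv_splits(labels, 5, 10, seed = 1))
  expect_error(make_cv_splits(c(rep("A", 10), rep("B", 3)), k = 5),
               "B")
})

test_that("uneven classes keep fold counts within one sample", {
  labels <- c(rep("A", 23), rep("B", 11))
  splits <- make_cv_splits(labels, k = 5, repetitions = 1, seed = 2)
  for (s in splits) {
    tab <- table(factor(labels[s$test], levels = c("A", "B")))
    expect_true(tab[["A"]] %in% 4:5)
    expect_true(tab[["B"]] %in% 2:3)
  }
})

test_that("trivially separable constant images are classified perfectly", {
  fx <- fix_constant_images()
  cfg <- cnn_config(n_classes = 2, epochs = 10)
  sp <- make_cv_splits(fx$labels, k = 5, repetitions = 1, seed = 1)
  cms <- train_and_eval(fx$images, fx$labels, sp[1], cfg, seed = 1)
  cm <- cms[[1]]
  expect_equal(sum(diag(cm)) / sum(cm), 1)
  # confusion matrix bookkeeping
  expect_equal(sum(cm), length(sp[[1]]$test))
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(fx$labels[sp[[1]]$test]))))
})

test_that("training is exactly reproducible for fixed seeds", {
  fx <- fix_constant_images(10)
  cfg <- cnn_config(n_classes = 2, epochs = 2)
  sp <- make_cv_splits(fx$labels, k = 2, repetitions = 1, seed = 3)
  a <- train_and_eval(fx$images, fx$labels, sp, cfg, seed = 5)
  b <- train_and_eval(fx$images, fx$labels, sp, cfg, seed = 5)
  expect_identical(a, b)
})

test_that("shuffled labels yield chance-level accuracy", {
  set.seed(31)
  n_per <- 20
  imgs <- lapply(seq_len(7 * n_per), function(i)
    array(runif(134 * 134 * 3), c(134, 134, 3)))
  labels <- sample(rep(paste0("U", 1:7), each = n_per))
  cfg <- cnn_config(n_classes = 7, epochs = 2)
  sp <- make_cv_splits(labels, k = 5, repetitions = 1, seed = 4)
  cms <- train_and_eval(imgs, labels, sp[1:2], cfg, seed = 6)
  acc <- cv_mean_accuracy(cms)
  expect_gte(acc, 0.07)  # 1/7 = 0.143 plus sampling noise
  expect_lte(acc, 0.25)
})

test_that("inputs outside [0,1] and degenerate label sets are rejected", {
  img <- list(array(2, c(134, 134, 3)))
  expect_error(train_and_eval(img, "A", list(), cnn_config()), "\\[0, 1\\]")
  imgs <- lapply(1:4, function(i) array(0.5, c(134, 134, 3)))
  expect_error(train_and_eval(imgs, rep("A", 4), list(), cnn_config()),
               "2 classes")
})
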