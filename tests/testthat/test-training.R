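test_that("per-group test sizes follow the piecewise split rule", {
  gts <- bios2net:::group_test_size
  expect_equal(gts(150), 20L)        # fixed 20 above 100 members
  expect_equal(gts(101), 20L)
  expect_equal(gts(10), 3L)          # at least 30% below 30
  expect_equal(gts(29), 9L)
  expect_equal(gts(30), 9L)          # interpolation anchors
  expect_equal(gts(100), 20L)
  expect_equal(gts(65), 15L)         # round(9 + 35 * 11/70) = round(14.5), half-up
})

test_that("split_dataset partitions every group with the rule's sizes", {
  labels <- rep(c("a", "b", "c"), times = c(150, 10, 65))
  manifest <- data.frame(label = labels)
  sp <- split_dataset(manifest, seed = 3)
  expect_equal(unname(sp$test_sizes[c("a", "b", "c")]), c(20L, 3L, 15L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # per-group counts in the realized split
  for (g in c("a", "b", "c")) {
    expect_equal(sum(labels[sp$test] == g), unname(sp$test_sizes[g]))
  }
  # seeded: reproducible
  expect_identical(split_dataset(manifest, seed = 3), sp)
  expect_false(identical(split_dataset(manifest, seed = 4)$test, sp$test))
})

test_that("singleton groups stay in train with a warning", {
  manifest <- data.frame(label = c(rep("a", 5), "b"))
  expect_warning(sp <- split_dataset(manifest, seed = 1), "single member")
  expect_true(6 %in% sp$train)
})

test_that("accuracy metrics follow their definitions", {
  # class A 2/2, class B 0/2
  ev <- evaluate_predictions(c("A", "A", "B", "B"), c("A", "A", "A", "A"))
  expect_equal(ev$simple_accuracy, 0.5)
  expect_equal(ev$mean_class_accuracy, 0.5)
  # imbalance: class A 3/3, class B 0/1
  ev2 <- evaluate_predictions(c("A", "A", "A", "B"), c("A", "A", "A", "A"))
  expect_equal(ev2$simple_accuracy, 0.75)
  expect_equal(ev2$mean_class_accuracy, 0.5)
  # all correct
  ev3 <- evaluate_predictions(c("A", "B"), c("A", "B"))
  expect_equal(ev3$simple_accuracy, 1)
  expect_equal(ev3$mean_class_accuracy, 1)
  expect_error(evaluate_predictions(character(0), character(0)), "no predictions")
})

test_that("mean class accuracy is invariant to relabeling and duplication", {
  truth <- c("A", "A", "B", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "C", "C")
  base <- evaluate_predictions(truth, pred)$mean_class_accuracy
  # relabel classes
  map <- c(A = "z", B = "y", C = "x")
  expect_equal(evaluate_predictions(map[truth], map[pred])$mean_class_accuracy,
               base)
  # duplicate every member of one class
  dup <- c(truth, truth[truth == "B"])
  dupp <- c(pred, pred[truth == "B"])
  expect_equal(evaluate_predictions(dup, dupp)$mean_class_accuracy, base)
})

test_that("history summaries use mean and population standard deviation", {
  h <- data.frame(epoch = 1:20, test_simple_accuracy = rep(0.8, 20),
                  test_mean_class_accuracy = rep(0.8, 20))
  s <- summarize_history(h, 20)
  expect_equal(s$simple_accuracy_mean, 0.8)
  expect_equal(s$simple_accuracy_sd, 0)
  h2 <- h
  h2$test_mean_class_accuracy <- rep(c(0.7, 0.9), 10)
  s2 <- summarize_history(h2, 20)
  expect_equal(s2$mean_class_accuracy_mean, 0.8)
  expect_equal(s2$mean_class_accuracy_sd, 0.1)
  s3 <- summarize_history(h2, 1)
  expect_equal(s3$mean_class_accuracy_mean, 0.9)
  expect_equal(s3$mean_class_accuracy_sd, 0)
  expect_error(summarize_history(h[1:5, ], 20), "last_k")
})

test_that("training is reproducible and zero learning rate freezes the model", {
  manifest <- fixture_tiny_manifest()
  clouds <- fixture_tiny_clouds()
  fit1 <- bios2net_fit(manifest, epochs = 2, batch_size = 4, seed = 5,
                       clouds = clouds)
  fit2 <- bios2net_fit(manifest, epochs = 2, batch_size = 4, seed = 5,
                       clouds = clouds)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  # all tiny clouds have < 128 atoms, so sampling pads deterministically and
  # with augmentation off and lr 0 every epoch must see identical losses
  expect_true(all(vapply(clouds, function(cl) nrow(cl$points), 0) < 128))
  fit0 <- bios2net_fit(manifest, epochs = 3, batch_size = 4, seed = 5,
                       lr = 0, augmentation = NULL, clouds = clouds)
  expect_lt(diff(range(fit0$history$train_loss)), 1e-6)
})

test_that("fitted objects predict and expose coherent methods", {
  manifest <- fixture_tiny_manifest()
  clouds <- fixture_tiny_clouds()
  fit <- bios2net_fit(manifest, epochs = 4, batch_size = 4, seed = 9,
                      clouds = clouds)
  expect_s3_class(fit, "bios2net")
  expect_equal(nrow(fit$history), 4)
  probs <- predict(fit, clouds[1:3], type = "prob")
  expect_equal(dim(probs), c(3, 2))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  cls <- predict(fit, clouds[1:3])
  expect_true(all(cls %in% fit$classes))
  expect_output(print(fit), "bios2net")
  expect_output(summary(fit, last_k = 2), "mean-class")
})

test_that("global feature extraction is deterministic with the expected shape", {
  manifest <- fixture_tiny_manifest()
  clouds <- fixture_tiny_clouds()
  fit <- bios2net_fit(manifest, epochs = 2, batch_size = 4, seed = 12,
                      clouds = clouds)
  v1 <- extract_global_features(fit, clouds = clouds[1:4])
  v2 <- extract_global_features(fit, clouds = clouds[1:4])
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 4)
  expect_equal(ncol(v1), 128 + 32)    # compact structural + temporal widths
  f <- tempfile(fileext = ".tsv")
  extract_global_features(fit, clouds = clouds[1:2], file = f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(ncol(tab), 2 + 160)
})
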