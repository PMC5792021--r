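test_that("zero-iteration training returns the initialization unchanged", {
  sp <- tiny_split(seed = 1)
  arch <- tiny_arch()
  m1 <- train_general(sp, arch, fast_hp(iterations = 0, seed = 3))
  m2 <- train_general(sp, arch, fast_hp(iterations = 0, seed = 3))
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$best_iteration, 0L)
  expect_equal(m1$history$iteration, 0L)
  # different seed, different initialization
  m3 <- train_general(sp, arch, fast_hp(iterations = 0, seed = 4))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("training is deterministic given the seed", {
  sp <- tiny_split(seed = 2)
  arch <- tiny_arch()
  m1 <- train_general(sp, arch, fast_hp(iterations = 20, seed = 5))
  m2 <- train_general(sp, arch, fast_hp(iterations = 20, seed = 5))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("the optimizer memorizes a small training set", {
  sp <- tiny_split(n_genera = 2, per_genus = 4, seed = 8, noise_sd = 0)
  arch <- tiny_arch()
  m <- train_general(sp, arch, fast_hp(iterations = 150, seed = 2))
  train_samples <- flatten_to_samples(sp$train)
  sc <- score_images(m, train_samples)
  top1 <- max.col(sc, ties.method = "first")
  expect_equal(mean(top1 == train_samples$genus), 1.0)
  # loss fell to near zero
  hist <- tidy(m)
  expect_lt(utils::tail(hist$train_loss, 1), 0.2)
})

test_that("checkpoint selection maximizes recorded validation accuracy", {
  sp <- tiny_split(seed = 3)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 40, seed = 7))
  h <- tidy(m)
  expect_equal(m$best_accuracy, max(h$val_accuracy))
  expect_equal(m$best_iteration,
               h$iteration[which(h$val_accuracy == max(h$val_accuracy))[1]])
})

test_that("view-specific training restricts to the view and validates input", {
  sp <- tiny_split(seed = 4)
  m <- train_specific(sp, "head", tiny_arch(), fast_hp(iterations = 10))
  expect_equal(m$regime, "specific")
  expect_equal(m$view, "head")

  # remove every head image: specific training must fail
  nohead <- sp
  for (i in seq_along(nohead$train$specimens)) {
    nohead$train$specimens[[i]]$images$head <- list()
  }
  expect_error(train_specific(nohead, "head", tiny_arch(), fast_hp()),
               "no training images")
  expect_error(train_specific(sp, "side", tiny_arch(), fast_hp()),
               "unknown view")
})

test_that("architecture and dataset label counts must agree", {
  sp <- tiny_split(n_genera = 2, seed = 5)
  expect_error(train_general(sp, tiny_arch(n_labels = 4), fast_hp()),
               "does not match")
})

test_that("transfer warm-starts from the parent exactly", {
  sp <- tiny_split(seed = 6)
  g <- train_general(sp, tiny_arch(), fast_hp(iterations = 20, seed = 1))
  tr0 <- train_transfer(g, sp, "head", fast_hp(iterations = 0, seed = 9))
  expect_identical(tr0$weights, g$weights)
  expect_equal(tr0$regime, "transfer")
  expect_equal(tr0$provenance$parent$regime, "general")

  # iteration-0 validation accuracy equals the parent's on that view
  val_head <- flatten_to_samples(sp$validation, views = "head")
  parent_sc <- score_images(g, val_head)
  parent_acc <- mean(max.col(parent_sc, ties.method = "first") ==
                       val_head$genus)
  expect_equal(tr0$history$val_accuracy[1], parent_acc)

  # only general parents are admissible
  s <- train_specific(sp, "head", tiny_arch(), fast_hp(iterations = 0))
  expect_error(train_transfer(s, sp, "head", fast_hp()),
               "general-purpose")
})

test_that("score vectors are softmax-normalized for any model state", {
  sp <- tiny_split(seed = 7)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 0))
  img <- sp$train$specimens[[1]]$images$head[[1]]
  s <- score_image(m, img)
  expect_length(s, 2L)
  expect_true(all(s > 0 & s < 1))
  expect_equal(sum(s), 1, tolerance = 1e-6)

  sc <- score_images(m, flatten_to_samples(sp$validation))
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-6)
})

test_that("a zeroed final layer yields the uniform score vector", {
  sp <- tiny_split(seed = 8)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 5))
  last_fc <- max(which(m$architecture$layers$kind == "fully_connected"))
  m$weights[[last_fc]]$W[] <- 0
  m$weights[[last_fc]]$b[] <- 0
  s <- score_image(m, sp$train$specimens[[1]]$images$dorsum[[1]])
  expect_equal(unname(s), rep(0.5, 2), tolerance = 1e-12)
})

test_that("penultimate features have the descriptor's width and are stable", {
  sp <- tiny_split(seed = 9)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 5))
  img <- sp$train$specimens[[1]]$images$profile[[1]]
  f1 <- extract_penultimate_features(m, img)
  f2 <- extract_penultimate_features(m, img)
  expect_length(f1, 16L)  # second fully-connected width in tiny_arch
  expect_identical(f1, f2)

  one_fc <- architecture(
    dplyr::bind_rows(layer_spec("input"),
                     layer_spec("fully_connected", C_out = 2),
                     layer_spec("softmax"), layer_spec("loss")),
    input_size = 16, n_labels = 2)
  m1 <- train_general(sp, one_fc, fast_hp(iterations = 0))
  expect_error(extract_penultimate_features(m1, img),
               "fewer than two fully-connected")
})

test_that("checkpoints round-trip through save and load with a sidecar", {
  sp <- tiny_split(seed = 10)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 10))
  path <- file.path(withr::local_tempdir(), "ck", "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$weights, m$weights)
  expect_identical(tidy(back), tidy(m))
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$regime, "general")
  expect_equal(sidecar$hyperparams$iterations, 10)
})

test_that("tidy, glance and autoplot expose the training history", {
  sp <- tiny_split(seed = 11)
  m <- train_general(sp, tiny_arch(), fast_hp(iterations = 20, seed = 2))
  h <- tidy(m)
  expect_named(h, c("iteration", "train_loss", "val_accuracy"))
  g <- glance(m)
  expect_equal(g$regime, "general")
  expect_equal(g$best_iteration, m$best_iteration)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
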