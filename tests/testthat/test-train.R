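test_that("the plateau schedule reduces by exactly the factor", {
  cfg <- train_config(initial_lr = 6e-3, plateau_patience = 3)
  improving <- data.frame(lr = rep(6e-3, 6), val_accuracy = seq(0.5, 1, 0.1))
  expect_equal(lr_schedule_step(improving, cfg), 6e-3)
  flat <- data.frame(lr = rep(6e-3, 4), val_accuracy = rep(0.7, 4))
  expect_equal(lr_schedule_step(flat, cfg), 6e-4)
  # two successive plateaus: 6e-2 -> 6e-3 -> 6e-4
  h <- data.frame(lr = 6e-2, val_accuracy = 0.7)
  for (i in 1:10) {
    nl <- lr_schedule_step(h, cfg)
    h <- rbind(h, data.frame(lr = nl, val_accuracy = 0.7))
  }
  expect_equal(sort(unique(h$lr), decreasing = TRUE)[1:3],
               c(6e-2, 6e-3, 6e-4))
  # tracking resets after each reduction: three flat epochs needed again
  h2 <- data.frame(lr = c(6e-2, 6e-2, 6e-2, 6e-2, 6e-3),
                   val_accuracy = rep(0.7, 5))
  expect_equal(lr_schedule_step(h2, cfg), 6e-3)
  expect_error(lr_schedule_step(h2[0, ], cfg), "at least one")
})

test_that("augmentation is shape/range preserving, seeded, and optional", {
  set.seed(2)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  off <- augment_config(FALSE, FALSE, 0, 0)
  expect_identical(augment_batch(x, off), x)
  cfg <- augment_config()
  set.seed(9); a1 <- augment_batch(x, cfg)
  set.seed(9); a2 <- augment_batch(x, cfg)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(x))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # flips are involutions
  flipped <- x[, 16:1, , , drop = FALSE]
  expect_identical(flipped[, 16:1, , , drop = FALSE], x)
  expect_error(augment_config(width_shift_fraction = 0.6), "0.5")
})

test_that("training configs round-trip through YAML", {
  cfg <- train_config(initial_lr = 6e-4, batch_size = 12, max_epochs = 40,
                      seed = 42)
  path <- tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  back <- read_train_config(path)
  expect_equal(back, cfg)
})

test_that("a separable toy task is learned to (near-)perfect train accuracy", {
  d <- separable_data(n = 200, size = 32, seed = 3)
  m <- tiny_binary_model(32, seed = 3)
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 80, batch_size = 24,
                      augment = NULL, seed = 3, early_stop_patience = 10)
  fit <- her2_train(m, d, config = cfg)
  expect_gte(max(fit$history$train_accuracy), 0.99)
  expect_lte(nrow(fit$history), 80)
  # the recorded learning-rate trace is a valid plateau step function
  lr <- fit$history$lr
  drops <- which(diff(lr) != 0)
  expect_true(all(abs(lr[drops + 1] / lr[drops] - 0.1) < 1e-12))
  expect_true(all(diff(lr) <= 0))
})

test_that("training is bit-reproducible from its seed", {
  d <- separable_data(n = 30, size = 16, seed = 5)
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 4, batch_size = 10,
                      seed = 11)
  f1 <- her2_train(tiny_binary_model(16, seed = 2), d, config = cfg)
  f2 <- her2_train(tiny_binary_model(16, seed = 2), d, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("early stopping halts once validation accuracy stops improving", {
  d <- separable_data(n = 40, size = 16, seed = 7)
  val <- separable_data(n = 10, size = 16, seed = 8)
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 60, batch_size = 20,
                      early_stop_patience = 4, augment = NULL, seed = 1)
  fit <- her2_train(tiny_binary_model(16, seed = 1), d, val = val,
                    config = cfg)
  expect_lt(nrow(fit$history), 60)
  best <- fit$history$val_accuracy[fit$best_epoch]
  expect_gte(best, max(fit$history$val_accuracy) - 1e-12)
})

test_that("degenerate datasets and label/head mismatches are rejected", {
  m <- tiny_binary_model(16)
  expect_error(her2_train(m, list(x = array(0, c(16, 16, 3, 0)),
                                  y = integer())), "empty")
  d <- separable_data(20, 16)
  d$y <- sample(0:3, 20, replace = TRUE)
  expect_error(her2_train(m, d), "label/head mismatch")
})

test_that("frozen layers are bit-invariant under training", {
  e <- asNamespace("her2lite")
  d <- separable_data(n = 20, size = 16, seed = 9)
  m <- tiny_binary_model(16, seed = 4)
  wl <- e$weighted_layer_names(m$net)
  expect_identical(wl, c("c1", "c2", "d"))
  m <- freeze_first_layers(m, 2)
  before <- coef(m)
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 2, batch_size = 10,
                      augment = NULL, seed = 2, early_stop_patience = 10)
  fit <- her2_train(m, d, config = cfg)
  after <- coef(fit)
  expect_identical(after[["c1"]], before[["c1"]])
  expect_identical(after[["c2"]], before[["c2"]])
  expect_false(identical(after[["d"]], before[["d"]]))
  # n = 0 restores full trainability; out-of-range is an error
  m0 <- freeze_first_layers(m, 0)
  expect_true(all(vapply(m0$net$layers, `[[`, TRUE, "trainable")))
  expect_error(freeze_first_layers(m, 99), "weighted layers")
})

test_that("freezing the first six weighted layers of ATHER2 works", {
  e <- asNamespace("her2lite")
  m <- ather2(c(96, 96, 3), 2, seed = 1)
  wl <- e$weighted_layer_names(m$net)
  expect_identical(wl[1:6], c("C-1", "L-1", "L-1-att", "L-4", "R-1", "R-3"))
  m <- freeze_first_layers(m, 6)
  frozen <- vapply(m$net$layers[wl[1:6]], `[[`, TRUE, "trainable")
  expect_true(all(!frozen))
  expect_true(m$net$layers[["C-5"]]$trainable)
})

test_that("pretraining transplants feature weights bit-exactly", {
  e <- asNamespace("her2lite")
  m1 <- tiny_binary_model(16, seed = 1)
  # pretend m1 was trained: perturb its weights deterministically
  for (nm in c("c1", "c2", "d"))
    m1$net$layers[[nm]]$params <- lapply(m1$net$layers[[nm]]$params,
                                         function(p) p + 0.5)
  m2 <- tiny_binary_model(16, seed = 99)
  keep <- e$transplantable_layers(m1$net, m2$net, head_names = "d")
  expect_setequal(keep, c("c1", "c2"))
  m2$net <- e$nn_set_weights(m2$net, e$nn_get_weights(m1$net)[keep])
  expect_identical(coef(m2)[["c1"]], coef(m1)[["c1"]])
  expect_identical(coef(m2)[["c2"]], coef(m1)[["c2"]])
  expect_false(identical(coef(m2)[["d"]], coef(m1)[["d"]]))
})

test_that("the two-stage workflow retargets the head to the target arity", {
  d_src <- separable_data(n = 24, size = 16, seed = 21)
  # four-class target: brightness quartiles
  set.seed(22)
  y4 <- rep(0:3, 6)
  x4 <- array(runif(16 * 16 * 3 * 24, 0, 0.2), c(16, 16, 3, 24))
  for (i in 1:24) x4[, , , i] <- x4[, , , i] + y4[i] * 0.2
  builder <- function(k) {
    m <- tiny_binary_model(16, seed = 13)
    if (k > 2) {
      e <- asNamespace("her2lite")
      m$net$layers[["d"]] <- e$layer_dense("d", "g", as.integer(k), 8L,
                                           "linear")
      m$net <- e$nn_init(m$net, 13)
      m$num_classes <- as.integer(k)
      m$out_activation <- "softmax"
    }
    m
  }
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 2, batch_size = 12,
                      augment = NULL, seed = 5, early_stop_patience = 10)
  res <- domain_pretrain_finetune(builder, d_src, list(x = x4, y = y4),
                                  frozen_layer_count = 1,
                                  pretrain_cfg = cfg, finetune_cfg = cfg,
                                  head_names = "d")
  expect_identical(res$fit$model$num_classes, 4L)
  expect_setequal(res$transplanted, c("c1", "c2"))
  z <- predict(res$fit, x4[, , , 1])
  expect_identical(ncol(z), 4L)
  # the frozen first layer kept its transplanted (stage-1) weights
  expect_identical(coef(res$fit)[["c1"]], coef(res$pretrain_fit)[["c1"]])
})
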