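# Shared fixtures. The trained IHC model is expensive (a full training run at
# the 128x128 study conditions), so it is built once per test session and
# shared between the learnability and Grad-CAM checks.

.fixture_env <- new.env(parent = emptyenv())

# 12-patient synthetic IHC cohort at the 128x128 binary study conditions
ihc_cohort_128 <- function() {
  if (is.null(.fixture_env$ihc128))
    .fixture_env$ihc128 <- generate_cohort(12, 8, "IHC", size = 128, seed = 11)
  .fixture_env$ihc128
}

trained_ihc_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  co <- ihc_cohort_128()
  sp <- split_subjectwise(co$manifest, 1 / 3, seed = 2)
  tr <- cohort_data(co, "binary", sp$train)
  te <- cohort_data(co, "binary", sp$test)
  cfg <- train_config(initial_lr = 6e-3, max_epochs = 80,
                      early_stop_patience = 6, seed = 5)
  fit <- her2_train(ather2(c(128, 128, 3), 2, seed = 5), tr, config = cfg)
  .fixture_env$fit <- list(fit = fit, test = te, train = tr)
  .fixture_env$fit
}

# a minimal runnable binary model over the internal graph engine, cheap to
# train; used to exercise the training loop without ATHER2's cost
tiny_binary_model <- function(size = 32, seed = 1) {
  e <- asNamespace("her2lite")
  layers <- list(
    e$layer_input("in"),
    e$layer_conv("c1", "in", 3, 2, 4, 3, "same", "leaky_relu"),
    e$layer_maxpool("p1", "c1", 2, 2),
    e$layer_conv("c2", "p1", 3, 2, 8, 4, "same", "leaky_relu"),
    e$layer_gap("g", "c2"),
    e$layer_dense("d", "g", 1L, 8L, "linear"))
  net <- e$nn_init(e$nn_graph(layers, c(size, size, 3)), seed)
  structure(list(net = net, input_size = c(size, size, 3L), num_classes = 2L,
                 out_activation = "sigmoid", kind = "tiny"),
            class = "her2_model")
}

# linearly separable two-class image set: class 1 is globally brighter
separable_data <- function(n = 60, size = 32, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- array(stats::runif(size * size * 3 * n, 0, 0.4), c(size, size, 3, n))
  x[, , , y == 1] <- x[, , , y == 1] + 0.4
  list(x = x, y = y)
}
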