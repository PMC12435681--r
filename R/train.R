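# Training protocol: Adam with a reduce-on-plateau learning-rate schedule,
# early stopping on validation accuracy with best-weight restoration,
# flip/shift augmentation, and the two pretraining workflows
# (generic transfer vs domain-specific pretraining with layer freezing).

#' Augmentation configuration
#'
#' Training-time augmentation: independent horizontal/vertical flips (each
#' applied with probability 0.5 when enabled) and integer pixel translations
#' drawn uniformly within the shift fractions of each dimension.
#'
#' @param horizontal_flip,vertical_flip Enable the flips.
#' @param width_shift_fraction,height_shift_fraction Maximum translation as a
#'   fraction of the image side, in `[0, 0.5)`.
#' @param fill_mode How vacated pixels are filled: `"nearest"` (edge
#'   replication), `"reflect"` or `"constant"` (zeros).
#' @return An `augment_config` object.
#' @export
augment_config <- function(horizontal_flip = TRUE, vertical_flip = TRUE,
                           width_shift_fraction = 0.1,
                           height_shift_fraction = 0.1,
                           fill_mode = c("nearest", "reflect", "constant")) {
  fill_mode <- match.arg(fill_mode)
  for (f in c(width_shift_fraction, height_shift_fraction))
    if (f < 0 || f >= 0.5) stop("shift fractions must lie in [0, 0.5)")
  structure(list(horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 width_shift_fraction = width_shift_fraction,
                 height_shift_fraction = height_shift_fraction,
                 fill_mode = fill_mode),
            class = "augment_config")
}

shift_indices <- function(n, off, fill_mode) {
  i <- seq_len(n) - off
  switch(fill_mode,
         nearest = pmin(pmax(i, 1L), n),
         reflect = { i <- ((i - 1) %% (2 * n)); ifelse(i < n, i + 1, 2 * n - i) },
         constant = ifelse(i >= 1 & i <= n, i, NA_integer_))
}

#' Augment a batch of images
#'
#' Each image is independently flipped and translated; output shape and pixel
#' range are unchanged. Uses the current R random stream: seed it for
#' bit-identical batches across runs. With all augmentations disabled this is
#' the identity.
#'
#' @param images `(H, W, C, N)` array.
#' @param cfg An [augment_config()].
#' @return An array with the shape of `images`.
#' @export
augment_batch <- function(images, cfg) {
  d <- dim(images)
  out <- images
  for (n in seq_len(d[4])) {
    im <- images[, , , n, drop = FALSE]
    dim(im) <- d[1:3]
    if (cfg$horizontal_flip && stats::runif(1) < 0.5)
      im <- im[, d[2]:1, , drop = FALSE]
    if (cfg$vertical_flip && stats::runif(1) < 0.5)
      im <- im[d[1]:1, , , drop = FALSE]
    dh <- if (cfg$height_shift_fraction > 0)
      sample.int(2 * floor(cfg$height_shift_fraction * d[1]) + 1, 1) -
        floor(cfg$height_shift_fraction * d[1]) - 1 else 0L
    dw <- if (cfg$width_shift_fraction > 0)
      sample.int(2 * floor(cfg$width_shift_fraction * d[2]) + 1, 1) -
        floor(cfg$width_shift_fraction * d[2]) - 1 else 0L
    if (dh != 0 || dw != 0) {
      ih <- shift_indices(d[1], dh, cfg$fill_mode)
      iw <- shift_indices(d[2], dw, cfg$fill_mode)
      im <- im[ih, iw, , drop = FALSE]
      im[is.na(im)] <- 0
    }
    out[, , , n] <- im
  }
  out
}

#' Training configuration
#'
#' Mirrors the training protocol: Adam, cross-entropy loss (binary or
#' categorical per head), batches of 24, at most 80 epochs, a plateau
#' learning-rate schedule (factor 0.1 on validation-accuracy plateaus) and
#' early stopping with best-weight restoration. The initial learning rate is
#' drawn from the grid 6e-2 / 6e-3 / 6e-4 — larger for freshly initialized
#' networks, smaller when fine-tuning.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_factor Multiplicative plateau reduction factor in (0, 1).
#' @param plateau_patience Epochs without validation-accuracy improvement
#'   before the learning rate is reduced.
#' @param early_stop_patience Epochs without improvement before training
#'   stops.
#' @param max_epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @param l2 L2 penalty coefficient on conv/dense kernels.
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @param val_fraction Fraction of training data held out for validation when
#'   no validation set is supplied (stratified; patient-grouped when patient
#'   ids are available).
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` object.
#' @export
train_config <- function(initial_lr = 6e-3, lr_factor = 0.1,
                         plateau_patience = 5L, early_stop_patience = 10L,
                         max_epochs = 80L, batch_size = 24L, l2 = 1e-4,
                         augment = augment_config(), val_fraction = 0.1,
                         seed = 1L, verbose = FALSE) {
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must lie in (0, 1)")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), l2 = l2,
                 augment = augment, val_fraction = val_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Read / write a training configuration as YAML
#'
#' @param cfg A [train_config()].
#' @param path YAML file path.
#' @export
write_train_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$augment <- if (is.null(cfg$augment)) NULL else unclass(cfg$augment)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  aug <- if (is.null(y$augment)) NULL else do.call(augment_config, y$augment)
  y$augment <- NULL
  cfg <- do.call(train_config, y)
  cfg$augment <- aug
  cfg
}

#' Next learning rate under the plateau schedule
#'
#' Recomputes the reduce-on-plateau decision from a training history: if the
#' monitored validation accuracy has not improved for `plateau_patience`
#' epochs since the last improvement (or since the last reduction —
#' improvement tracking resets when the rate drops), the learning rate is
#' multiplied by `lr_factor`, otherwise it is unchanged.
#'
#' @param history Data frame with columns `lr` and `val_accuracy`, one row
#'   per completed epoch.
#' @param cfg A [train_config()].
#' @return The learning rate for the next epoch.
#' @export
lr_schedule_step <- function(history, cfg) {
  n <- nrow(history)
  if (n < 1) stop("need at least one completed epoch")
  cur <- history$lr[n]
  window_start <- 1L
  if (n > 1) {
    ch <- which(history$lr[-1] != history$lr[-n])
    if (length(ch)) window_start <- max(ch) + 1L
  }
  best <- -Inf; wait <- 0L
  for (i in window_start:n) {
    if (history$val_accuracy[i] > best) {
      best <- history$val_accuracy[i]; wait <- 0L
    } else wait <- wait + 1L
  }
  if (wait >= cfg$plateau_patience) cur * cfg$lr_factor else cur
}

#' Freeze the first weighted layers of a model
#'
#' Excludes the first `n` weighted layers (layers carrying trainable
#' parameters, in topological order from the input) from gradient updates;
#' their weights are bit-identical before and after subsequent training.
#' `n = 0` makes every layer trainable.
#'
#' @param model A `her2_model` or `pruneff_model`.
#' @param n Number of leading weighted layers to freeze.
#' @return The model with updated trainability flags.
#' @export
freeze_first_layers <- function(model, n) {
  wl <- weighted_layer_names(model$net)
  if (n < 0 || n > length(wl))
    stop("n must lie in [0, ", length(wl), "] (weighted layers), got ", n)
  for (nm in wl) model$net$layers[[nm]]$trainable <- TRUE
  for (nm in utils::head(wl, n)) model$net$layers[[nm]]$trainable <- FALSE
  model
}

check_data <- function(data, model, what) {
  if (is.null(data$x) || length(data$x) == 0 || is.null(data$y) ||
      length(data$y) == 0)
    stop(what, " dataset is empty")
  k <- length(unique(data$y))
  arity <- max(data$y) + 1L
  if (arity > model$num_classes)
    stop("label/head mismatch: ", what, " labels imply >= ", arity,
         " classes but the model head has ", model$num_classes)
  invisible(TRUE)
}

stratified_holdout <- function(y, patient, fraction) {
  n <- length(y)
  if (!is.null(patient)) {
    pat <- unique(data.frame(patient = patient, y = y))
    val_pat <- character()
    for (cl in unique(pat$y)) {
      pool <- pat$patient[pat$y == cl]
      k <- max(1L, round(length(pool) * fraction))
      if (k >= length(pool)) k <- length(pool) - 1L
      if (k >= 1) val_pat <- c(val_pat, sample(pool, k))
    }
    which(patient %in% val_pat)
  } else {
    idx <- integer()
    for (cl in unique(y)) {
      pool <- which(y == cl)
      k <- max(1L, round(length(pool) * fraction))
      if (k >= length(pool)) k <- max(length(pool) - 1L, 0L)
      if (k >= 1) idx <- c(idx, sample(pool, k))
    }
    idx
  }
}

predict_batched <- function(net, x, batch = 24L) {
  n <- dim(x)[4]
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    z <- nn_forward(net, x[, , , s:e, drop = FALSE], training = FALSE)$out
    out <- if (is.null(out)) z else cbind(out, z)
  }
  out
}

#' Train a HER2 network
#'
#' Runs the full training protocol on in-memory data: Adam updates with L2
#' kernel penalty, augmentation, reduce-on-plateau learning rate, early
#' stopping monitored on validation accuracy, and restoration of the
#' best-validation weights. Fully reproducible from `config$seed`.
#'
#' @param model A `her2_model` or `pruneff_model`.
#' @param train A list with `x` (`(H, W, 3, N)` array, values 0-1), `y`
#'   (0-based integer labels) and optionally `patient` (ids used for grouped
#'   validation splits), e.g. from [cohort_data()].
#' @param val Optional validation list of the same form; when `NULL`, a
#'   stratified (patient-grouped) fraction of `train` is held out.
#' @param config A [train_config()].
#' @return A `her2_fit`: the trained model (best weights), the per-epoch
#'   `history` (learning rate, losses, accuracies), `best_epoch` and
#'   `val_accuracy`.
#' @export
her2_train <- function(model, train, val = NULL, config = train_config()) {
  check_data(train, model, "train")
  binary <- model$out_activation == "sigmoid"
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  if (is.null(val)) {
    vi <- stratified_holdout(train$y, train$patient, config$val_fraction)
    val <- list(x = train$x[, , , vi, drop = FALSE], y = train$y[vi])
    train <- list(x = train$x[, , , -vi, drop = FALSE], y = train$y[-vi],
                  patient = train$patient[-vi])
  }
  check_data(val, model, "validation")

  net <- model$net
  opt <- adam_init(net)
  lr <- config$initial_lr
  n <- dim(train$x)[4]
  hist <- data.frame()
  best_acc <- -Inf; best_epoch <- 0L
  best_w <- nn_get_weights(net); best_b <- nn_get_buffers(net)
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tl <- 0; tc <- 0; nb <- 0L
    for (s in seq(1, n, by = config$batch_size)) {
      bi <- ord[s:min(s + config$batch_size - 1, n)]
      xb <- train$x[, , , bi, drop = FALSE]
      if (!is.null(config$augment)) xb <- augment_batch(xb, config$augment)
      f <- nn_forward(net, xb, training = TRUE)
      L <- nn_loss(f$out, train$y[bi], binary)
      bk <- nn_backward(net, f, L$dz)
      st <- adam_step(net, bk$pgrads, opt, lr, weight_decay = config$l2)
      net <- st$net; opt <- st$state
      nb <- nb + 1L
      net <- nn_update_bn(net, f, momentum = (nb - 1) / nb)
      tl <- tl + L$loss * length(bi)
      tc <- tc + sum(L$pred == train$y[bi])
    }
    zv <- predict_batched(net, val$x, config$batch_size)
    Lv <- nn_loss(zv, val$y, binary)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = tl / n, train_accuracy = tc / n,
      val_loss = Lv$loss, val_accuracy = mean(Lv$pred == val$y)))
    if (config$verbose)
      message(sprintf("epoch %3d lr %.1e loss %.4f acc %.3f val %.3f",
                      epoch, lr, tl / n, tc / n, mean(Lv$pred == val$y)))
    if (hist$val_accuracy[epoch] > best_acc) {
      best_acc <- hist$val_accuracy[epoch]; best_epoch <- epoch
      best_w <- nn_get_weights(net); best_b <- nn_get_buffers(net)
      wait <- 0L
    } else wait <- wait + 1L
    if (wait >= config$early_stop_patience) break
    lr <- lr_schedule_step(hist, config)
  }
  net <- nn_set_weights(net, best_w)
  net <- nn_set_buffers(net, best_b)
  model$net <- net
  structure(list(model = model, history = hist, config = config,
                 best_epoch = best_epoch, val_accuracy = best_acc),
            class = "her2_fit")
}

#' @export
print.her2_fit <- function(x, ...) {
  cat(sprintf("her2_fit: %d epochs, best validation accuracy %.3f (epoch %d)\n",
              nrow(x$history), x$val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
predict.her2_fit <- function(object, x, type = c("prob", "class", "logit"),
                             ...) {
  predict(object$model, x, type = match.arg(type), ...)
}

#' @export
coef.her2_fit <- function(object, ...) coef(object$model)

#' Plot training curves
#'
#' @param x A `her2_fit`.
#' @param ... Unused.
#' @export
plot.her2_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mar = c(4, 4, 2, 4))
  plot(h$epoch, h$train_accuracy, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", col = "steelblue")
  graphics::lines(h$epoch, h$val_accuracy, col = "firebrick")
  graphics::legend("bottomright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate a model on labelled data
#'
#' @param object A `her2_fit`, `her2_model` or `pruneff_model`.
#' @param data A list with `x`, `y` and optionally `levels` (class names for
#'   the report).
#' @return A [confusion_and_summary()] metrics report.
#' @export
evaluate_model <- function(object, data) {
  model <- if (inherits(object, "her2_fit")) object$model else object
  pr <- predict(model, data$x, type = "prob")
  lev <- data$levels %||% as.character(seq_len(ncol(pr)) - 1L)
  y <- factor(lev[data$y + 1L], levels = lev)
  confusion_and_summary(y, pr)
}

transplantable_layers <- function(from_net, to_net, head_names) {
  keep <- character()
  for (nm in names(from_net$layers)) {
    if (nm %in% head_names || is.null(to_net$layers[[nm]])) next
    pf <- from_net$layers[[nm]]$params
    pt <- to_net$layers[[nm]]$params
    if (length(pf) && identical(lapply(pf, dim), lapply(pt, dim)) &&
        identical(lengths(pf), lengths(pt)))
      keep <- c(keep, nm)
  }
  keep
}

#' Domain-specific pretraining followed by fine-tuning
#'
#' Stage 1 trains a freshly built network on the source task. Stage 2 builds
#' the same architecture with a fresh classification head of the target
#' arity, transplants every feature-extraction weight from stage 1
#' (bit-exact), optionally freezes the first `frozen_layer_count` weighted
#' layers, and fine-tunes on the target task.
#'
#' @param builder Function `function(num_classes)` returning an untrained
#'   model (e.g. a wrapper around [ather2()]).
#' @param source,target Data lists (`x`, `y`, optional `patient`) for the two
#'   stages; class arities are inferred from the labels.
#' @param frozen_layer_count Leading weighted layers frozen during stage 2.
#' @param pretrain_cfg,finetune_cfg [train_config()]s for the two stages; by
#'   convention the fine-tuning rate is one grid step below the pretraining
#'   rate.
#' @param head_names Names of head layers never transplanted (default: the
#'   final dense layer `"C-5"` / `"head_dense"`).
#' @return A list: `fit` (stage-2 `her2_fit`), `pretrain_fit` (stage 1),
#'   and `transplanted` (layer names copied).
#' @export
domain_pretrain_finetune <- function(builder, source, target,
                                     frozen_layer_count = 0L,
                                     pretrain_cfg = train_config(),
                                     finetune_cfg = train_config(initial_lr = 6e-4),
                                     head_names = c("C-5", "head_dense")) {
  src_classes <- max(2L, max(source$y) + 1L)
  tgt_classes <- max(2L, max(target$y) + 1L)
  m1 <- builder(src_classes)
  fit1 <- her2_train(m1, source, config = pretrain_cfg)
  m2 <- builder(tgt_classes)
  keep <- transplantable_layers(fit1$model$net, m2$net, head_names)
  w <- nn_get_weights(fit1$model$net)[keep]
  b <- nn_get_buffers(fit1$model$net)[keep]
  m2$net <- nn_set_weights(m2$net, w)
  m2$net <- nn_set_buffers(m2$net, b)
  m2 <- freeze_first_layers(m2, frozen_layer_count)
  fit2 <- her2_train(m2, target, config = finetune_cfg)
  list(fit = fit2, pretrain_fit = fit1, transplanted = keep)
}
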