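# S3 methods shared by her2_model (ATHER2) and pruneff_model objects.

#' @export
print.her2_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("ATHER2 network (%s variant)\n", x$variant))
  cat(sprintf("  input %dx%dx%d, %d classes (%s head)\n",
              x$input_size[1], x$input_size[2], x$input_size[3],
              x$num_classes, x$out_activation))
  cat(sprintf("  %s parameters (%s trainable)\n",
              format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ",")))
  invisible(x)
}

#' Per-layer summary table
#'
#' @param object A `her2_model` or `pruneff_model`.
#' @param ... Unused.
#' @return A data frame with one row per layer: name, kind, output shape and
#'   parameter count, suitable for CSV export.
#' @export
summary.her2_model <- function(object, ...) {
  tr <- object$trace
  shp <- function(nm) {
    i <- match(sub("-att$", "", nm), tr$name)
    if (is.na(i)) return(NA_character_)
    if (is.na(tr$height[i])) as.character(tr$channels[i])
    else sprintf("%d x %d x %d", tr$height[i], tr$width[i], tr$channels[i])
  }
  out <- data.frame(
    name = vapply(object$net$layers, `[[`, "", "name"),
    kind = vapply(object$net$layers, `[[`, "", "kind"),
    output_shape = vapply(vapply(object$net$layers, `[[`, "", "name"), shp, ""),
    parameters = vapply(object$net$layers, function(l)
      sum(vapply(l$params, length, 0L)) + sum(vapply(l$buffers, length, 0L)),
      0L),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("her2_model_summary", "data.frame")
  out
}

#' @export
print.her2_model_summary <- function(x, ...) {
  print.data.frame(x, right = FALSE)
  cat(sprintf("Total parameters: %s\n",
              format(sum(x$parameters), big.mark = ",")))
  invisible(x)
}

#' Export a per-layer model summary to CSV
#'
#' @param model A `her2_model` or `pruneff_model`.
#' @param path Output CSV path.
#' @return The summary data frame, invisibly.
#' @export
write_model_summary <- function(model, path) {
  s <- summary(model)
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(s)
}

#' @export
coef.her2_model <- function(object, ...) nn_get_weights(object$net)

as_batch <- function(x, input_size) {
  if (is.list(x) && !is.array(x)) {
    x <- array(unlist(x), c(dim(x[[1]]), length(x)))
  }
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (length(dim(x)) != 4)
    stop("images must be an (H, W, C) array or an (H, W, C, N) batch")
  if (!is.null(input_size) && !all(dim(x)[1:3] == input_size))
    stop("image shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match model input ", paste(input_size, collapse = "x"))
  x
}

#' Predict from a HER2 network
#'
#' Runs the network in inference mode (dropout off, batch-norm moving
#' statistics).
#'
#' @param object A `her2_model` or `pruneff_model`.
#' @param x An `(H, W, C)` image or `(H, W, C, N)` batch with values in 0-1.
#' @param type `"prob"` for class probabilities, `"class"` for 0-based class
#'   ids, `"logit"` for raw head outputs.
#' @param ... Unused.
#' @return A numeric matrix (N x K probabilities; binary models report the two
#'   class probabilities), an integer vector, or a logit matrix.
#' @export
predict.her2_model <- function(object, x,
                               type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  x <- as_batch(x, object$input_size)
  z <- nn_forward(object$net, x, training = FALSE)$out  # (U, N)
  binary <- object$out_activation == "sigmoid"
  if (type == "logit") return(t(z))
  if (binary) {
    p1 <- 1 / (1 + exp(-z[1, ]))
    pr <- cbind(`0` = 1 - p1, `1` = p1)
  } else {
    pr <- t(softmax_cols(z))
    colnames(pr) <- as.character(seq_len(ncol(pr)) - 1L)
  }
  if (type == "prob") pr else max.col(pr) - 1L
}
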