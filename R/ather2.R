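# ATHER2: a two-branch lightweight CNN for HER2 scoring. A shared stem
# (3x3 conv + 2x2 max pool) forks into a left branch (3x3 convs with CBAM
# attention and dropout) and a right branch (3x3/5x5 convs with batch
# normalization); each branch ends in global average pooling, the two
# 128-length vectors are concatenated and fed to a small dense head.

ather2_arch_table <- function(num_classes, variant) {
  row <- function(name, kind, branch, kernel = NA, stride = NA, units = NA,
                  rate = NA, inputs = NULL)
    list(name = name, kind = kind, branch = branch, kernel = kernel,
         stride = stride, units = units, rate = rate, inputs = inputs)
  stem <- list(
    row("C-0", "input", "common"),
    row("C-1", "conv", "common", 3, 1, 16),
    row("C-2", "maxpool", "common", 2, 2))
  left <- list(
    row("L-1", "conv_cbam", "left", 3, 3, 64, inputs = "C-2"),
    row("L-2", "maxpool", "left", 3, 2),
    row("L-3", "dropout", "left", rate = 0.1),
    row("L-4", "conv", "left", 3, 3, 128),
    row("L-5", "maxpool", "left", 3, 2),
    row("L-6", "dropout", "left", rate = 0.1),
    row("L-7", "gap", "left"))
  right <- list(
    row("R-1", "conv", "right", 3, 1, 32, inputs = "C-2"),
    row("R-2", "maxpool", "right", 3, 1),
    row("R-3", "conv", "right", 3, 2, 64),
    row("R-4", "maxpool", "right", 3, 2),
    row("R-5", "batchnorm", "right"),
    row("R-6", "conv", "right", 5, 2, 128),
    row("R-7", "maxpool", "right", 3, 3),
    row("R-8", "gap", "right"))
  head_units <- if (num_classes == 2) 1L else as.integer(num_classes)
  rows <- switch(variant,
    full = c(stem, left, right,
             list(row("C-3", "concat", "head", inputs = c("L-7", "R-8")))),
    left_only = c(stem, left),
    right_only = c(stem, right))
  feeder <- switch(variant, full = "C-3", left_only = "L-7",
                   right_only = "R-8")
  rows <- c(rows, list(
    row("C-4", "dense", "head", units = 128, inputs = feeder),
    row("C-5", "dense", "head", units = head_units, inputs = "C-4")))
  rows
}

#' Build the ATHER2 network
#'
#' Constructs the two-branch attention network as a runnable model: a 3x3/16
#' stride-1 convolution and 2x2 stride-2 max pool stem; a left branch of 3x3
#' convolutions (strides 3) with CBAM attention after the first convolution,
#' 3x3 max pools and 10% dropout; a right branch of 3x3 and 5x5 convolutions
#' with max pooling and batch normalization; global average pooling in each
#' branch (128 features each), concatenation (256), a 128-unit dense layer and
#' the classification head. All convolutions use same padding, all pools valid
#' padding; hidden activations are leaky ReLU; conv/dense kernels carry an L2
#' penalty during training. With `num_classes = 2` the head is a single
#' sigmoid unit, otherwise `num_classes` softmax units.
#'
#' @param input_size Integer vector `c(height, width, 3)`. Height and width
#'   must be large enough for every stride/pool (at least 86).
#' @param num_classes Number of classes (>= 2).
#' @param variant `"full"` (both branches), `"left_only"` or `"right_only"`
#'   (single-branch ablations feeding one 128-length vector to the head).
#' @param cbam A [cbam_config()] for the left-branch attention block.
#' @param alpha Leaky-ReLU negative slope.
#' @param l2 L2 penalty coefficient applied to conv/dense kernels by the
#'   trainer.
#' @param seed Integer seed for weight initialization; the same seed always
#'   yields identical initial weights.
#' @return An object of class `her2_model` with `print`, `summary`, `coef`
#'   and `predict` methods.
#' @seealso [shape_trace()], [count_parameters()], [her2_train()]
#' @export
#' @examples
#' m <- ather2(input_size = c(512, 512, 3), num_classes = 2)
#' count_parameters(m)
ather2 <- function(input_size = c(512, 512, 3), num_classes = 2L,
                   variant = c("full", "left_only", "right_only"),
                   cbam = cbam_config(), alpha = 0.3, l2 = 1e-4, seed = 1L) {
  variant <- match.arg(variant)
  if (length(input_size) != 3 || input_size[3] != 3)
    stop("input_size must be c(height, width, 3): RGB input only")
  if (num_classes < 2) stop("num_classes must be >= 2")
  arch <- ather2_arch_table(num_classes, variant)
  trace <- ather2_shape_trace(arch, input_size)   # errors name failing layer

  chans <- structure(trace$channels, names = trace$name)
  layers <- list(layer_input("C-0"))
  prev <- "C-0"
  for (r in arch[-1]) {
    inp <- r$inputs %||% prev
    in_ch <- chans[[inp[[1]]]]
    new <- switch(r$kind,
      conv = layer_conv(r$name, inp, r$kernel, r$stride, r$units, in_ch,
                        "same", "leaky_relu", alpha),
      conv_cbam = {
        cv <- layer_conv(r$name, inp, r$kernel, r$stride, r$units, in_ch,
                         "same", "leaky_relu", alpha)
        at <- layer_cbam(paste0(r$name, "-att"), r$name, r$units, cbam)
        list(cv, at)
      },
      maxpool = layer_maxpool(r$name, inp, r$kernel, r$stride),
      dropout = layer_dropout(r$name, inp, r$rate),
      batchnorm = layer_batchnorm(r$name, inp, in_ch),
      gap = layer_gap(r$name, inp),
      concat = layer_concat(r$name, inp),
      dense = layer_dense(r$name, inp, r$units,
                          sum(vapply(inp, function(j) chans[[j]], 0)),
                          if (r$name == "C-5") "linear" else "leaky_relu",
                          alpha))
    if (r$kind == "conv_cbam") {
      layers <- c(layers, new)
      prev <- new[[2]]$name
      chans[[prev]] <- r$units
    } else {
      layers[[length(layers) + 1]] <- new
      prev <- r$name
    }
  }
  # dense inputs must point at the CBAM output, not the raw conv, in the
  # left branch; fix predecessors that referenced a conv_cbam row
  att_of <- "L-1"
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$name != paste0(att_of, "-att") && att_of %in% l$inputs)
      layers[[i]]$inputs[l$inputs == att_of] <- paste0(att_of, "-att")
  }
  net <- nn_init(nn_graph(layers, input_size), seed)
  structure(list(net = net, arch = arch, trace = trace,
                 input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes), variant = variant,
                 out_activation = if (num_classes == 2) "sigmoid" else "softmax",
                 cbam = cbam, alpha = alpha, l2 = l2, seed = as.integer(seed),
                 kind = "ather2"),
            class = "her2_model")
}

ather2_shape_trace <- function(arch, input_size) {
  h <- list(); w <- list(); ch <- list()
  out <- data.frame(name = character(), height = integer(),
                    width = integer(), channels = integer(),
                    stringsAsFactors = FALSE)
  shp <- list()  # name -> c(h, w, c) for maps, c(NA, NA, len) for vectors
  for (r in arch) {
    inp <- (r$inputs %||% if (nrow(out)) out$name[nrow(out)] else NULL)
    s <- if (r$kind == "input") as.integer(input_size) else shp[[inp[[1]]]]
    res <- switch(r$kind,
      input = s,
      conv = , conv_cbam = {
        hh <- conv_output_size(s[1], r$kernel, r$stride)
        ww <- conv_output_size(s[2], r$kernel, r$stride)
        c(hh, ww, r$units)
      },
      maxpool = {
        if (s[1] < r$kernel || s[2] < r$kernel)
          stop("layer ", r$name, ": input ", s[1], "x", s[2],
               " too small for a ", r$kernel, "x", r$kernel, " valid pool")
        c(pool_output_size(s[1], r$kernel, r$stride),
          pool_output_size(s[2], r$kernel, r$stride), s[3])
      },
      dropout = , batchnorm = s,
      gap = c(NA_integer_, NA_integer_, s[3]),
      concat = c(NA_integer_, NA_integer_,
                 sum(vapply(r$inputs, function(j) shp[[j]][3], 0L))),
      dense = c(NA_integer_, NA_integer_, r$units))
    if (any(!is.na(res[1:2]) & res[1:2] < 1))
      stop("layer ", r$name, ": spatial size collapsed to ", res[1], "x",
           res[2])
    shp[[r$name]] <- as.integer(res)
    out <- rbind(out, data.frame(name = r$name, height = as.integer(res[1]),
                                 width = as.integer(res[2]),
                                 channels = as.integer(res[3])))
  }
  class(out) <- c("shape_trace", "data.frame")
  out
}

#' Per-layer output shapes of a model
#'
#' Computes the deterministic per-layer shape trace using the network's
#' padding rules (same-padded convolutions, valid pooling); dropout, batch
#' normalization and attention preserve shape, global average pooling maps
#' `(H, W, C)` to `C`, concatenation sums feature lengths.
#'
#' @param model A [ather2()] model (or any object with a stored trace).
#' @param input_size Optional `c(height, width, 3)` to retrace at a different
#'   input resolution.
#' @return A data frame of class `shape_trace` with columns `name`, `height`,
#'   `width`, `channels` (height/width are `NA` for vector-valued layers).
#' @export
#' @examples
#' shape_trace(ather2(c(512, 512, 3), 2))
shape_trace <- function(model, input_size = NULL) {
  stopifnot(inherits(model, "her2_model"))
  if (is.null(input_size)) return(model$trace)
  ather2_shape_trace(model$arch, input_size)
}

#' Count model parameters
#'
#' Tallies trainable parameters (conv/dense kernels and biases, batch-norm
#' scale/shift, attention weights) and non-trainable parameters (batch-norm
#' moving statistics).
#'
#' @param model A `her2_model`, a `pruneff_model`, or an internal graph.
#' @return A list with components `trainable`, `non_trainable` and `total`
#'   (`total = trainable + non_trainable`), of class `param_count`.
#' @export
#' @examples
#' count_parameters(ather2(c(512, 512, 3), 2))
count_parameters <- function(model) {
  net <- if (inherits(model, "nn_graph")) model else model$net
  tr <- 0L; ntr <- 0L
  for (l in net$layers) {
    tr <- tr + sum(vapply(l$params, length, 0L))
    ntr <- ntr + sum(vapply(l$buffers, length, 0L))
  }
  structure(list(trainable = tr, non_trainable = ntr, total = tr + ntr),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("Parameters: %s trainable + %s non-trainable = %s total\n",
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ","),
              format(x$total, big.mark = ",")))
  invisible(x)
}
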