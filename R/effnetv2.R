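# EfficientNetV2B0 backbone (stem + six MBConv/fused-MBConv stages + top),
# expressed as data so block pruning is generic over any layer-named graph.
# Layer names follow the canonical published naming scheme
# (e.g. "block4c_add", "block1a_project_activation").

effnetv2b0_stages <- function() {
  list(
    list(id = 1L, type = "fused", expand = 1, kernel = 3, stride = 1,
         filters = 16, repeats = 1),
    list(id = 2L, type = "fused", expand = 4, kernel = 3, stride = 2,
         filters = 32, repeats = 2),
    list(id = 3L, type = "fused", expand = 4, kernel = 3, stride = 2,
         filters = 48, repeats = 2),
    list(id = 4L, type = "mbconv", expand = 4, kernel = 3, stride = 2,
         filters = 96, repeats = 3, se = 0.25),
    list(id = 5L, type = "mbconv", expand = 6, kernel = 3, stride = 1,
         filters = 112, repeats = 5, se = 0.25),
    list(id = 6L, type = "mbconv", expand = 6, kernel = 3, stride = 2,
         filters = 192, repeats = 8, se = 0.25))
}

# Append one fused-MBConv or MBConv block's layers to a growing layer list.
effnet_block_layers <- function(prefix, type, expand, kernel, stride,
                                cin, cout, se_ratio, prev) {
  L <- list(); nm <- function(s) paste0(prefix, "_", s)
  push <- function(l) L[[length(L) + 1]] <<- l
  cexp <- as.integer(round(cin * expand))
  if (type == "fused" && expand == 1) {
    push(layer_conv(nm("project_conv"), prev, kernel, stride, cout, cin,
                    "same", "linear", use_bias = FALSE))
    push(layer_batchnorm(nm("project_bn"), nm("project_conv"), cout))
    push(layer_activation(nm("project_activation"), nm("project_bn"), "swish"))
    return(list(layers = L, out = nm("project_activation")))
  }
  if (type == "fused") {
    push(layer_conv(nm("expand_conv"), prev, kernel, stride, cexp, cin,
                    "same", "linear", use_bias = FALSE))
    push(layer_batchnorm(nm("expand_bn"), nm("expand_conv"), cexp))
    push(layer_activation(nm("expand_activation"), nm("expand_bn"), "swish"))
    cur <- nm("expand_activation")
  } else {
    push(layer_conv(nm("expand_conv"), prev, 1, 1, cexp, cin,
                    "same", "linear", use_bias = FALSE))
    push(layer_batchnorm(nm("expand_bn"), nm("expand_conv"), cexp))
    push(layer_activation(nm("expand_activation"), nm("expand_bn"), "swish"))
    push(layer_dwconv(nm("dwconv2"), nm("expand_activation"), kernel, stride,
                      cexp, "same", "linear"))
    push(layer_batchnorm(nm("bn"), nm("dwconv2"), cexp))
    push(layer_activation(nm("activation"), nm("bn"), "swish"))
    cur <- nm("activation")
    if (!is.null(se_ratio) && se_ratio > 0) {
      cse <- max(1L, as.integer(cin * se_ratio))
      push(layer_gap(nm("se_squeeze"), cur))
      push(layer_dense(nm("se_reduce"), nm("se_squeeze"), cse, cexp, "swish"))
      push(layer_dense(nm("se_expand"), nm("se_reduce"), cexp, cse, "sigmoid"))
      push(layer_scale_channels(nm("se_excite"), c(cur, nm("se_expand"))))
      cur <- nm("se_excite")
    }
  }
  push(layer_conv(nm("project_conv"), cur, 1, 1, cout, cexp,
                  "same", "linear", use_bias = FALSE))
  push(layer_batchnorm(nm("project_bn"), nm("project_conv"), cout))
  out <- nm("project_bn")
  if (stride == 1 && cin == cout) {
    push(layer_add(nm("add"), c(out, prev)))
    out <- nm("add")
  }
  list(layers = L, out = out)
}

#' Build the EfficientNetV2B0 backbone
#'
#' Constructs the full feature-extraction path (stem, six stages of
#' fused-MBConv / MBConv blocks with squeeze-excitation, and the 1x1x1280 top
#' convolution) with the canonical per-layer naming scheme, so that named stop
#' layers such as `"block4c_add"` resolve. Weights are seeded-random;
#' externally trained checkpoints can be loaded with [load_weights()].
#'
#' @param input_size `c(height, width, 3)`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `effnet_backbone` wrapping the layer graph.
#' @export
build_effnetv2b0 <- function(input_size = c(224, 224, 3), seed = 1L) {
  layers <- list(layer_input("input"))
  push <- function(l) layers[[length(layers) + 1]] <<- l
  push(layer_conv("stem_conv", "input", 3, 2, 32, 3, "same", "linear",
                  use_bias = FALSE))
  push(layer_batchnorm("stem_bn", "stem_conv", 32))
  push(layer_activation("stem_activation", "stem_bn", "swish"))
  prev <- "stem_activation"; cin <- 32L
  for (st in effnetv2b0_stages()) {
    for (r in seq_len(st$repeats)) {
      prefix <- paste0("block", st$id, letters[r])
      stride <- if (r == 1) st$stride else 1L
      bl <- effnet_block_layers(prefix, st$type, st$expand, st$kernel, stride,
                                cin, st$filters, st$se, prev)
      for (l in bl$layers) push(l)
      prev <- bl$out; cin <- st$filters
    }
  }
  push(layer_conv("top_conv", prev, 1, 1, 1280L, cin, "same", "linear",
                  use_bias = FALSE))
  push(layer_batchnorm("top_bn", "top_conv", 1280L))
  push(layer_activation("top_activation", "top_bn", "swish"))
  net <- nn_init(nn_graph(layers, input_size), seed)
  structure(list(net = net, input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "effnet_backbone")
}

#' @export
print.effnet_backbone <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("EfficientNetV2B0 backbone: %d layers, %s parameters\n",
              length(x$net$layers), format(pc$total, big.mark = ",")))
  invisible(x)
}

#' The block-pruning subnetwork catalog
#'
#' Lists the five pruned subnetworks obtained by truncating EfficientNetV2B0
#' after each of its first five stages, in diminishing-size order SBN5 (blocks
#' 1-5) down to SBN1 (block 1 only), with the named stop layer of each.
#'
#' @return A data frame of class `subnetwork_catalog` with columns `name`,
#'   `blocks` and `stop_layer`.
#' @export
#' @examples
#' list_stop_layers()
list_stop_layers <- function() {
  out <- data.frame(
    name = c("SBN5", "SBN4", "SBN3", "SBN2", "SBN1"),
    blocks = c("1-5", "1-4", "1-3", "1-2", "1"),
    stop_layer = c("block5e_add", "block4c_add", "block3b_add",
                   "block2b_add", "block1a_project_activation"),
    stringsAsFactors = FALSE)
  class(out) <- c("subnetwork_catalog", "data.frame")
  out
}

#' Truncate a backbone at a named stop layer
#'
#' Block pruning removes every layer after `stop_layer`, yielding a feature
#' extractor that maps an input image to the activation tensor of the stop
#' layer. Retained weights are carried over unchanged.
#'
#' @param backbone An [build_effnetv2b0()] backbone.
#' @param stop_layer Layer name at which to cut (e.g. `"block4c_add"`).
#' @return An `effnet_backbone` containing only the retained prefix.
#' @export
prune_backbone <- function(backbone, stop_layer) {
  stopifnot(inherits(backbone, "effnet_backbone"))
  nms <- vapply(backbone$net$layers, `[[`, "", "name")
  i <- match(stop_layer, nms)
  if (is.na(i)) {
    near <- utils::head(agrep(stop_layer, nms, max.distance = 0.3,
                              value = TRUE), 5)
    stop("unknown stop layer '", stop_layer, "'",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  net <- backbone$net
  net$layers <- net$layers[seq_len(i)]
  net$output <- stop_layer
  structure(list(net = net, input_size = backbone$input_size,
                 seed = backbone$seed, stop_layer = stop_layer),
            class = "effnet_backbone")
}

# channel count of a graph's output layer
graph_out_channels <- function(net) {
  l <- net$layers[[net$output]]
  repeat {
    ch <- switch(l$kind,
      conv = l$filters, dwconv = l$channels, batchnorm = l$channels,
      dense = l$units, NULL)
    if (!is.null(ch)) return(as.integer(ch))
    l <- net$layers[[l$inputs[[1]]]]
  }
}

#' Attach the pruning projection and classification head
#'
#' Appends the block-pruning head to a truncated feature extractor: a 7x7,
#' 192-channel same-padded convolution (projecting features into a richer
#' representation space), batch normalization, leaky ReLU, global average
#' pooling, and a dense output layer (1 sigmoid unit for two classes,
#' `num_classes` softmax units otherwise). Only the appended layers are
#' freshly initialized; the extractor's weights are untouched.
#'
#' @param extractor An `effnet_backbone` whose output is a feature map.
#' @param num_classes Number of target classes (>= 2).
#' @param seed Seed for the fresh head weights.
#' @return A `pruneff_model` (also a `her2_model`), runnable with `predict`.
#' @export
attach_projection_head <- function(extractor, num_classes, seed = 1L) {
  stopifnot(inherits(extractor, "effnet_backbone"))
  cin <- graph_out_channels(extractor$net)
  head_units <- if (num_classes == 2) 1L else as.integer(num_classes)
  top <- extractor$net$output
  hl <- list(
    layer_conv("head_project_conv", top, 7, 1, 192L, cin, "same",
               "linear", use_bias = TRUE),
    layer_batchnorm("head_project_bn", "head_project_conv", 192L),
    layer_activation("head_project_activation", "head_project_bn",
                     "leaky_relu", 0.3),
    layer_gap("head_gap", "head_project_activation"),
    layer_dense("head_dense", "head_gap", head_units, 192L, "linear"))
  init <- nn_init(nn_graph(c(list(layer_input("x")),
                             lapply(hl, function(l) { l$inputs <- "x"; l })),
                           NULL), seed)
  for (j in seq_along(hl)) {
    hl[[j]]$params <- init$layers[[hl[[j]]$name]]$params
    hl[[j]]$buffers <- init$layers[[hl[[j]]$name]]$buffers
  }
  net <- extractor$net
  for (l in hl) net$layers[[l$name]] <- l
  net$output <- "head_dense"
  structure(list(net = net, input_size = extractor$input_size,
                 num_classes = as.integer(num_classes),
                 out_activation = if (num_classes == 2) "sigmoid" else "softmax",
                 stop_layer = extractor$stop_layer %||% NA_character_,
                 kind = "pruneff"),
            class = c("pruneff_model", "her2_model"))
}

#' Build a PrunEff subnetwork (or the unpruned reference model)
#'
#' Composes [prune_backbone()] and [attach_projection_head()] at one of the
#' five catalog stop layers. `level = "SBN4"` is PrunEff4, the configuration
#' that balances size against accuracy. `level = "full"` attaches only global
#' average pooling and a dense head to the untruncated backbone (the 7x7
#' projection is specific to the pruned variants).
#'
#' @param level One of `"SBN1"`..`"SBN5"` or `"full"`.
#' @param num_classes Number of target classes (>= 2).
#' @param input_size `c(height, width, 3)`; the canonical resolution is
#'   224x224.
#' @param weights Optional path to a checkpoint saved with [save_weights()]
#'   holding externally pretrained backbone weights; retained layers load
#'   bit-identically. `NULL` leaves the seeded-random initialization.
#' @param seed Seed for weight initialization.
#' @return A `pruneff_model`.
#' @export
#' @examples
#' m <- build_pruneff("SBN1", num_classes = 2, input_size = c(96, 96, 3))
#' count_parameters(m)
build_pruneff <- function(level = "SBN4", num_classes = 2L,
                          input_size = c(224, 224, 3), weights = NULL,
                          seed = 1L) {
  cat_ <- list_stop_layers()
  if (!level %in% c(cat_$name, "full"))
    stop("level must be one of ", paste(c(cat_$name, "full"), collapse = ", "))
  bb <- build_effnetv2b0(input_size, seed)
  if (!is.null(weights)) bb$net <- nn_set_weights(bb$net, readRDS(weights))
  if (level == "full") {
    net <- bb$net
    head_units <- if (num_classes == 2) 1L else as.integer(num_classes)
    dl <- layer_dense("head_dense", "head_gap", head_units, 1280L, "linear")
    init <- nn_init(nn_graph(list(layer_input("x"),
                                  { d <- dl; d$inputs <- "x"; d }), NULL),
                    seed)
    dl$params <- init$layers[["head_dense"]]$params
    net$layers[["head_gap"]] <- layer_gap("head_gap", "top_activation")
    net$layers[["head_dense"]] <- dl
    net$output <- "head_dense"
    return(structure(list(net = net, input_size = bb$input_size,
                          num_classes = as.integer(num_classes),
                          out_activation = if (num_classes == 2) "sigmoid"
                                           else "softmax",
                          stop_layer = NA_character_, kind = "pruneff"),
                     class = c("pruneff_model", "her2_model")))
  }
  stop_layer <- cat_$stop_layer[cat_$name == level]
  attach_projection_head(prune_backbone(bb, stop_layer), num_classes, seed)
}

#' @export
print.pruneff_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("PrunEff model (%s)\n",
              if (is.na(x$stop_layer)) "full EfficientNetV2B0"
              else paste("pruned at", x$stop_layer)))
  cat(sprintf("  input %dx%dx%d, %d classes (%s head)\n",
              x$input_size[1], x$input_size[2], x$input_size[3],
              x$num_classes, x$out_activation))
  cat(sprintf("  %s parameters (%s trainable)\n",
              format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ",")))
  invisible(x)
}

#' @export
summary.pruneff_model <- function(object, ...) {
  out <- data.frame(
    name = vapply(object$net$layers, `[[`, "", "name"),
    kind = vapply(object$net$layers, `[[`, "", "kind"),
    parameters = vapply(object$net$layers, function(l)
      sum(vapply(l$params, length, 0L)) + sum(vapply(l$buffers, length, 0L)),
      0L),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("her2_model_summary", "data.frame")
  out
}

#' Save / load model weights
#'
#' Checkpoints are the model's named weight and batch-norm buffer lists,
#' written with `saveRDS`; an architecture JSON sidecar records the layer
#' names and kinds so a checkpoint can be audited without loading it.
#'
#' @param model A `her2_model` or `pruneff_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns the
#'   model with weights and buffers replaced.
#' @export
save_weights <- function(model, path) {
  saveRDS(list(weights = nn_get_weights(model$net),
               buffers = nn_get_buffers(model$net)), path)
  sidecar <- lapply(model$net$layers, function(l)
    list(kind = l$kind, n_params = sum(vapply(l$params, length, 0L))))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  ck <- readRDS(path)
  model$net <- nn_set_weights(model$net, ck$weights)
  model$net <- nn_set_buffers(model$net, ck$buffers)
  model
}
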