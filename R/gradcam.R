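# Grad-CAM: gradient-weighted class activation maps. The class score is
# backpropagated to a chosen convolutional layer's activation maps; each map
# is weighted by the spatial mean of its gradient, the weighted sum is
# rectified, upsampled bilinearly to the input resolution and min-max
# normalized. For sigmoid binary heads the class score is the pre-sigmoid
# logit (signed for the negative class) to avoid saturation; for softmax
# heads it is the class logit.

bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # align-corners sampling grid
  ry <- if (H == 1) rep(1, H) else seq(1, h, length.out = H)
  rx <- if (W == 1) rep(1, W) else seq(1, w, length.out = W)
  y0 <- pmin(floor(ry), h - 1); y0 <- pmax(y0, 1)
  x0 <- pmin(floor(rx), w - 1); x0 <- pmax(x0, 1)
  fy <- ry - y0; fx <- rx - x0
  if (h == 1) { y0 <- rep(1, H); fy <- rep(0, H) }
  if (w == 1) { x0 <- rep(1, W); fx <- rep(0, W) }
  a <- m[y0, x0, drop = FALSE]; b <- m[pmin(y0 + 1, h), x0, drop = FALSE]
  c_ <- m[y0, pmin(x0 + 1, w), drop = FALSE]
  d <- m[pmin(y0 + 1, h), pmin(x0 + 1, w), drop = FALSE]
  fyM <- matrix(fy, H, W); fxM <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - fyM) * (1 - fxM) + b * fyM * (1 - fxM) +
    c_ * (1 - fyM) * fxM + d * fyM * fxM
}

#' Grad-CAM heatmap
#'
#' @param object A `her2_model`, `pruneff_model` or `her2_fit`.
#' @param image An `(H, W, 3)` image matching the model input.
#' @param target_layer Name of a convolutional layer of the model (e.g.
#'   `"L-4"` for ATHER2, `"block4c_project_conv"` for PrunEff).
#' @param target_class 0-based class index; defaults to the predicted class.
#' @return A `gradcam_heatmap`: `raw` (non-negative matrix at the layer's
#'   spatial resolution), `upsampled` (input-resolution matrix, min-max
#'   normalized to `[0, 1]`, all-zero if `raw` is), `target_layer`,
#'   `target_class`.
#' @export
gradcam <- function(object, image, target_layer, target_class = NULL) {
  model <- if (inherits(object, "her2_fit")) object$model else object
  net <- model$net
  l <- net$layers[[target_layer]]
  if (is.null(l)) stop("no layer named '", target_layer, "' in the model")
  if (!l$kind %in% c("conv", "dwconv"))
    stop("Grad-CAM requires a convolutional layer; '", target_layer,
         "' has kind '", l$kind, "'")
  x <- as_batch(image, model$input_size)
  f <- nn_forward(net, x, training = FALSE)
  z <- f$out                                  # (U, 1)
  binary <- model$out_activation == "sigmoid"
  if (is.null(target_class)) {
    target_class <- if (binary) as.integer(z[1, 1] >= 0)
                    else which.max(z[, 1]) - 1L
  }
  dout <- matrix(0, nrow(z), ncol(z))
  if (binary) {
    if (!target_class %in% 0:1) stop("binary model: target_class must be 0 or 1")
    dout[1, 1] <- if (target_class == 1) 1 else -1
  } else {
    if (target_class < 0 || target_class >= nrow(z))
      stop("target_class out of range")
    dout[target_class + 1L, 1] <- 1
  }
  bk <- nn_backward(net, f, dout)
  A <- f$acts[[target_layer]]                 # (h, w, K, 1)
  G <- bk$dacts[[target_layer]]
  if (is.null(G)) stop("no gradient reaches layer '", target_layer,
                       "': not on a differentiable path to the output")
  d <- dim(A)
  alpha <- colMeans(matrix(G, d[1] * d[2], d[3]))  # GAP of the gradients
  raw <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  raw <- pmax(raw, 0)
  up <- bilinear_resize(raw, dim(x)[1], dim(x)[2])
  if (max(up) > 0) up <- (up - min(up)) / (max(up) - min(up))
  structure(list(raw = raw, upsampled = up, target_layer = target_layer,
                 target_class = as.integer(target_class)),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap: layer %s, class %d, raw %dx%d -> %dx%d\n",
              x$target_layer, x$target_class, nrow(x$raw), ncol(x$raw),
              nrow(x$upsampled), ncol(x$upsampled)))
  invisible(x)
}

# blue-green-yellow-red colormap lookup for a [0,1] matrix
heat_colormap <- function(m) {
  pal <- grDevices::colorRampPalette(
    c("#00007F", "#0000FF", "#00FFFF", "#7FFF00", "#FFFF00", "#FF0000"))(256)
  rgbm <- grDevices::col2rgb(pal) / 255
  i <- pmin(pmax(floor(m * 255) + 1, 1), 256)
  out <- array(0, c(nrow(m), ncol(m), 3))
  for (k in 1:3) out[, , k] <- matrix(rgbm[k, i], nrow(m), ncol(m))
  out
}

#' Overlay a Grad-CAM heatmap on its input image
#'
#' Alpha-blends a colormap rendering of the normalized heatmap over the
#' image: `alpha = 0` returns the image, `alpha = 1` the pure colormap.
#' Deterministic for fixed inputs.
#'
#' @param heatmap A [gradcam()] result.
#' @param image The `(H, W, 3)` input image.
#' @param alpha Blend weight in `[0, 1]`.
#' @param path Optional PNG output path.
#' @return The blended `(H, W, 3)` array (invisibly when `path` is given).
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.4, path = NULL) {
  if (length(dim(image)) != 3)
    stop("image must be (H, W, 3)")
  if (!all(dim(image)[1:2] == dim(heatmap$upsampled)))
    stop("image and upsampled heatmap dimensions differ")
  cm <- heat_colormap(heatmap$upsampled)
  out <- (1 - alpha) * image + alpha * cm
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Localization score of a heatmap against a ground-truth mask
#'
#' The fraction of total heatmap mass falling inside the mask, and the
#' enrichment of that fraction over the mask's area fraction (enrichment 1 =
#' no better than a uniform map; 2 = twice the mass density inside the mask).
#'
#' @param heatmap A [gradcam()] result.
#' @param mask Binary matrix with the dimensions of the upsampled heatmap and
#'   at least one positive pixel.
#' @return A list with `score` in `[0, 1]` and `enrichment`.
#' @export
localization_score <- function(heatmap, mask) {
  up <- heatmap$upsampled
  if (!all(dim(mask) == dim(up)))
    stop("mask dimensions must match the upsampled heatmap")
  if (sum(mask > 0) == 0) stop("mask has no positive pixels")
  total <- sum(up)
  score <- if (total == 0) 0 else sum(up[mask > 0]) / total
  area <- sum(mask > 0) / length(mask)
  list(score = score, enrichment = score / area)
}
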