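#' Convolutional block attention module (CBAM) configuration
#'
#' CBAM refines a feature map in two sequential stages: channel attention
#' (a shared two-layer MLP applied to the spatially average- and max-pooled
#' channel descriptors, summed and squashed by a sigmoid) followed by spatial
#' attention (a single convolution over the stacked channel-wise mean and max
#' maps, squashed by a sigmoid). The defaults are the canonical CBAM choices.
#'
#' @param reduction_ratio Positive integer; the channel MLP bottleneck divisor.
#'   `channels %/% reduction_ratio` must be at least 1 for the feature map the
#'   module is applied to.
#' @param spatial_kernel Odd positive integer; side of the spatial-attention
#'   convolution kernel.
#' @param mlp_bias Logical; include bias terms in the channel MLP.
#' @return An object of class `cbam_config`.
#' @export
#' @examples
#' cbam_config()
#' cbam_config(reduction_ratio = 8, spatial_kernel = 3)
cbam_config <- function(reduction_ratio = 16L, spatial_kernel = 7L,
                        mlp_bias = TRUE) {
  check_positive_int(reduction_ratio, "reduction_ratio")
  check_positive_int(spatial_kernel, "spatial_kernel")
  if (spatial_kernel %% 2 == 0)
    stop("spatial_kernel must be odd, got ", spatial_kernel)
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 mlp_bias = isTRUE(mlp_bias)),
            class = "cbam_config")
}

#' @export
print.cbam_config <- function(x, ...) {
  cat("CBAM config: reduction_ratio =", x$reduction_ratio,
      "| spatial_kernel =", x$spatial_kernel,
      "| mlp_bias =", x$mlp_bias, "\n")
  invisible(x)
}

#' Read / write a CBAM configuration as YAML
#'
#' Serializes the keys `reduction_ratio`, `spatial_kernel` and `mlp_bias`.
#'
#' @param cfg A [cbam_config()].
#' @param path YAML file path.
#' @export
write_cbam_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_cbam_config
#' @export
read_cbam_config <- function(path) do.call(cbam_config, yaml::read_yaml(path))

#' Initialize standalone CBAM parameters
#'
#' Creates the weight set for applying CBAM to a feature map with a given
#' channel count, for use with [channel_attention()], [spatial_attention()]
#' and [apply_cbam()]. Weights use seeded variance-scaling initialization; any
#' element may be overwritten to evaluate the module with hand-set weights.
#'
#' @param channels Number of channels of the target feature map.
#' @param cfg A [cbam_config()].
#' @param seed Integer seed for the initial weights.
#' @return A named list with elements `w1`, `b1`, `w2`, `b2` (channel MLP) and
#'   `ws`, `bs` (spatial convolution).
#' @export
cbam_params <- function(channels, cfg = cbam_config(), seed = 1L) {
  l <- layer_cbam("cbam", "x", channels, cfg)
  net <- nn_init(nn_graph(list(layer_input("x"), l), NULL), seed)
  net$layers[["cbam"]]$params
}

as_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3)
    stop("feature map must be a rank-3 array (height x width x channels)")
  if (any(dim(f) < 1)) stop("all feature-map dimensions must be >= 1")
  array(f, c(dim(f), 1))
}

#' Channel attention weights
#'
#' Computes the per-channel attention vector: sigmoid of the summed shared-MLP
#' responses to the spatially average-pooled and max-pooled channel
#' descriptors. All weights lie strictly in (0, 1).
#'
#' @param f Rank-3 numeric array (height x width x channels).
#' @param params CBAM parameters from [cbam_params()].
#' @param cfg A [cbam_config()].
#' @return Numeric vector of length `channels` with values in (0, 1).
#' @export
channel_attention <- function(f, params, cfg = cbam_config()) {
  x <- as_feature_map(f)
  C <- dim(x)[3]
  if (cfg$reduction_ratio > C)
    stop("invalid CBAM config: reduction_ratio (", cfg$reduction_ratio,
         ") exceeds channel count (", C, ")")
  cs <- cbam_channel_stats(x)
  fa <- cbam_mlp(params, cs$avg, cfg$mlp_bias)
  fm <- cbam_mlp(params, cs$mx, cfg$mlp_bias)
  as.vector(1 / (1 + exp(-(fa$out + fm$out))))
}

#' Spatial attention map
#'
#' Computes the spatial attention map: sigmoid of a `spatial_kernel`
#' convolution (same padding, stride 1) over the stacked channel-wise mean and
#' max maps. Spatial dimensions are preserved.
#'
#' @inheritParams channel_attention
#' @return Numeric matrix (height x width) with values in (0, 1).
#' @export
spatial_attention <- function(f, params, cfg = cbam_config()) {
  x <- as_feature_map(f)
  sp <- cbam_spatial_stack(x)
  spre <- cpp_conv2d_fwd(sp$stack, params$ws, params$bs, 1L, TRUE)
  matrix(1 / (1 + exp(-spre)), dim(x)[1], dim(x)[2])
}

#' Apply CBAM to a feature map
#'
#' Refines the input by channel attention first, then spatial attention:
#' `f * channel_weights * spatial_map` with the obvious broadcasts. The output
#' has the same shape as the input and is element-wise no larger in magnitude
#' (attention weights are strictly below 1).
#'
#' @inheritParams channel_attention
#' @return Rank-3 array with the shape of `f`.
#' @export
apply_cbam <- function(f, params, cfg = cbam_config()) {
  x <- as_feature_map(f)
  cw <- channel_attention(f, params, cfg)
  d <- dim(x)
  y1 <- x * array(rep(cw, each = d[1] * d[2]), d)
  sm <- spatial_attention(array(y1[, , , 1], d[1:3]), params, cfg)
  y <- y1 * array(rep(as.vector(sm), d[3]), d)
  array(y, d[1:3])
}
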