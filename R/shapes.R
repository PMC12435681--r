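#' Spatial size of a "same"-padded convolution output
#'
#' Convolutions in ATHER2 use TensorFlow-style *same* padding, so the output
#' side length is `ceiling(in_size / stride)` regardless of the kernel. This
#' is the unique convention consistent with the network's published layer
#' table (e.g. a 3x3, stride-3 convolution maps 256 to 86).
#'
#' @param in_size Input side length (positive integer).
#' @param kernel Kernel side length (positive integer).
#' @param stride Stride (positive integer).
#' @return Output side length (integer).
#' @seealso [pool_output_size()]
#' @export
#' @examples
#' conv_output_size(256, 3, 3)  # 86
#' conv_output_size(254, 3, 2)  # 127
conv_output_size <- function(in_size, kernel, stride) {
  check_positive_int(in_size, "in_size")
  check_positive_int(kernel, "kernel")
  check_positive_int(stride, "stride")
  as.integer(ceiling(in_size / stride))
}

#' Spatial size of a "valid" pooling output
#'
#' Pooling layers use *valid* padding: `floor((in_size - kernel) / stride) + 1`.
#' Together with same-padded convolutions this reproduces the published
#' per-layer output sizes (e.g. a 3x3, stride-1 pool maps 256 to 254).
#'
#' @inheritParams conv_output_size
#' @return Output side length (integer).
#' @export
#' @examples
#' pool_output_size(256, 3, 1)  # 254
#' pool_output_size(86, 3, 2)   # 42
pool_output_size <- function(in_size, kernel, stride) {
  check_positive_int(in_size, "in_size")
  check_positive_int(kernel, "kernel")
  check_positive_int(stride, "stride")
  if (in_size < kernel)
    stop("pooling window (", kernel, ") larger than input (", in_size, ")")
  as.integer((in_size - kernel) %/% stride + 1L)
}

check_positive_int <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(what, " must be a positive integer, got ", deparse(substitute(x)))
  invisible(x)
}
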