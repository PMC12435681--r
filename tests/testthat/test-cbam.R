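# Oracles for the attention module: direct scalar re-implementations of the
# channel MLP and the spatial convolution, evaluated element by element.

mlp_oracle <- function(p, v, bias = TRUE) {
  h <- pmax(t(p$w1) %*% v + if (bias) p$b1 else 0, 0)
  as.vector(t(p$w2) %*% h + if (bias) p$b2 else 0)
}

conv_oracle <- function(stack, w, b) {
  # same-padded stride-1 convolution of an (H, W, 2) stack with a (k, k, 2, 1)
  # kernel, computed by quadruple loop
  H <- dim(stack)[1]; W <- dim(stack)[2]; k <- dim(w)[1]
  pad <- (k - 1) %/% 2
  out <- matrix(b, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    for (ki in seq_len(k)) for (kj in seq_len(k)) for (c in 1:2) {
      ii <- i + ki - 1 - pad; jj <- j + kj - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        out[i, j] <- out[i, j] + stack[ii, jj, c] * w[ki, kj, c, 1]
    }
  out
}

test_that("channel attention matches a scalar oracle on hand-set weights", {
  cfg <- cbam_config(reduction_ratio = 2, spatial_kernel = 3)
  p <- cbam_params(2, cfg, seed = 3)
  p$w1 <- matrix(c(0.5, -0.2), 2, 1)
  p$b1 <- 0.1
  p$w2 <- matrix(c(0.7, -0.4), 1, 2)
  p$b2 <- c(-0.1, 0.2)
  f <- array(c(1, 2, 3, 4, -1, 0.5, 2, -2), c(2, 2, 2))
  got <- channel_attention(f, p, cfg)
  avg <- apply(f, 3, mean); mx <- apply(f, 3, max)
  want <- 1 / (1 + exp(-(mlp_oracle(p, avg) + mlp_oracle(p, mx))))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))
})

test_that("constant feature maps make the two pooled branches coincide", {
  cfg <- cbam_config(reduction_ratio = 2, spatial_kernel = 3)
  p <- cbam_params(4, cfg, seed = 5)
  f <- array(0.7, c(3, 3, 4))
  got <- channel_attention(f, p, cfg)
  # avg-pool equals max-pool, so the pre-sigmoid logit is 2 * MLP(c)
  want <- 1 / (1 + exp(-2 * mlp_oracle(p, rep(0.7, 4))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("invalid reduction ratios are rejected", {
  expect_error(channel_attention(array(1, c(2, 2, 4)),
                                 cbam_params(4, cbam_config(4)),
                                 cbam_config(reduction_ratio = 8)),
               "reduction_ratio")
  expect_error(cbam_config(spatial_kernel = 4), "odd")
})

test_that("spatial attention matches a brute-force convolution oracle", {
  cfg <- cbam_config(reduction_ratio = 1, spatial_kernel = 3)
  set.seed(8)
  p <- cbam_params(2, cfg, seed = 8)
  p$ws <- array(rnorm(9 * 2), c(3, 3, 2, 1))
  p$bs <- 0.05
  f <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  got <- spatial_attention(f, p, cfg)
  stack <- array(0, c(3, 3, 2))
  stack[, , 1] <- apply(f, c(1, 2), mean)
  stack[, , 2] <- apply(f, c(1, 2), max)
  want <- 1 / (1 + exp(-conv_oracle(stack, p$ws, p$bs)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_identical(dim(got), dim(f)[1:2])
  expect_true(all(got > 0 & got < 1))
})

test_that("channel-constant inputs equalize the mean and max maps", {
  cfg <- cbam_config(reduction_ratio = 1, spatial_kernel = 7)
  p <- cbam_params(3, cfg, seed = 2)
  base <- matrix(runif(25), 5, 5)
  f <- array(rep(base, 3), c(5, 5, 3))   # identical across channels
  stack_mean <- apply(f, c(1, 2), mean)
  stack_max <- apply(f, c(1, 2), max)
  expect_equal(stack_mean, stack_max, tolerance = 1e-12)
  expect_identical(dim(spatial_attention(f, p, cfg)), c(5L, 5L))
})

test_that("apply_cbam composes channel-then-spatial and is bounded", {
  cfg <- cbam_config(reduction_ratio = 4, spatial_kernel = 3)
  set.seed(21)
  p <- cbam_params(8, cfg, seed = 21)
  f <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  got <- apply_cbam(f, p, cfg)
  # oracle: compose the two exported stages explicitly
  cw <- channel_attention(f, p, cfg)
  y1 <- f * array(rep(cw, each = 16), dim(f))
  sm <- spatial_attention(y1, p, cfg)
  want <- y1 * array(rep(as.vector(sm), 8), dim(f))
  expect_equal(got, want, tolerance = 1e-12)
  expect_identical(dim(got), dim(f))
  expect_true(all(abs(got) <= abs(f) + 1e-12))
  # zero input stays zero
  expect_equal(apply_cbam(array(0, c(4, 4, 8)), p, cfg),
               array(0, c(4, 4, 8)))
})

test_that("attention order matters: channel-first differs from spatial-first", {
  cfg <- cbam_config(reduction_ratio = 4, spatial_kernel = 3)
  set.seed(22)
  p <- cbam_params(8, cfg, seed = 22)
  f <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  channel_first <- apply_cbam(f, p, cfg)
  sm <- spatial_attention(f, p, cfg)
  y1 <- f * array(rep(as.vector(sm), 8), dim(f))
  cw <- channel_attention(y1, p, cfg)
  spatial_first <- y1 * array(rep(cw, each = 16), dim(f))
  expect_gt(max(abs(channel_first - spatial_first)), 1e-6)
})

test_that("saturating the attention logits recovers the identity", {
  cfg <- cbam_config(reduction_ratio = 2, spatial_kernel = 3)
  p <- cbam_params(4, cfg, seed = 1)
  p$b2 <- rep(50, 4)   # drive channel logits to +inf
  p$bs <- 50           # drive spatial logits to +inf
  f <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_equal(apply_cbam(f, p, cfg), f, tolerance = 1e-12)
})

test_that("the engine's CBAM layer equals the functional composition", {
  e <- asNamespace("her2lite")
  cfg <- cbam_config(reduction_ratio = 4, spatial_kernel = 7)
  l <- e$layer_cbam("att", "x", 8, cfg)
  net <- e$nn_init(e$nn_graph(list(e$layer_input("x"), l), NULL), 9)
  p <- net$layers[["att"]]$params
  set.seed(33)
  f <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  got <- e$nn_forward(net, array(f, c(6, 6, 8, 1)))$out
  expect_equal(array(got, c(6, 6, 8)), apply_cbam(f, p, cfg),
               tolerance = 1e-12)
})

test_that("CBAM configs round-trip through YAML", {
  cfg <- cbam_config(reduction_ratio = 8, spatial_kernel = 5, mlp_bias = FALSE)
  path <- tempfile(fileext = ".yaml")
  write_cbam_config(cfg, path)
  expect_equal(read_cbam_config(path), cfg)
})
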