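# Minimal seedable CNN runtime: a directed acyclic graph of named layers with
# forward, backward (reverse-mode) and Adam updates. Activations are stored as
# (H, W, C, N) arrays; fully connected features as (F, N) matrices. Heavy
# convolution/pooling kernels live in src/convops.cpp.

# ---- layer constructors -----------------------------------------------------

nn_layer <- function(name, kind, inputs, ...) {
  structure(list(name = name, kind = kind, inputs = inputs,
                 params = list(), buffers = list(), trainable = TRUE, ...),
            class = "nn_layer")
}

layer_input <- function(name = "input") nn_layer(name, "input", character())

layer_conv <- function(name, inputs, kernel, stride, filters, in_channels,
                       padding = c("same", "valid"), activation = "leaky_relu",
                       alpha = 0.3, use_bias = TRUE) {
  padding <- match.arg(padding)
  nn_layer(name, "conv", inputs, kernel = kernel, stride = stride,
           filters = filters, in_channels = in_channels, padding = padding,
           activation = activation, alpha = alpha, use_bias = use_bias)
}

layer_dwconv <- function(name, inputs, kernel, stride, channels,
                         padding = "same", activation = "linear", alpha = 0.3) {
  nn_layer(name, "dwconv", inputs, kernel = kernel, stride = stride,
           channels = channels, padding = padding, activation = activation,
           alpha = alpha)
}

layer_maxpool <- function(name, inputs, kernel, stride)
  nn_layer(name, "maxpool", inputs, kernel = kernel, stride = stride)

layer_batchnorm <- function(name, inputs, channels, momentum = 0.9,
                            eps = 1e-3)
  nn_layer(name, "batchnorm", inputs, channels = channels, momentum = momentum,
           eps = eps)

layer_dropout <- function(name, inputs, rate)
  nn_layer(name, "dropout", inputs, rate = rate)

layer_gap <- function(name, inputs) nn_layer(name, "gap", inputs)

layer_dense <- function(name, inputs, units, in_features,
                        activation = "leaky_relu", alpha = 0.3)
  nn_layer(name, "dense", inputs, units = units, in_features = in_features,
           activation = activation, alpha = alpha)

layer_concat <- function(name, inputs) nn_layer(name, "concat", inputs)

layer_add <- function(name, inputs) nn_layer(name, "add", inputs)

# multiply a feature map by a per-channel (C, N) gate (squeeze-excitation)
layer_scale_channels <- function(name, inputs) nn_layer(name, "scale", inputs)

layer_activation <- function(name, inputs, activation, alpha = 0.3)
  nn_layer(name, "activation", inputs, activation = activation, alpha = alpha)

layer_cbam <- function(name, inputs, channels, cfg) {
  hidden <- channels %/% cfg$reduction_ratio
  if (hidden < 1)
    stop("invalid CBAM config: reduction_ratio ", cfg$reduction_ratio,
         " leaves no hidden units for ", channels, " channels")
  nn_layer(name, "cbam", inputs, channels = channels, hidden = hidden,
           spatial_kernel = cfg$spatial_kernel, mlp_bias = isTRUE(cfg$mlp_bias))
}

# ---- graph ------------------------------------------------------------------

nn_graph <- function(layers, input_dim) {
  names(layers) <- vapply(layers, `[[`, "", "name")
  structure(list(layers = layers, input_dim = input_dim,
                 output = layers[[length(layers)]]$name),
            class = "nn_graph")
}

# variance-scaling (fan-in) initialization, fully determined by `seed`
nn_init <- function(net, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vs <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    l$params <- switch(l$kind,
      conv = {
        p <- list(w = vs(c(l$kernel, l$kernel, l$in_channels, l$filters),
                         l$kernel^2 * l$in_channels))
        if (l$use_bias) p$b <- numeric(l$filters)
        p
      },
      dwconv = list(w = vs(c(l$kernel, l$kernel, l$channels), l$kernel^2),
                    b = numeric(l$channels)),
      dense = list(w = vs(c(l$in_features, l$units), l$in_features),
                   b = numeric(l$units)),
      batchnorm = list(gamma = rep(1, l$channels), beta = numeric(l$channels)),
      cbam = {
        sk <- l$spatial_kernel
        list(w1 = vs(c(l$channels, l$hidden), l$channels),
             b1 = numeric(l$hidden),
             w2 = vs(c(l$hidden, l$channels), l$hidden),
             b2 = numeric(l$channels),
             ws = vs(c(sk, sk, 2, 1), sk^2 * 2),
             bs = numeric(1))
      },
      list())
    if (l$kind == "batchnorm")
      l$buffers <- list(mean = numeric(l$channels), var = rep(1, l$channels))
    net$layers[[i]] <- l
  }
  net
}

act_fwd <- function(z, type, alpha = 0.3) {
  switch(type,
         linear = z,
         relu = pmax(z, 0),
         leaky_relu = ifelse(z > 0, z, alpha * z),
         sigmoid = 1 / (1 + exp(-z)),
         swish = z / (1 + exp(-z)),
         stop("unknown activation: ", type))
}

act_bwd <- function(da, z, type, alpha = 0.3) {
  switch(type,
         linear = da,
         relu = da * (z > 0),
         leaky_relu = da * ifelse(z > 0, 1, alpha),
         sigmoid = { s <- 1 / (1 + exp(-z)); da * s * (1 - s) },
         swish = { s <- 1 / (1 + exp(-z)); da * (s * (1 + z * (1 - s))) },
         stop("unknown activation: ", type))
}

keep_dim <- function(x, d) { dim(x) <- d; x }

# per-channel statistics helpers on (H, W, C, N) arrays
chan_matrix <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3] * d[4])  # columns ordered c fastest, then n
}

# ---- forward ----------------------------------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  acts <- list(); extra <- list()
  for (l in net$layers) {
    if (l$kind == "input") { acts[[l$name]] <- x; next }
    inp <- lapply(l$inputs, function(nm) acts[[nm]])
    r <- layer_fwd(l, inp, training)
    acts[[l$name]] <- r$y
    if (!is.null(r$cache)) extra[[l$name]] <- r$cache
  }
  list(out = acts[[net$output]], acts = acts, extra = extra,
       training = training)
}

layer_fwd <- function(l, inp, training) {
  switch(l$kind,
    conv = {
      z <- cpp_conv2d_fwd(inp[[1]], l$params$w,
                          if (l$use_bias) l$params$b else numeric(l$filters),
                          l$stride, l$padding == "same")
      list(y = keep_dim(act_fwd(z, l$activation, l$alpha), dim(z)),
           cache = list(z = z))
    },
    dwconv = {
      z <- cpp_dwconv2d_fwd(inp[[1]], l$params$w, l$params$b, l$stride,
                            l$padding == "same")
      list(y = keep_dim(act_fwd(z, l$activation, l$alpha), dim(z)),
           cache = list(z = z))
    },
    maxpool = {
      r <- cpp_maxpool_fwd(inp[[1]], l$kernel, l$stride)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(inp[[1]])))
    },
    batchnorm = bn_fwd(l, inp[[1]], training),
    dropout = {
      x <- inp[[1]]
      if (training && l$rate > 0) {
        mask <- array((stats::runif(length(x)) >= l$rate) / (1 - l$rate), dim(x))
        list(y = x * mask, cache = list(mask = mask))
      } else list(y = x)
    },
    gap = {
      d <- dim(inp[[1]])
      cm <- colMeans(chan_matrix(inp[[1]]))
      list(y = matrix(cm, d[3], d[4]), cache = list(xdim = d))
    },
    dense = {
      z <- crossprod(l$params$w, inp[[1]]) + l$params$b
      list(y = act_fwd(z, l$activation, l$alpha), cache = list(z = z))
    },
    concat = {
      sizes <- vapply(inp, nrow, 0L)
      list(y = do.call(rbind, inp), cache = list(sizes = sizes))
    },
    add = list(y = inp[[1]] + inp[[2]]),
    scale = {
      x <- inp[[1]]; s <- inp[[2]]  # s is (C, N)
      d <- dim(x)
      sb <- array(rep(as.vector(s), each = d[1] * d[2]), d)
      list(y = x * sb, cache = list(sb = sb))
    },
    activation = {
      z <- inp[[1]]
      list(y = keep_dim(act_fwd(z, l$activation, l$alpha), dim(z)),
           cache = list(z = z))
    },
    cbam = cbam_fwd(l, inp[[1]]),
    stop("unknown layer kind: ", l$kind))
}

bn_fwd <- function(l, x, training) {
  d <- dim(x); eps <- l$eps
  xm <- chan_matrix(x)
  if (training) {
    cm <- matrix(colMeans(xm), d[3], d[4])
    mu <- rowMeans(cm)
    cm2 <- matrix(colMeans(xm^2), d[3], d[4])
    v <- rowMeans(cm2) - mu^2
  } else {
    mu <- l$buffers$mean; v <- l$buffers$var
  }
  ivar <- 1 / sqrt(v + eps)
  sc <- rep(l$params$gamma * ivar, d[4])
  sh <- rep(l$params$beta - l$params$gamma * ivar * mu, d[4])
  y <- keep_dim(sweep(sweep(xm, 2, sc, "*"), 2, sh, "+"), d)
  list(y = y, cache = list(mu = mu, v = v, ivar = ivar, training = training))
}

# ---- CBAM: channel attention then spatial attention -------------------------

cbam_channel_stats <- function(x) {
  d <- dim(x)
  xm <- chan_matrix(x)
  avg <- matrix(colMeans(xm), d[3], d[4])
  mxi <- apply(xm, 2, which.max)
  mx <- matrix(xm[cbind(mxi, seq_len(ncol(xm)))], d[3], d[4])
  list(avg = avg, mx = mx, mxi = mxi)
}

cbam_mlp <- function(p, v, use_bias) {
  hpre <- crossprod(p$w1, v)
  if (use_bias) hpre <- hpre + p$b1
  h <- pmax(hpre, 0)
  out <- crossprod(p$w2, h)
  if (use_bias) out <- out + p$b2
  list(out = out, hpre = hpre, h = h)
}

# channel-wise mean/max maps stacked as a 2-channel image, per sample
cbam_spatial_stack <- function(y1) {
  d <- dim(y1)
  st <- array(0, c(d[1], d[2], 2, d[4]))
  mmidx <- array(1L, c(d[1] * d[2], d[4]))
  hw <- d[1] * d[2]
  ym <- matrix(y1, hw, d[3] * d[4])
  for (n in seq_len(d[4])) {
    block <- ym[, (n - 1) * d[3] + seq_len(d[3]), drop = FALSE]
    st[, , 1, n] <- rowMeans(block)
    mm <- block[, 1]; mi <- rep(1L, hw)
    for (c in seq_len(d[3])[-1]) {
      upd <- block[, c] > mm
      mm[upd] <- block[upd, c]; mi[upd] <- c
    }
    st[, , 2, n] <- mm
    mmidx[, n] <- mi
  }
  list(stack = st, mmidx = mmidx)
}

cbam_fwd <- function(l, x) {
  d <- dim(x)
  p <- l$params; ub <- l$mlp_bias
  cs <- cbam_channel_stats(x)
  fa <- cbam_mlp(p, cs$avg, ub)
  fm <- cbam_mlp(p, cs$mx, ub)
  logit <- fa$out + fm$out
  cw <- 1 / (1 + exp(-logit))                       # (C, N)
  cwb <- array(rep(as.vector(cw), each = d[1] * d[2]), d)
  y1 <- x * cwb
  sp <- cbam_spatial_stack(y1)
  spre <- cpp_conv2d_fwd(sp$stack, p$ws, p$bs, 1L, TRUE)
  s <- 1 / (1 + exp(-spre))                         # (H, W, 1, N)
  sfull <- array(apply(s, 4, function(m) rep(as.vector(m), d[3])), d)
  y <- y1 * sfull
  list(y = y,
       cache = list(cs = cs, fa = fa, fm = fm, cw = cw, cwb = cwb, y1 = y1,
                    stack = sp$stack, mmidx = sp$mmidx, spre = spre, s = s,
                    sfull = sfull, x = x))
}

cbam_bwd <- function(l, cache, dy) {
  d <- dim(cache$x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  p <- l$params; ub <- l$mlp_bias
  # spatial gate
  dy1 <- dy * cache$sfull
  ds <- array(0, c(d[1], d[2], 1, N))
  prod_m <- matrix(dy * cache$y1, hw, C * N)
  for (n in seq_len(N))
    ds[, , 1, n] <- rowSums(prod_m[, (n - 1) * C + seq_len(C), drop = FALSE])
  dspre <- ds * cache$s * (1 - cache$s)
  cb <- cpp_conv2d_bwd(cache$stack, p$ws, dspre, 1L, TRUE)
  dstack <- cb$dx
  dam <- dstack[, , 1, , drop = FALSE]
  dmm <- dstack[, , 2, , drop = FALSE]
  dy1 <- dy1 + array(apply(dam, 4, function(m) rep(as.vector(m) / C, C)), d)
  # scatter channel-max gradient to argmax channels
  dmm_m <- matrix(dmm, hw, N)
  dy1_m <- matrix(dy1, hw, C * N)
  for (n in seq_len(N)) {
    cols <- (n - 1) * C + cache$mmidx[, n]
    ii <- cbind(seq_len(hw), cols)
    dy1_m[ii] <- dy1_m[ii] + dmm_m[, n]
  }
  dy1 <- keep_dim(dy1_m, d)
  # channel gate
  xm <- matrix(cache$x, hw, C * N)
  dcw <- matrix(colSums(matrix(dy1, hw, C * N) * xm), C, N)
  dx <- dy1 * cache$cwb
  dlogit <- dcw * cache$cw * (1 - cache$cw)
  g <- list(w1 = 0 * p$w1, b1 = 0 * p$b1, w2 = 0 * p$w2, b2 = 0 * p$b2,
            ws = cb$dw, bs = cb$db)
  mlp_back <- function(br, v, dlog) {
    g$w2 <<- g$w2 + br$h %*% t(dlog)
    if (ub) g$b2 <<- g$b2 + rowSums(dlog)
    dh <- p$w2 %*% dlog
    dhpre <- dh * (br$hpre > 0)
    g$w1 <<- g$w1 + v %*% t(dhpre)
    if (ub) g$b1 <<- g$b1 + rowSums(dhpre)
    p$w1 %*% dhpre                                   # (C, N)
  }
  davg <- mlp_back(cache$fa, cache$cs$avg, dlogit)
  dmx <- mlp_back(cache$fm, cache$cs$mx, dlogit)
  # d avg: spread uniformly; d max: scatter to spatial argmax
  dx_m <- matrix(dx, hw, C * N)
  dx_m <- dx_m + matrix(rep(as.vector(davg) / hw, each = hw), hw, C * N)
  cols <- seq_len(C * N)
  ii <- cbind(cache$cs$mxi, cols)
  dx_m[ii] <- dx_m[ii] + as.vector(dmx)
  list(dx = keep_dim(dx_m, d), grads = g)
}

# ---- backward ---------------------------------------------------------------

nn_backward <- function(net, fwd, dout) {
  dacts <- list(); pgrads <- list()
  dacts[[net$output]] <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    dy <- dacts[[l$name]]
    if (is.null(dy) || l$kind == "input") next
    cache <- fwd$extra[[l$name]]
    inp <- lapply(l$inputs, function(nm) fwd$acts[[nm]])
    r <- layer_bwd(l, inp, cache, dy, fwd$training)
    if (!is.null(r$grads)) pgrads[[l$name]] <- r$grads
    for (j in seq_along(l$inputs)) {
      nm <- l$inputs[[j]]
      dacts[[nm]] <- if (is.null(dacts[[nm]])) r$dx[[j]] else dacts[[nm]] + r$dx[[j]]
    }
  }
  list(pgrads = pgrads, dacts = dacts)
}

layer_bwd <- function(l, inp, cache, dy, training) {
  switch(l$kind,
    conv = {
      dz <- keep_dim(act_bwd(dy, cache$z, l$activation, l$alpha), dim(dy))
      r <- cpp_conv2d_bwd(inp[[1]], l$params$w, dz, l$stride,
                          l$padding == "same")
      g <- list(w = r$dw)
      if (l$use_bias) g$b <- r$db
      list(dx = list(r$dx), grads = g)
    },
    dwconv = {
      dz <- keep_dim(act_bwd(dy, cache$z, l$activation, l$alpha), dim(dy))
      r <- cpp_dwconv2d_bwd(inp[[1]], l$params$w, dz, l$stride,
                            l$padding == "same")
      list(dx = list(r$dx), grads = list(w = r$dw, b = r$db))
    },
    maxpool = list(dx = list(cpp_maxpool_bwd(cache$xdim, cache$idx, dy))),
    batchnorm = bn_bwd(l, inp[[1]], cache, dy),
    dropout = list(dx = list(if (training && l$rate > 0) dy * cache$mask else dy)),
    gap = {
      d <- cache$xdim
      list(dx = list(array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)))
    },
    dense = {
      dz <- act_bwd(dy, cache$z, l$activation, l$alpha)
      list(dx = list(l$params$w %*% dz),
           grads = list(w = inp[[1]] %*% t(dz), b = rowSums(dz)))
    },
    concat = {
      ends <- cumsum(cache$sizes)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      list(dx = lapply(seq_along(cache$sizes),
                       function(j) dy[starts[j]:ends[j], , drop = FALSE]))
    },
    add = list(dx = list(dy, dy)),
    scale = {
      x <- inp[[1]]; d <- dim(x)
      dsm <- matrix(colSums(matrix(dy * x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      list(dx = list(dy * cache$sb, dsm))
    },
    activation = list(dx = list(keep_dim(act_bwd(dy, cache$z, l$activation, l$alpha),
                                         dim(dy)))),
    cbam = {
      r <- cbam_bwd(l, cache, dy)
      list(dx = list(r$dx), grads = r$grads)
    },
    stop("no backward for layer kind: ", l$kind))
}

bn_bwd <- function(l, x, cache, dy) {
  d <- dim(x); m <- d[1] * d[2] * d[4]
  xm <- chan_matrix(x); dym <- chan_matrix(dy)
  per_chan <- function(mat) rowSums(matrix(colSums(mat), d[3], d[4]))
  mu <- cache$mu; ivar <- cache$ivar
  xc <- sweep(xm, 2, rep(mu, d[4]), "-")
  xhat <- sweep(xc, 2, rep(ivar, d[4]), "*")
  dgamma <- per_chan(dym * xhat)
  dbeta <- per_chan(dym)
  dxhat <- sweep(dym, 2, rep(l$params$gamma, d[4]), "*")
  if (!isTRUE(cache$training)) {
    dx <- sweep(dxhat, 2, rep(ivar, d[4]), "*")
    return(list(dx = list(keep_dim(dx, d)),
                grads = list(gamma = dgamma, beta = dbeta)))
  }
  dvar <- per_chan(dxhat * xc) * (-0.5) * (ivar^3)
  dmu <- per_chan(dxhat) * (-ivar) + dvar * per_chan(-2 * xc) / m
  dx <- sweep(dxhat, 2, rep(ivar, d[4]), "*") +
    sweep(xc, 2, rep(2 * dvar / m, d[4]), "*") +
    matrix(rep(rep(dmu / m, d[4]), each = d[1] * d[2]), d[1] * d[2], d[3] * d[4])
  list(dx = list(keep_dim(dx, d)), grads = list(gamma = dgamma, beta = dbeta))
}

# update batch-norm moving statistics after a training-mode forward pass;
# `momentum` overrides the layer momentum (the trainer passes (i-1)/i for a
# running within-epoch average, which adapts immediately at small batch
# counts where a long EMA would lag the weights)
nn_update_bn <- function(net, fwd, momentum = NULL) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$kind != "batchnorm") next
    cache <- fwd$extra[[l$name]]
    if (is.null(cache) || !isTRUE(cache$training)) next
    mom <- momentum %||% l$momentum
    net$layers[[i]]$buffers$mean <- mom * l$buffers$mean + (1 - mom) * cache$mu
    net$layers[[i]]$buffers$var <- mom * l$buffers$var + (1 - mom) * cache$v
  }
  net
}

# ---- losses -----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# logits (U, N); y integer class ids in 0..K-1 (binary: 0/1, U == 1)
nn_loss <- function(logits, y, binary) {
  n <- ncol(logits)
  if (binary) {
    p <- 1 / (1 + exp(-logits[1, ]))
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    dz <- matrix((p - y) / n, 1, n)
    pred <- as.integer(p >= 0.5)
  } else {
    p <- softmax_cols(logits)
    idx <- cbind(y + 1L, seq_len(n))
    loss <- -mean(log(p[idx] + 1e-12))
    dz <- p
    dz[idx] <- dz[idx] - 1
    dz <- dz / n
    pred <- max.col(t(p)) - 1L
  }
  list(loss = loss, dz = dz, pred = pred)
}

# ---- parameters, freezing, Adam ---------------------------------------------

weighted_layer_names <- function(net) {
  nm <- vapply(net$layers, function(l)
    if (length(l$params) > 0) l$name else NA_character_, "")
  unname(nm[!is.na(nm)])
}

nn_get_weights <- function(net) lapply(net$layers, `[[`, "params")

nn_set_weights <- function(net, ws) {
  for (nm in names(ws))
    if (length(ws[[nm]])) net$layers[[nm]]$params <- ws[[nm]]
  net
}

nn_get_buffers <- function(net) lapply(net$layers, `[[`, "buffers")

nn_set_buffers <- function(net, bs) {
  for (nm in names(bs))
    if (length(bs[[nm]])) net$layers[[nm]]$buffers <- bs[[nm]]
  net
}

adam_init <- function(net) {
  st <- list(t = 0, m = list(), v = list())
  for (l in net$layers)
    if (length(l$params)) {
      st$m[[l$name]] <- lapply(l$params, function(p) p * 0)
      st$v[[l$name]] <- lapply(l$params, function(p) p * 0)
    }
  st
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7, weight_decay = 1e-4) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    l <- net$layers[[nm]]
    if (!isTRUE(l$trainable)) next
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      # L2 penalty on kernels only (not biases / batch-norm parameters)
      if (pn %in% c("w", "w1", "w2", "ws") && weight_decay > 0)
        g <- g + 2 * weight_decay * l$params[[pn]]
      m <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g^2
      state$m[[nm]][[pn]] <- m
      state$v[[nm]][[pn]] <- v
      net$layers[[nm]]$params[[pn]] <- l$params[[pn]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(net = net, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
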