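#' Sinogram-domain residual U-net
#'
#' Builds the encoder-decoder network that restores complete sinograms from
#' corrupted ones. The full-size configuration -- input 720 x 731, 64 base
#' channels, depth 4 -- has 27 layers: an input layer, three 3x3
#' convolutions, four encoder stages (a 2x2 stride-2 down-sampling
#' convolution that doubles the channels, then a 3x3 convolution), four
#' decoder stages (a 3x3 stride-2 transposed convolution that halves the
#' channels, concatenation with the matching encoder map, and two 3x3
#' convolutions), a final 1-channel 3x3 convolution, a residual addition of
#' the network input, and a whole-map normalization. Odd spatial sizes are
#' ceil-halved on the way down (731 -> 366 -> 183 -> 92 -> 46) and restored
#' exactly by the paired transposed convolution.
#'
#' Every convolution except the final 1-channel one is followed by batch
#' normalization and a ReLU; with batch size 1 the batch statistics reduce to
#' per-feature-map statistics, which is this framework's operating
#' condition. Down-sampling is a trainable strided convolution by default;
#' `max_pool` / `mean_pool` variants replace it by the fixed 2x2 pooling
#' followed by a 1x1 convolution that doubles the channels (so all layer
#' shapes are unchanged).
#'
#' @param input_shape Integer pair `(height, width)` of the sinogram grid.
#' @param base_channels Channels of the first encoder stage (64 full-size).
#' @param depth Number of down-samplings (4 full-size).
#' @param pooling_mode One of `"strided_conv"`, `"max_pool"`, `"mean_pool"`.
#' @return An object of class `sino_unet` (weights unset until
#'   [initialize_parameters()] is called).
#' @examples
#' net <- build_unet(c(64, 64), base_channels = 8, depth = 1)
#' layer_spec(net)
#' @export
build_unet <- function(input_shape, base_channels = 64, depth = 4,
                       pooling_mode = c("strided_conv", "max_pool",
                                        "mean_pool")) {
  pooling_mode <- match.arg(pooling_mode)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  if (base_channels < 1) stop("base_channels must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (H < 2^depth || W < 2^depth)
    stop("input spatial size too small for depth ", depth)
  ceil2 <- function(n) (n + 1L) %/% 2L
  hs <- Reduce(function(h, l) ceil2(h), seq_len(depth), accumulate = TRUE,
               init = H)
  ws <- Reduce(function(w, l) ceil2(w), seq_len(depth), accumulate = TRUE,
               init = W)
  ch <- base_channels * 2^(0:depth)

  nodes <- list()
  add_node <- function(kind, in_nodes, out_shape, ...) {
    idx <- length(nodes) + 1L
    nodes[[idx]] <<- c(list(idx = idx, kind = kind,
                            in_nodes = as.integer(in_nodes),
                            out_shape = as.integer(out_shape)), list(...))
    idx
  }
  conv_node <- function(from, cin, cout, h, w, bn = TRUE, act = "relu") {
    add_node("conv", from, c(h, w, cout), kernel = c(3L, 3L),
             stride = c(1L, 1L), cin = cin, cout = cout, bn = bn, act = act)
  }

  inp <- add_node("input", integer(0), c(H, W, 1L))
  cur <- conv_node(inp, 1L, ch[1], H, W)
  cur <- conv_node(cur, ch[1], ch[1], H, W)
  cur <- conv_node(cur, ch[1], ch[1], H, W)
  skips <- integer(depth)          # skips[l] = encoder map at level l-1
  skips[1] <- cur
  for (l in seq_len(depth)) {
    cur <- add_node("down", cur, c(hs[l + 1], ws[l + 1], ch[l + 1]),
                    kernel = c(2L, 2L), stride = c(2L, 2L),
                    cin = ch[l], cout = ch[l + 1], bn = TRUE, act = "relu",
                    pool_mode = pooling_mode)
    cur <- conv_node(cur, ch[l + 1], ch[l + 1], hs[l + 1], ws[l + 1])
    if (l < depth) skips[l + 1] <- cur
  }
  for (l in rev(seq_len(depth))) {
    cur <- add_node("convt", cur, c(hs[l], ws[l], ch[l]),
                    kernel = c(3L, 3L), stride = c(2L, 2L),
                    cin = ch[l + 1], cout = ch[l], bn = TRUE, act = "relu")
    cur <- conv_node(c(cur, skips[l]), 2L * ch[l], ch[l], hs[l], ws[l])
    cur <- conv_node(cur, ch[l], ch[l], hs[l], ws[l])
  }
  cur <- conv_node(cur, ch[1], 1L, H, W, bn = FALSE, act = "linear")
  cur <- add_node("add", c(cur, inp), c(H, W, 1L))
  add_node("norm", cur, c(H, W, 1L))

  structure(list(nodes = nodes, input_shape = c(H, W),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), pooling_mode = pooling_mode,
                 params = NULL),
            class = "sino_unet")
}

#' @export
print.sino_unet <- function(x, ...) {
  cat(sprintf(
    "sino_unet: %d layers, input %d x %d, base %d channels, depth %d, %s%s\n",
    length(x$nodes), x$input_shape[1], x$input_shape[2], x$base_channels,
    x$depth, x$pooling_mode,
    if (is.null(x$params)) " (uninitialized)" else ""))
  invisible(x)
}

#' Per-layer shape table
#'
#' One row per layer with input/output shapes, stride and kernel, in the
#' layout of the published full-size parameter table. Channel counts of
#' concatenating layers are reported as totals (e.g. 512 + 512 = 1024).
#'
#' @param net A `sino_unet`.
#' @return A data frame with one row per layer.
#' @export
layer_spec <- function(net) {
  rows <- lapply(net$nodes, function(nd) {
    if (nd$kind == "input") {
      inshape <- nd$out_shape
    } else {
      first <- net$nodes[[nd$in_nodes[1]]]$out_shape
      cin <- sum(vapply(nd$in_nodes,
                        function(j) net$nodes[[j]]$out_shape[3], integer(1)))
      inshape <- c(first[1], first[2], cin)
    }
    kindlab <- switch(nd$kind, input = "Input", conv = "Conv",
                      down = "Conv", convt = "ConvTranspose",
                      add = "Add", norm = "Norm")
    data.frame(index = nd$idx, kind = kindlab,
               in_h = inshape[1], in_w = inshape[2], in_c = inshape[3],
               out_h = nd$out_shape[1], out_w = nd$out_shape[2],
               out_c = nd$out_shape[3],
               stride_h = if (is.null(nd$stride)) NA_integer_ else nd$stride[1],
               stride_w = if (is.null(nd$stride)) NA_integer_ else nd$stride[2],
               kernel_h = if (is.null(nd$kernel)) NA_integer_ else nd$kernel[1],
               kernel_w = if (is.null(nd$kernel)) NA_integer_ else nd$kernel[2])
  })
  do.call(rbind, rows)
}

#' Gaussian parameter initialization
#'
#' Draws every weight from a zero-mean Gaussian with standard deviation
#' `sqrt(2 / (n_in + n_out))`, where `n_in` and `n_out` count the input and
#' output units of the layer (`kernel_area * channels`). Biases start at
#' zero, batch-normalization scales at one and shifts at zero. Deterministic
#' under `seed`.
#'
#' @param net A `sino_unet`.
#' @param seed Integer seed.
#' @return The network with `params` filled in.
#' @export
initialize_parameters <- function(net, seed) {
  params <- vector("list", length(net$nodes))
  withr::with_seed(as.integer(seed), {
    for (nd in net$nodes) {
      if (!nd$kind %in% c("conv", "down", "convt")) next
      pooled <- nd$kind == "down" && nd$pool_mode != "strided_conv"
      kdim <- if (pooled) c(1L, 1L) else nd$kernel
      wdim <- if (nd$kind == "convt") {
        c(kdim, nd$cout, nd$cin)      # kernel of the adjoint convolution
      } else {
        c(kdim, nd$cin, nd$cout)
      }
      n_in <- prod(kdim) * nd$cin
      n_out <- prod(kdim) * nd$cout
      sdw <- sqrt(2 / (n_in + n_out))
      p <- list(W = array(stats::rnorm(prod(wdim), 0, sdw), wdim),
                b = numeric(nd$cout))
      if (isTRUE(nd$bn)) {
        p$gamma <- rep(1, nd$cout)
        p$beta <- numeric(nd$cout)
      }
      params[[nd$idx]] <- p
    }
  })
  net$params <- params
  net
}

#' Stand-alone 2x2 stride-2 down-sampling
#'
#' Applies one down-sampling step to a feature map, halving each spatial
#' axis (ceil for odd sizes). In `strided_conv` mode the four window
#' coefficients `C11, C12, C21, C22` (top-left, top-right, bottom-left,
#' bottom-right) weight the window entries per channel; with all four equal
#' to 1/4 this reproduces mean-pooling exactly. `max_pool` and `mean_pool`
#' apply the fixed reductions (mean-pooling treats out-of-range window
#' positions at odd edges as zeros, matching the strided convolution).
#'
#' @param x Numeric matrix or 3-d array `(H, W, C)`.
#' @param coefficients Length-4 numeric, used in `strided_conv` mode.
#' @param mode One of `"strided_conv"`, `"max_pool"`, `"mean_pool"`.
#' @return Down-sampled map of the same type as `x`.
#' @export
downsample <- function(x, coefficients = rep(0.25, 4),
                       mode = c("strided_conv", "max_pool", "mean_pool")) {
  mode <- match.arg(mode)
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  ho <- (d[1] + 1L) %/% 2L; wo <- (d[2] + 1L) %/% 2L
  if (mode == "strided_conv") {
    if (length(coefficients) != 4) stop("need 4 window coefficients")
    xe <- array(0, c(2L * ho, 2L * wo, d[3]))
    xe[seq_len(d[1]), seq_len(d[2]), ] <- x
    odd_r <- seq(1L, 2L * ho, by = 2L); odd_c <- seq(1L, 2L * wo, by = 2L)
    out <- coefficients[1] * xe[odd_r, odd_c, , drop = FALSE] +
      coefficients[2] * xe[odd_r, odd_c + 1L, , drop = FALSE] +
      coefficients[3] * xe[odd_r + 1L, odd_c, , drop = FALSE] +
      coefficients[4] * xe[odd_r + 1L, odd_c + 1L, , drop = FALSE]
  } else {
    out <- cpp_pool_fwd(x, if (mode == "max_pool") 0L else 1L)$y
  }
  if (was_matrix) out <- array(out[, , 1], dim(out)[1:2])
  out
}

# --- internal forward / backward engine -------------------------------------

bn_fwd <- function(z, gamma, beta, eps = 1e-5) {
  d <- dim(z); N <- d[1] * d[2]
  m <- matrix(z, N, d[3])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = N)
  v <- colMeans(xc^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * rep(ivar, each = N)
  y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(y = array(y, d), xhat = xhat, ivar = ivar)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy); N <- d[1] * d[2]
  dym <- matrix(dy, N, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = N)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dxm <- dxhat - cache$xhat * rep(t2 / N, each = N) - rep(t1 / N, each = N)
  dxm <- dxm * rep(cache$ivar, each = N)
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

add_bias_cube <- function(z, b) {
  d <- dim(z)
  z + array(rep(b, each = d[1] * d[2]), d)
}

kmat <- function(W) matrix(W, prod(dim(W)[1:3]), dim(W)[4])

gather_input <- function(acts, nd) {
  if (length(nd$in_nodes) == 1) acts[[nd$in_nodes[1]]]
  else bind_channels(acts[[nd$in_nodes[1]]], acts[[nd$in_nodes[2]]])
}

unet_forward <- function(net, x, train = FALSE) {
  if (is.null(net$params)) stop("network has no parameters; ",
                                "call initialize_parameters() first")
  nn <- length(net$nodes)
  acts <- vector("list", nn)
  cache <- if (train) vector("list", nn) else NULL
  for (nd in net$nodes) {
    i <- nd$idx
    a <- switch(nd$kind,
      input = array(x, c(nd$out_shape[1], nd$out_shape[2], 1L)),
      add = acts[[nd$in_nodes[1]]] + acts[[nd$in_nodes[2]]],
      norm = {
        z <- acts[[nd$in_nodes[1]]]
        mu <- mean(z)
        s <- sqrt(mean((z - mu)^2))
        # non-finite maps propagate NaN so the caller's loss check reports
        # the offending epoch/pair; only a genuinely constant map errors
        if (is.finite(s) && s < 1e-12)
          stop("degenerate map in normalization layer")
        y <- (z - mu) / s
        if (train) cache[[i]] <- list(sd = s, y = y)
        y
      },
      { # conv / down / convt
        p <- net$params[[i]]
        xin <- gather_input(acts, nd)
        os <- nd$out_shape
        if (nd$kind == "conv") {
          z <- cpp_conv_fwd(xin, kmat(p$W), p$b, 3L, 3L, 1L, 1L, 1L, 1L,
                            os[1], os[2])
        } else if (nd$kind == "down") {
          if (nd$pool_mode == "strided_conv") {
            z <- cpp_conv_fwd(xin, kmat(p$W), p$b, 2L, 2L, 2L, 2L, 0L, 0L,
                              os[1], os[2])
          } else {
            pf <- cpp_pool_fwd(xin, if (nd$pool_mode == "max_pool") 0L else 1L)
            z <- cpp_conv_fwd(pf$y, kmat(p$W), p$b, 1L, 1L, 1L, 1L, 0L, 0L,
                              os[1], os[2])
            if (train) cache[[i]] <- list(pool = pf)
          }
        } else { # convt: adjoint of a 3x3 stride-2 pad-1 convolution
          z <- cpp_conv_gradin(xin, kmat(p$W), 3L, 3L, 2L, 2L, 1L, 1L,
                               os[1], os[2])
          z <- add_bias_cube(z, p$b)
        }
        if (isTRUE(nd$bn)) {
          bf <- bn_fwd(z, p$gamma, p$beta)
          if (train) cache[[i]] <- c(cache[[i]],
                                     list(xhat = bf$xhat, ivar = bf$ivar))
          z <- bf$y
        }
        if (identical(nd$act, "relu")) z <- z * (z > 0)
        z
      })
    acts[[i]] <- a
  }
  list(out = acts[[nn]][, , 1], acts = acts, cache = cache)
}

# gradients of a scalar loss w.r.t. all parameters, given dY = dL/d(output)
unet_backward <- function(net, fw, dY) {
  nn <- length(net$nodes)
  gacc <- vector("list", nn)
  pgrad <- vector("list", nn)
  push <- function(j, g) {
    gacc[[j]] <<- if (is.null(gacc[[j]])) g else gacc[[j]] + g
  }
  d1 <- dim(fw$acts[[nn]])
  gacc[[nn]] <- array(dY, d1)
  for (i in rev(seq_len(nn))) {
    nd <- net$nodes[[i]]
    dy <- gacc[[i]]
    if (is.null(dy) || nd$kind == "input") next
    if (nd$kind == "norm") {
      cc <- fw$cache[[i]]
      dz <- (dy - mean(dy) - cc$y * mean(dy * cc$y)) / cc$sd
      push(nd$in_nodes[1], dz)
      next
    }
    if (nd$kind == "add") {
      push(nd$in_nodes[1], dy)
      push(nd$in_nodes[2], dy)
      next
    }
    p <- net$params[[i]]
    a <- fw$acts[[i]]
    if (identical(nd$act, "relu")) dy <- dy * (a > 0)
    g <- list()
    if (isTRUE(nd$bn)) {
      bb <- bn_bwd(dy, fw$cache[[i]], p$gamma)
      dy <- bb$dx
      g$gamma <- bb$dgamma
      g$beta <- bb$dbeta
    }
    g$b <- as.numeric(cpp_slice_sums(dy))
    xin <- gather_input(fw$acts, nd)
    di <- dim(xin)
    if (nd$kind == "conv") {
      g$W <- array(cpp_conv_gradK(xin, dy, 3L, 3L, 1L, 1L, 1L, 1L), dim(p$W))
      dxin <- cpp_conv_gradin(dy, kmat(p$W), 3L, 3L, 1L, 1L, 1L, 1L,
                              di[1], di[2])
    } else if (nd$kind == "down") {
      if (nd$pool_mode == "strided_conv") {
        g$W <- array(cpp_conv_gradK(xin, dy, 2L, 2L, 2L, 2L, 0L, 0L),
                     dim(p$W))
        dxin <- cpp_conv_gradin(dy, kmat(p$W), 2L, 2L, 2L, 2L, 0L, 0L,
                                di[1], di[2])
      } else {
        pf <- fw$cache[[i]]$pool
        g$W <- array(cpp_conv_gradK(pf$y, dy, 1L, 1L, 1L, 1L, 0L, 0L),
                     dim(p$W))
        dxp <- cpp_conv_gradin(dy, kmat(p$W), 1L, 1L, 1L, 1L, 0L, 0L,
                               dim(pf$y)[1], dim(pf$y)[2])
        dxin <- cpp_pool_bwd(dxp, pf$argmax,
                             if (nd$pool_mode == "max_pool") 0L else 1L,
                             di[1], di[2])
      }
    } else { # convt
      dxin <- cpp_conv_fwd(dy, kmat(p$W), numeric(di[3]), 3L, 3L, 2L, 2L,
                           1L, 1L, di[1], di[2])
      g$W <- array(cpp_conv_gradK(dy, xin, 3L, 3L, 2L, 2L, 1L, 1L), dim(p$W))
    }
    pgrad[[i]] <- g
    if (length(nd$in_nodes) == 1) {
      push(nd$in_nodes[1], dxin)
    } else {
      c1 <- net$nodes[[nd$in_nodes[1]]]$out_shape[3]
      push(nd$in_nodes[1], dxin[, , seq_len(c1), drop = FALSE])
      push(nd$in_nodes[2],
           dxin[, , (c1 + 1):di[3], drop = FALSE])
    }
  }
  pgrad
}

#' Network forward pass
#'
#' Runs a normalized sinogram through the residual U-net. The output is the
#' residual prediction added to the input and re-normalized (the last two
#' layers of the architecture); its recorded inversion statistics are those
#' of the input grid, which are the ones available at inference time.
#'
#' @param net An initialized `sino_unet`.
#' @param x A `normalized_grid` whose spatial shape equals the network
#'   input shape.
#' @return A `normalized_grid` of the same shape.
#' @export
forward_pass <- function(net, x) {
  if (!inherits(x, "normalized_grid")) stop("x must be a normalized_grid")
  d <- dim(x$values)
  if (!all(d == net$input_shape))
    stop(sprintf("input shape %d x %d does not match network input %d x %d",
                 d[1], d[2], net$input_shape[1], net$input_shape[2]))
  out <- unet_forward(net, x$values, train = FALSE)$out
  structure(list(values = out, source_mean = x$source_mean,
                 source_sd = x$source_sd),
            class = "normalized_grid")
}
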