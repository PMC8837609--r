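# Reverse-mode automatic differentiation on a linear tape.
#
# Nodes are environments holding a numeric array `value`, an accumulated
# `grad`, and a `backward` closure that pushes the node's gradient into its
# parents. Operations append nodes in execution order; `nn_backward` walks
# the tape in reverse. Single-image feature maps are (H, W, C) arrays,
# token blocks are (N, C) matrices, parameters keep their natural shapes.
# This is deliberately minimal: enough primitives for an encoder-decoder
# segmentation network with window attention, nothing more.

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

nn_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

nn_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = c(1))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

op_const <- function(tape, value) nn_node(tape, value)

op_add <- function(a, b) {
  nd <- nn_node(a$tape, a$value + b$value,
                function(g) { acc_grad(a, g); acc_grad(b, g) })
  nd
}

op_scale <- function(a, s) {
  nn_node(a$tape, a$value * s, function(g) acc_grad(a, g * s))
}

# add a constant array (e.g. an attention mask); no gradient to the constant
op_add_const <- function(a, k) {
  nn_node(a$tape, a$value + k, function(g) acc_grad(a, g))
}

# broadcast a length-C bias over the last dimension of a (N,C) matrix or
# (H,W,C) array
op_add_bias <- function(x, b) {
  d <- dim(x$value)
  cn <- d[length(d)]
  spread <- prod(d[-length(d)])
  val <- x$value + rep(b$value, each = spread)
  nn_node(x$tape, val, function(g) {
    acc_grad(x, g)
    acc_grad(b, colSums(matrix(g, spread, cn)))
  })
}

op_matmul <- function(a, b) {
  nn_node(a$tape, a$value %*% b$value, function(g) {
    acc_grad(a, tcrossprod(g, b$value))
    acc_grad(b, crossprod(a$value, g))
  })
}

op_matmul_bt <- function(a, b) {
  # a %*% t(b)
  nn_node(a$tape, tcrossprod(a$value, b$value), function(g) {
    acc_grad(a, g %*% b$value)
    acc_grad(b, crossprod(g, a$value))
  })
}

op_cbind <- function(nodes) {
  chans <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(chans); starts <- ends - chans + 1L
  nn_node(nodes[[1]]$tape, do.call(cbind, lapply(nodes, function(n) n$value)),
          function(g) {
            for (k in seq_along(nodes)) {
              acc_grad(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
            }
          })
}

op_relu <- function(a) {
  m <- a$value > 0
  nn_node(a$tape, a$value * m, function(g) acc_grad(a, g * m))
}

op_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  nn_node(a$tape, x * ph,
          function(g) acc_grad(a, g * (ph + x * stats::dnorm(x))))
}

# row-wise softmax of a matrix (used for attention logits)
op_softmax_rows <- function(a) {
  x <- a$value
  x <- x - apply(x, 1, max)
  e <- exp(x)
  y <- e / rowSums(e)
  nn_node(a$tape, y, function(g) {
    acc_grad(a, (g - rowSums(g * y)) * y)
  })
}

# channel softmax of an (H,W,C) map (the dense prediction head)
op_softmax_channels <- function(a) {
  d <- dim(a$value)
  m <- matrix(a$value, prod(d[1:2]), d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  yv <- array(y, d)
  nn_node(a$tape, yv, function(g) {
    gm <- matrix(g, prod(d[1:2]), d[3])
    acc_grad(a, array((gm - rowSums(gm * y)) * y, d))
  })
}

# per-channel RMS instance normalization of an (H,W,C) map with learned
# scale/shift: y_c = x_c / rms(x_c) * g_c + b_c. Single-image training has
# no batch statistics; channel RMS is the stable alternative.
op_rmsnorm_channels <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  n <- prod(d[1:2])
  xm <- matrix(x$value, n, d[3])
  inv <- 1 / sqrt(colMeans(xm^2) + eps)
  xh <- sweep(xm, 2, inv, "*")
  y <- sweep(sweep(xh, 2, gamma$value, "*"), 2, beta$value, "+")
  nn_node(x$tape, array(y, d), function(g) {
    gm <- matrix(g, n, d[3])
    acc_grad(gamma, colSums(gm * xh))
    acc_grad(beta, colSums(gm))
    s <- colMeans(gm * xm)          # per-channel mean of g*x
    dx <- sweep(gm, 2, gamma$value * inv, "*") -
      sweep(xm, 2, gamma$value * inv^3 * s, "*")
    acc_grad(x, array(dx, d))
  })
}

# layer norm over the last dimension (channels) of a token matrix (N,C)
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc^2)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, gamma$value, "*")
  y <- sweep(y, 2, beta$value, "+")
  nn_node(x$tape, y, function(g) {
    acc_grad(gamma, colSums(g * xhat))
    acc_grad(beta, colSums(g))
    dxhat <- sweep(g, 2, gamma$value, "*")
    acc_grad(x, (dxhat - rowMeans(dxhat) -
                   xhat * rowMeans(dxhat * xhat)) * inv)
  })
}

op_reshape <- function(a, dims) {
  old <- dim(a$value)
  nn_node(a$tape, array(a$value, dims),
          function(g) acc_grad(a, array(g, old)))
}

# gather rows of a token matrix; backward scatter-adds (indices may repeat)
op_gather_rows <- function(a, idx) {
  nn_node(a$tape, a$value[idx, , drop = FALSE], function(g) {
    d <- matrix(0, nrow(a$value), ncol(a$value))
    # rowsum aggregates duplicate indices
    agg <- rowsum(g, group = idx)
    d[as.integer(rownames(agg)), ] <- agg
    acc_grad(a, d)
  })
}

op_rbind <- function(nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  nn_node(nodes[[1]]$tape, do.call(rbind, lapply(nodes, function(n) n$value)),
          function(g) {
            for (k in seq_along(nodes)) {
              acc_grad(nodes[[k]], g[starts[k]:ends[k], , drop = FALSE])
            }
          })
}

# concatenate (H,W,C_k) maps along channels
op_concat_c <- function(nodes) {
  d1 <- dim(nodes[[1]]$value)
  chans <- vapply(nodes, function(n) dim(n$value)[3], integer(1))
  ends <- cumsum(chans); starts <- ends - chans + 1L
  val <- array(0, c(d1[1], d1[2], sum(chans)))
  for (k in seq_along(nodes)) {
    val[, , starts[k]:ends[k]] <- nodes[[k]]$value
  }
  nn_node(nodes[[1]]$tape, val, function(g) {
    for (k in seq_along(nodes)) {
      acc_grad(nodes[[k]], g[, , starts[k]:ends[k], drop = FALSE])
    }
  })
}

# cyclic roll of an (H,W,C) map by (sr, sc); negative shifts roll upward/left
op_roll <- function(a, sr, sc) {
  d <- dim(a$value)
  ir <- ((seq_len(d[1]) - 1 - sr) %% d[1]) + 1
  ic <- ((seq_len(d[2]) - 1 - sc) %% d[2]) + 1
  jr <- ((seq_len(d[1]) - 1 + sr) %% d[1]) + 1
  jc <- ((seq_len(d[2]) - 1 + sc) %% d[2]) + 1
  nn_node(a$tape, a$value[ir, ic, , drop = FALSE],
          function(g) acc_grad(a, g[jr, jc, , drop = FALSE]))
}

# zero padding helpers for convolution
pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# 2-D convolution via im2col; same padding, odd kernels
op_conv2d <- function(x, w, stride = 1, dilation = 1) {
  dx <- dim(x$value)
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  stopifnot(dx[3] == cin)
  p <- dilation * (kh - 1) / 2
  xp <- pad_hw(x$value, p)
  ho <- (dx[1] - 1) %/% stride + 1
  wo <- (dx[2] - 1) %/% stride + 1
  cols <- matrix(0, ho * wo, kh * kw * cin)
  ri_list <- vector("list", kh * kw)
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    ri <- (i - 1) * dilation + seq(1, by = stride, length.out = ho)
    cj <- (j - 1) * dilation + seq(1, by = stride, length.out = wo)
    blk <- i + (j - 1) * kh
    ri_list[[blk]] <- list(ri = ri, cj = cj)
    cols[, blk + (seq_len(cin) - 1) * kh * kw] <-
      matrix(xp[ri, cj, , drop = FALSE], ho * wo, cin)
  }
  wmat <- matrix(w$value, kh * kw * cin, cout)
  y <- array(cols %*% wmat, c(ho, wo, cout))
  nn_node(x$tape, y, function(g) {
    gm <- matrix(g, ho * wo, cout)
    acc_grad(w, array(crossprod(cols, gm), dw))
    dcols <- tcrossprod(gm, matrix(w$value, kh * kw * cin, cout))
    dxp <- array(0, dim(xp))
    for (j in seq_len(kw)) for (i in seq_len(kh)) {
      blk <- i + (j - 1) * kh
      ri <- ri_list[[blk]]$ri; cj <- ri_list[[blk]]$cj
      dxp[ri, cj, ] <- dxp[ri, cj, , drop = FALSE] +
        array(dcols[, blk + (seq_len(cin) - 1) * kh * kw], c(ho, wo, cin))
    }
    acc_grad(x, if (p > 0) {
      dxp[p + seq_len(dx[1]), p + seq_len(dx[2]), , drop = FALSE]
    } else dxp)
  })
}

# depthwise 3x3 convolution (one filter per channel), used by the atrous
# separable stage
op_dwconv2d <- function(x, w, stride = 1, dilation = 1) {
  dx <- dim(x$value)
  dw <- dim(w$value)          # (kh, kw, C)
  kh <- dw[1]; kw <- dw[2]; cn <- dw[3]
  p <- dilation * (kh - 1) / 2
  xp <- pad_hw(x$value, p)
  ho <- (dx[1] - 1) %/% stride + 1
  wo <- (dx[2] - 1) %/% stride + 1
  y <- array(0, c(ho, wo, cn))
  slices <- vector("list", kh * kw)
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    ri <- (i - 1) * dilation + seq(1, by = stride, length.out = ho)
    cj <- (j - 1) * dilation + seq(1, by = stride, length.out = wo)
    s <- xp[ri, cj, , drop = FALSE]
    slices[[i + (j - 1) * kh]] <- list(ri = ri, cj = cj, s = s)
    y <- y + s * rep(w$value[i, j, ], each = ho * wo)
  }
  nn_node(x$tape, y, function(g) {
    dwv <- array(0, dw)
    dxp <- array(0, dim(xp))
    for (j in seq_len(kw)) for (i in seq_len(kh)) {
      sl <- slices[[i + (j - 1) * kh]]
      dwv[i, j, ] <- colSums(matrix(g * sl$s, ho * wo, cn))
      dxp[sl$ri, sl$cj, ] <- dxp[sl$ri, sl$cj, , drop = FALSE] +
        array(g * rep(w$value[i, j, ], each = ho * wo), c(ho, wo, cn))
    }
    acc_grad(w, dwv)
    acc_grad(x, if (p > 0) {
      dxp[p + seq_len(dx[1]), p + seq_len(dx[2]), , drop = FALSE]
    } else dxp)
  })
}

# 2x transpose convolution with a 2x2 kernel and stride 2 (non-overlapping):
# each input pixel expands into a learned 2x2 block
op_convT2 <- function(x, w) {
  dx <- dim(x$value)
  dw <- dim(w$value)          # (2, 2, Cin, Cout)
  cin <- dw[3]; cout <- dw[4]
  xm <- matrix(x$value, dx[1] * dx[2], cin)
  y <- array(0, c(2 * dx[1], 2 * dx[2], cout))
  for (di in 1:2) for (dj in 1:2) {
    y[seq(di, 2 * dx[1], 2), seq(dj, 2 * dx[2], 2), ] <-
      array(xm %*% matrix(w$value[di, dj, , ], cin, cout),
            c(dx[1], dx[2], cout))
  }
  nn_node(x$tape, y, function(g) {
    dwv <- array(0, dw)
    dxm <- matrix(0, dx[1] * dx[2], cin)
    for (di in 1:2) for (dj in 1:2) {
      gs <- matrix(g[seq(di, 2 * dx[1], 2), seq(dj, 2 * dx[2], 2), ,
                     drop = FALSE], dx[1] * dx[2], cout)
      dwv[di, dj, , ] <- crossprod(xm, gs)
      dxm <- dxm + tcrossprod(gs, matrix(w$value[di, dj, , ], cin, cout))
    }
    acc_grad(w, dwv)
    acc_grad(x, array(dxm, dx))
  })
}

# adaptive average pooling to (bins x bins); uneven block sizes are
# handled by floor-spaced boundaries, so any bins <= min(H, W) works
op_avgpool_bins <- function(x, bins) {
  d <- dim(x$value)
  bins <- min(bins, d[1], d[2])
  er <- floor(seq(0, d[1], length.out = bins + 1))
  ec <- floor(seq(0, d[2], length.out = bins + 1))
  y <- array(0, c(bins, bins, d[3]))
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    blkr <- (er[a] + 1):er[a + 1]; blkc <- (ec[b] + 1):ec[b + 1]
    y[a, b, ] <- colMeans(matrix(x$value[blkr, blkc, , drop = FALSE],
                                 length(blkr) * length(blkc), d[3]))
  }
  nn_node(x$tape, y, function(g) {
    dx <- array(0, d)
    for (a in seq_len(bins)) for (b in seq_len(bins)) {
      blkr <- (er[a] + 1):er[a + 1]; blkc <- (ec[b] + 1):ec[b + 1]
      npx <- length(blkr) * length(blkc)
      dx[blkr, blkc, ] <- dx[blkr, blkc, , drop = FALSE] +
        array(rep(g[a, b, ] / npx, each = npx),
              c(length(blkr), length(blkc), d[3]))
    }
    acc_grad(x, dx)
  })
}

# nearest-neighbour upsampling to an arbitrary (ho, wo)
op_upsample_to <- function(x, ho, wo) {
  d <- dim(x$value)
  ir <- floor((seq_len(ho) - 1) * d[1] / ho) + 1
  ic <- floor((seq_len(wo) - 1) * d[2] / wo) + 1
  nn_node(x$tape, x$value[ir, ic, , drop = FALSE], function(g) {
    red <- array(0, d)
    for (a in seq_len(ho)) for (b in seq_len(wo)) {
      red[ir[a], ic[b], ] <- red[ir[a], ic[b], ] + g[a, b, ]
    }
    acc_grad(x, red)
  })
}

# weighted multiclass soft dice loss on channel-softmax probabilities.
# Per channel j: dice_j = 2*sum(p*g) / (2*sum(p*g) + sum((1-p)*g) +
# sum(p*(1-g))); loss = mean_j xi_j * (1 - dice_j). `smooth` stabilizes
# channels empty in both maps (their dice -> 1, no loss).
op_weighted_dice <- function(probs, onehot, xi, smooth = 1e-7) {
  d <- dim(probs$value)
  pm <- matrix(probs$value, prod(d[1:2]), d[3])
  gm <- matrix(onehot, prod(d[1:2]), d[3])
  inter <- colSums(pm * gm)
  psum <- colSums(pm); gsum <- colSums(gm)
  num <- 2 * inter + smooth
  den <- psum + gsum + smooth       # algebraic form of the full denominator
  dice <- num / den
  loss <- mean(xi * (1 - dice))
  cn <- d[3]
  nn_node(probs$tape, array(loss, c(1)), function(g) {
    gl <- as.numeric(g)
    # d(1-dice_j)/dp_i = -(2*g_i*den_j - num_j) / den_j^2
    coef <- gl * xi / cn
    dp <- -sweep(sweep(gm, 2, 2 / den, "*"), 2, num / den^2, "-")
    dp <- sweep(dp, 2, coef, "*")
    acc_grad(probs, array(dp, d))
  })
}
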