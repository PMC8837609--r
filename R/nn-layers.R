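# Layer builders for the segmentation network. A model is an environment
# holding a named list of parameter arrays; builders register parameters
# under hierarchical names at construction time, and the matching forward
# helpers fetch them as tape nodes through a per-forward context.

new_param <- function(model, name, value) {
  model$params[[name]] <- value
  invisible(name)
}

init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0,
                     sqrt(2 / (kh * kw * cin))), c(kh, kw, cin, cout))
}

init_linear <- function(cin, cout, gain = 1) {
  matrix(stats::rnorm(cin * cout, 0, gain * sqrt(1 / cin)), cin, cout)
}

# forward context: wraps params of `model` as tape nodes on first use so
# gradients can be read back after nn_backward
fwd_ctx <- function(model, tape) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$model <- model
  ctx$nodes <- list()
  ctx
}

getp <- function(ctx, name) {
  nd <- ctx$nodes[[name]]
  if (is.null(nd)) {
    v <- ctx$model$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- nn_node(ctx$tape, v)
    ctx$nodes[[name]] <- nd
  }
  nd
}

# --- convolution blocks -----------------------------------------------------

build_conv <- function(model, name, k, cin, cout, bias = TRUE,
                       norm = FALSE) {
  new_param(model, paste0(name, ".w"), init_conv(k, k, cin, cout))
  if (bias) new_param(model, paste0(name, ".b"), numeric(cout))
  if (norm) {
    new_param(model, paste0(name, ".ng"), rep(1, cout))
    new_param(model, paste0(name, ".nb"), numeric(cout))
  }
}

fwd_conv <- function(ctx, name, x, stride = 1, dilation = 1, act = "relu") {
  y <- op_conv2d(x, getp(ctx, paste0(name, ".w")), stride = stride,
                 dilation = dilation)
  bn <- paste0(name, ".b")
  if (!is.null(ctx$model$params[[bn]])) y <- op_add_bias(y, getp(ctx, bn))
  if (!is.null(ctx$model$params[[paste0(name, ".ng")]])) {
    y <- op_rmsnorm_channels(y, getp(ctx, paste0(name, ".ng")),
                             getp(ctx, paste0(name, ".nb")))
  }
  if (identical(act, "relu")) y <- op_relu(y)
  y
}

build_convT <- function(model, name, cin, cout, norm = FALSE) {
  new_param(model, paste0(name, ".w"),
            array(stats::rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))),
                  c(2, 2, cin, cout)))
  new_param(model, paste0(name, ".b"), numeric(cout))
  if (norm) {
    new_param(model, paste0(name, ".ng"), rep(1, cout))
    new_param(model, paste0(name, ".nb"), numeric(cout))
  }
}

fwd_convT <- function(ctx, name, x, act = "relu") {
  y <- op_convT2(x, getp(ctx, paste0(name, ".w")))
  y <- op_add_bias(y, getp(ctx, paste0(name, ".b")))
  if (!is.null(ctx$model$params[[paste0(name, ".ng")]])) {
    y <- op_rmsnorm_channels(y, getp(ctx, paste0(name, ".ng")),
                             getp(ctx, paste0(name, ".nb")))
  }
  if (identical(act, "relu")) y <- op_relu(y)
  y
}

# atrous separable convolution: depthwise dilated 3x3 + pointwise 1x1
build_sepconv <- function(model, name, cin, cout) {
  new_param(model, paste0(name, ".dw"),
            array(stats::rnorm(9 * cin, 0, sqrt(2 / 9)), c(3, 3, cin)))
  build_conv(model, paste0(name, ".pw"), 1, cin, cout, norm = TRUE)
}

fwd_sepconv <- function(ctx, name, x, stride = 1, dilation = 2) {
  y <- op_dwconv2d(x, getp(ctx, paste0(name, ".dw")), stride = stride,
                   dilation = dilation)
  fwd_conv(ctx, paste0(name, ".pw"), y, act = "relu")
}

# --- window attention (Swin-style) ------------------------------------------

# token indices of each (ws x ws) window of an H x W map, column-major
window_indices <- function(h, w, ws) {
  idx <- list()
  for (wb in seq_len(w %/% ws)) for (hb in seq_len(h %/% ws)) {
    rows <- (hb - 1) * ws + seq_len(ws)
    cols <- (wb - 1) * ws + seq_len(ws)
    idx[[length(idx) + 1]] <- as.integer(outer(rows, (cols - 1) * h, "+"))
  }
  idx
}

# additive attention masks for the shifted-window configuration: tokens
# from different pre-shift regions must not attend to each other
shifted_window_masks <- function(h, w, ws, shift) {
  rid <- function(n) {
    r <- integer(n)
    r[seq_len(n - ws)] <- 0L
    if (n - ws + 1 <= n - shift) r[(n - ws + 1):(n - shift)] <- 1L
    r[(n - shift + 1):n] <- 2L
    r
  }
  region <- outer(rid(h), rid(w) * 3L, "+")
  # roll like the feature map
  ir <- ((seq_len(h) - 1 + shift) %% h) + 1
  ic <- ((seq_len(w) - 1 + shift) %% w) + 1
  region <- region[ir, ic]
  lapply(window_indices(h, w, ws), function(idx) {
    r <- as.integer(region)[idx]
    m <- outer(r, r, function(a, b) ifelse(a == b, 0, -1e9))
    m
  })
}

build_swin_block <- function(model, name, c, heads, mlp_ratio = 4) {
  dh <- c %/% heads
  stopifnot(dh * heads == c)
  for (h in seq_len(heads)) {
    for (nm in c("q", "k", "v")) {
      new_param(model, paste0(name, ".", nm, h), init_linear(c, dh))
    }
  }
  new_param(model, paste0(name, ".o"), init_linear(c, c))
  new_param(model, paste0(name, ".ln1.g"), rep(1, c))
  new_param(model, paste0(name, ".ln1.b"), numeric(c))
  new_param(model, paste0(name, ".ln2.g"), rep(1, c))
  new_param(model, paste0(name, ".ln2.b"), numeric(c))
  new_param(model, paste0(name, ".mlp1.w"), init_linear(c, mlp_ratio * c))
  new_param(model, paste0(name, ".mlp1.b"), numeric(mlp_ratio * c))
  new_param(model, paste0(name, ".mlp2.w"), init_linear(mlp_ratio * c, c))
  new_param(model, paste0(name, ".mlp2.b"), numeric(c))
}

# one Swin transformer block on an (H,W,C) map node; shift = 0 gives W-MSA,
# shift = ws/2 gives SW-MSA with masked cyclic shift
fwd_swin_block <- function(ctx, name, x, ws, heads, shift = 0) {
  d <- dim(x$value)
  h <- d[1]; w <- d[2]; c <- d[3]
  if (h %% ws != 0 || w %% ws != 0) {
    stop("feature map ", h, "x", w, " not divisible by window size ", ws)
  }
  dh <- c %/% heads
  tokens <- op_reshape(x, c(h * w, c))
  ln <- op_layernorm(tokens, getp(ctx, paste0(name, ".ln1.g")),
                     getp(ctx, paste0(name, ".ln1.b")))
  lnmap <- op_reshape(ln, c(h, w, c))
  if (shift > 0) lnmap <- op_roll(lnmap, -shift, -shift)
  lntok <- op_reshape(lnmap, c(h * w, c))
  widx <- window_indices(h, w, ws)
  masks <- if (shift > 0) shifted_window_masks(h, w, ws, shift) else NULL
  outs <- vector("list", length(widx))
  for (k in seq_along(widx)) {
    win <- op_gather_rows(lntok, widx[[k]])
    hs <- vector("list", heads)
    for (hd in seq_len(heads)) {
      q <- op_matmul(win, getp(ctx, paste0(name, ".q", hd)))
      ky <- op_matmul(win, getp(ctx, paste0(name, ".k", hd)))
      v <- op_matmul(win, getp(ctx, paste0(name, ".v", hd)))
      lg <- op_scale(op_matmul_bt(q, ky), 1 / sqrt(dh))
      if (!is.null(masks)) lg <- op_add_const(lg, masks[[k]])
      hs[[hd]] <- op_matmul(op_softmax_rows(lg), v)
    }
    cat_h <- if (heads > 1) op_cbind(hs) else hs[[1]]
    outs[[k]] <- op_matmul(cat_h, getp(ctx, paste0(name, ".o")))
  }
  comb <- op_rbind(outs)
  ord <- order(unlist(widx))
  attn <- op_gather_rows(comb, ord)
  if (shift > 0) {
    amap <- op_roll(op_reshape(attn, c(h, w, c)), shift, shift)
    attn <- op_reshape(amap, c(h * w, c))
  }
  x1 <- op_add(tokens, attn)
  ln2 <- op_layernorm(x1, getp(ctx, paste0(name, ".ln2.g")),
                      getp(ctx, paste0(name, ".ln2.b")))
  m1 <- op_gelu(op_add_bias(op_matmul(ln2, getp(ctx, paste0(name, ".mlp1.w"))),
                            getp(ctx, paste0(name, ".mlp1.b"))))
  m2 <- op_add_bias(op_matmul(m1, getp(ctx, paste0(name, ".mlp2.w"))),
                    getp(ctx, paste0(name, ".mlp2.b")))
  x2 <- op_add(x1, m2)
  op_reshape(x2, c(h, w, c))
}

build_st_sc <- function(model, name, c, heads, reduction = 1 / 8) {
  cr <- as.integer(round(c * reduction))
  stopifnot(cr >= 2, cr %% 2 == 0)
  build_swin_block(model, paste0(name, ".blk1"), c, heads)
  build_swin_block(model, paste0(name, ".blk2"), c, heads)
  build_conv(model, paste0(name, ".proj_x"), 1, c, cr %/% 2)
  build_conv(model, paste0(name, ".proj_sc"), 1, c, cr %/% 2)
}

# largest window size <= ws dividing both spatial dimensions, so odd
# aspect ratios still partition cleanly
eff_window <- function(h, w, ws) {
  for (d in seq(ws, 1)) {
    if (h %% d == 0 && w %% d == 0) return(d)
  }
  1L
}

# ST-SC skip module: two successive Swin blocks (regular then shifted
# windows), a 1x1 convolution on both the block output and the input, and
# channel splicing; output channels = reduction * input channels
fwd_st_sc <- function(ctx, name, x, ws, heads) {
  d <- dim(x$value)
  ws <- eff_window(d[1], d[2], ws)
  sc0 <- fwd_swin_block(ctx, paste0(name, ".blk1"), x, ws, heads, shift = 0)
  sc1 <- fwd_swin_block(ctx, paste0(name, ".blk2"), sc0, ws, heads,
                        shift = ws %/% 2)
  xh <- fwd_conv(ctx, paste0(name, ".proj_x"), x, act = "none")
  sh <- fwd_conv(ctx, paste0(name, ".proj_sc"), sc1, act = "none")
  op_concat_c(list(xh, sh))
}
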