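#' Segmentation network configuration
#'
#' Configures the encoder-decoder segmentation network: a strided
#' convolutional backbone performing 16x downsampling (with an atrous
#' separable convolution in its last stage), a depth-feature-extraction
#' (DFE) head combining pyramid pooling and atrous spatial pyramid pooling
#' (ASPP), window-attention skip-connection modules (ST-SC) on the 1/4 and
#' 1/8 resolution paths, multi-scale feature fusion in the decoder, a 3x3
#' double-convolution refinement, and learned 2x transpose-convolution
#' upsampling to a 14-channel softmax prediction.
#'
#' The `tiny` preset (base 32 channels) exercises every architectural path
#' at CPU-test scale; `full` scales the channel plan so the pyramid-pooling
#' concatenation reaches 4096 channels and ASPP emits 256, the full-scale
#' operating point. Input height and width must be divisible by 16.
#'
#' @param input_size `(H, W)`, both divisible by 16.
#' @param n_classes Number of output channels (14).
#' @param preset `"tiny"` or `"full"`.
#' @param base Base channel count (default 32 tiny, 64 full).
#' @param window Window size of the attention skip modules.
#' @param heads Attention heads per block.
#' @param reduction Channel reduction of the skip modules (default 1/8).
#' @param coord_channels Append normalized row/column coordinate channels
#'   to the intensity input (default `TRUE`); the anatomical classes are
#'   position-coded (L1 vs L3 differ only by craniocaudal position), so an
#'   explicit coordinate input makes them separable without relying on
#'   boundary effects.
#' @param seed Seed for weight initialization.
#' @return A `net_config` list.
#' @export
net_config <- function(input_size = c(64, 64), n_classes = 14,
                       preset = c("tiny", "full"), base = NULL,
                       window = 4, heads = 2, reduction = 1 / 8,
                       coord_channels = TRUE, seed = 42L) {
  preset <- match.arg(preset)
  if (any(input_size %% 16 != 0)) {
    stop("config error: input height and width must be divisible by 16")
  }
  if (reduction <= 0 || reduction > 1) stop("reduction must be in (0, 1]")
  if (is.null(base)) base <- if (preset == "tiny") 32L else 64L
  aspp_out <- if (preset == "tiny") 64L else 256L
  bins <- if (preset == "tiny") c(1L, 2L, 4L) else c(1L, 2L, 4L, 8L)
  rates <- if (preset == "tiny") c(1L, 2L, 3L) else c(6L, 12L, 18L)
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), preset = preset,
                 base = as.integer(base), window = as.integer(window),
                 heads = as.integer(heads), reduction = reduction,
                 coord_channels = isTRUE(coord_channels),
                 aspp_out = aspp_out, bins = bins, rates = rates,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Default channel weights of the weighted dice loss
#'
#' 0.9 for the five vertebral body channels, 0.8 for the five disc
#' channels, and 1 for the remaining four (background, sacrum, presacral
#' fat, CSF), ordered by class id 0..13.
#' @export
default_dice_weights <- function() {
  xi <- rep(1, 14)
  xi[1 + 1:5] <- 0.9   # class ids 1-5: vertebral bodies
  xi[1 + 6:10] <- 0.8  # class ids 6-10: discs
  xi
}

#' Build the segmentation network
#'
#' Allocates and initializes all parameters of the architecture described
#' in [net_config()]. Initialization is seeded and deterministic.
#'
#' @param config A [net_config()].
#' @return A model environment with `params` (named arrays), `config`.
#' @export
build_bianquenet <- function(config = net_config()) {
  set.seed(config$seed)
  b <- config$base
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$config <- config
  c_out <- 8L * b                        # backbone output channels (1/16)
  cin <- if (isTRUE(config$coord_channels)) 3L else 1L
  build_conv(model, "stem", 3, cin, b, norm = TRUE)             # 1/2
  build_conv(model, "enc1a", 3, b, 2 * b, norm = TRUE)          # 1/4 (mid skip tap)
  build_conv(model, "enc1b", 3, 2 * b, 2 * b, norm = TRUE)
  build_conv(model, "enc2a", 3, 2 * b, 4 * b, norm = TRUE)      # 1/8 (high skip tap)
  build_conv(model, "enc2b", 3, 4 * b, 4 * b, norm = TRUE)
  build_sepconv(model, "enc3", 4 * b, c_out)       # 1/16, atrous separable
  # DFE: pyramid pooling branches then ASPP
  pb <- c_out %/% 4L
  for (k in seq_along(config$bins)) {
    build_conv(model, paste0("pp", k), 1, c_out, pb, norm = TRUE)
  }
  cat_c <- c_out + length(config$bins) * pb
  ao <- config$aspp_out
  build_conv(model, "aspp0", 1, cat_c, ao, norm = TRUE)
  for (k in seq_along(config$rates)) {
    build_conv(model, paste0("aspp", k), 3, cat_c, ao, norm = TRUE)
  }
  build_conv(model, "aspp_img", 1, cat_c, ao, norm = TRUE)
  build_conv(model, "aspp_proj", 1, (2 + length(config$rates)) * ao, ao,
             norm = TRUE)
  # ST-SC skip modules on the 1/4 (2b channels) and 1/8 (4b) paths
  build_st_sc(model, "stsc_mid", 2 * b, config$heads, config$reduction)
  build_st_sc(model, "stsc_high", 4 * b, config$heads, config$reduction)
  rmid <- as.integer(round(2 * b * config$reduction))
  rhigh <- as.integer(round(4 * b * config$reduction))
  # decoder: MFF fusions + double-conv refinement + 2x transpose upsampling
  build_convT(model, "up1", ao, ao, norm = TRUE)                # 1/16 -> 1/8
  build_conv(model, "fuse1", 3, ao + rhigh, ao, norm = TRUE)
  build_convT(model, "up2", ao, ao, norm = TRUE)                # 1/8 -> 1/4
  build_conv(model, "fuse2a", 3, ao + rmid, ao, norm = TRUE)
  build_conv(model, "fuse2b", 3, ao, ao, norm = TRUE)
  build_convT(model, "up3", ao, ao %/% 2L, norm = TRUE)         # 1/4 -> 1/2
  build_convT(model, "up4", ao %/% 2L, config$n_classes)  # 1/2 -> 1/1
  model
}

# full forward pass; returns the softmax probability node
bianquenet_forward <- function(ctx, image) {
  cfg <- ctx$model$config
  d <- dim(image)
  inp <- if (isTRUE(cfg$coord_channels)) {
    # normalized row/col coordinate channels: the five vertebrae and five
    # discs are distinguished by craniocaudal position, which a purely
    # translation-equivariant net can only infer from boundary padding
    rr <- matrix(seq(-1, 1, length.out = d[1]), d[1], d[2])
    cc <- matrix(seq(-1, 1, length.out = d[2]), d[1], d[2], byrow = TRUE)
    array(c(image, rr, cc), c(d, 3))
  } else {
    array(image, c(d, 1))
  }
  x <- op_const(ctx$tape, inp)
  e0 <- fwd_conv(ctx, "stem", x, stride = 2)
  e1 <- fwd_conv(ctx, "enc1b", fwd_conv(ctx, "enc1a", e0, stride = 2))
  e2 <- fwd_conv(ctx, "enc2b", fwd_conv(ctx, "enc2a", e1, stride = 2))
  e3 <- fwd_sepconv(ctx, "enc3", e2, stride = 2, dilation = 2)
  # DFE
  d3 <- dim(e3$value)
  branches <- list(e3)
  for (k in seq_along(cfg$bins)) {
    p <- op_avgpool_bins(e3, cfg$bins[k])
    p <- fwd_conv(ctx, paste0("pp", k), p)
    branches[[k + 1]] <- op_upsample_to(p, d3[1], d3[2])
  }
  cat1 <- op_concat_c(branches)
  ab <- list(fwd_conv(ctx, "aspp0", cat1))
  for (k in seq_along(cfg$rates)) {
    ab[[k + 1]] <- fwd_conv(ctx, paste0("aspp", k), cat1,
                            dilation = cfg$rates[k])
  }
  gp <- op_avgpool_bins(cat1, 1)
  gp <- fwd_conv(ctx, "aspp_img", gp)
  ab[[length(ab) + 1]] <- op_upsample_to(gp, d3[1], d3[2])
  d0 <- fwd_conv(ctx, "aspp_proj", op_concat_c(ab))
  # skip modules
  smid <- fwd_st_sc(ctx, "stsc_mid", e1, cfg$window, cfg$heads)
  shigh <- fwd_st_sc(ctx, "stsc_high", e2, cfg$window, cfg$heads)
  # decoder with multi-scale feature fusion
  u1 <- fwd_convT(ctx, "up1", d0)
  f1 <- fwd_conv(ctx, "fuse1", op_concat_c(list(u1, shigh)))
  u2 <- fwd_convT(ctx, "up2", f1)
  f2 <- fwd_conv(ctx, "fuse2b",
                 fwd_conv(ctx, "fuse2a", op_concat_c(list(u2, smid))))
  u3 <- fwd_convT(ctx, "up3", f2)
  logits <- fwd_convT(ctx, "up4", u3, act = "none")
  op_softmax_channels(logits)
}

#' Run the network forward on an image
#'
#' @param model A built model from [build_bianquenet()].
#' @param image Numeric matrix matching the configured input size;
#'   intensities are normalized to `[0, 1]` by the image maximum.
#' @return `(H, W, n_classes)` array of per-pixel class probabilities
#'   (each pixel's probabilities sum to 1).
#' @export
predict_bianquenet <- function(model, image) {
  stopifnot(all(dim(image) == model$config$input_size))
  mx <- max(image)
  if (mx > 0) image <- image / mx
  tape <- nn_tape()
  ctx <- fwd_ctx(model, tape)
  bianquenet_forward(ctx, image)$value
}

#' Segment an image to a label mask
#'
#' Forward pass followed by per-pixel argmax over the class channels.
#'
#' @inheritParams predict_bianquenet
#' @return Integer matrix of class ids 0..n_classes-1.
#' @export
segment_image <- function(model, image) {
  probs <- predict_bianquenet(model, image)
  d <- dim(probs)
  cls <- max.col(matrix(probs, d[1] * d[2], d[3])) - 1L
  matrix(as.integer(cls), d[1], d[2])
}

#' Standalone window-attention skip module
#'
#' Builds and applies one ST-SC module to a feature map: two successive
#' window-attention transformer blocks (regular then shifted windows, each
#' layer-normalized with residual connections and a GELU MLP), a 1x1
#' convolution of both the block output and the module input, and channel
#' splicing of the two, reducing the channel count by `reduction`.
#'
#' @param x `(H, W, C)` numeric array; `H`, `W` divisible by `window`.
#' @param window Window size.
#' @param heads Attention heads (must divide `C`).
#' @param reduction Output channel fraction (default 1/8; `C * reduction`
#'   must be an even integer).
#' @param seed Seed for the module's weights.
#' @param weights Optional: a previously returned module environment to
#'   reuse (so repeated calls share parameters).
#' @return `(H, W, C * reduction)` array with the module environment as
#'   attribute `module`.
#' @export
st_sc_forward <- function(x, window = 4, heads = 2, reduction = 1 / 8,
                          seed = 42L, weights = NULL) {
  d <- dim(x)
  if (d[1] %% window != 0 || d[2] %% window != 0) {
    stop("feature map not divisible by window size")
  }
  model <- weights
  if (is.null(model)) {
    set.seed(seed)
    model <- new.env(parent = emptyenv())
    model$params <- list()
    build_st_sc(model, "m", d[3], heads, reduction)
  }
  tape <- nn_tape()
  ctx <- fwd_ctx(model, tape)
  out <- fwd_st_sc(ctx, "m", op_const(tape, x), window, heads)
  structure(out$value, module = model)
}

#' Weighted multiclass dice loss
#'
#' The per-channel soft dice complement, weighted and averaged:
#' `L = (1/C) * sum_j xi_j * (1 - 2*sum(p1*g1) /
#' (2*sum(p1*g1) + sum(p0*g1) + sum(p1*g0)))`, where `p1`/`g1` are the
#' predicted probability / ground-truth indicator of channel `j` and
#' `p0 = 1 - p1`, `g0 = 1 - g1`. Channels empty in both prediction and
#' truth agree vacuously (dice 1, no loss contribution). Default channel
#' weights: 0.9 for vertebral bodies, 0.8 for discs, 1 elsewhere.
#'
#' @param pred `(H, W, C)` array of per-pixel class probabilities.
#' @param target `(H, W, C)` one-hot array (see [one_hot_mask()]).
#' @param xi Per-channel weights, length `C`.
#' @return Scalar loss.
#' @export
weighted_dice_loss <- function(pred, target, xi = default_dice_weights()) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  cn <- dim(pred)[3]
  if (length(xi) != cn) stop("xi must have one weight per channel")
  pm <- matrix(pred, ncol = cn)
  gm <- matrix(target, ncol = cn)
  inter <- colSums(pm * gm)
  num <- 2 * inter
  den <- 2 * inter + colSums((1 - pm) * gm) + colSums(pm * (1 - gm))
  dice <- ifelse(den == 0, 1, num / den)
  mean(xi * (1 - dice))
}

#' One-hot encode a label mask
#'
#' @param mask Integer matrix of class ids `0..n_classes-1`.
#' @param n_classes Number of channels.
#' @return `(H, W, n_classes)` 0/1 array.
#' @export
one_hot_mask <- function(mask, n_classes = 14) {
  d <- dim(mask)
  oh <- array(0, c(d[1], d[2], n_classes))
  m <- as.integer(mask)
  for (k in seq_len(n_classes)) {
    oh[, , k] <- as.numeric(m == (k - 1L))
  }
  oh
}

#' Train the network on one or more image/mask pairs
#'
#' Plain Adam on the weighted dice loss. Intended for the small
#' CPU-testable preset (architecture smoke tests, single-image
#' overfitting); clinical-scale training is out of scope.
#'
#' @param model Model from [build_bianquenet()].
#' @param images List of intensity matrices (or a single matrix).
#' @param masks List of integer label matrices (class ids 0..C-1).
#' @param steps Optimization steps.
#' @param lr Adam learning rate (constant by default; single-scene
#'   overfitting is still descending fast at the end of a short run, so
#'   decaying early costs final loss).
#' @param lr_decay Optionally apply a cosine decay of the learning rate
#'   over the run.
#' @param xi Dice channel weights.
#' @param betas,eps Adam moment decays and stabilizer.
#' @return Numeric vector of the loss at every step (invisibly, the model
#'   is updated in place).
#' @export
train_bianquenet <- function(model, images, masks, steps = 200, lr = 4e-3,
                             xi = default_dice_weights(), lr_decay = FALSE,
                             betas = c(0.9, 0.999), eps = 1e-8) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  images <- lapply(images, function(im) {
    mx <- max(im); if (mx > 0) im / mx else im
  })
  onehots <- lapply(masks, one_hot_mask, n_classes = model$config$n_classes)
  if (is.null(model$adam_m)) {
    zero_like <- function(p) array(0, dim(p) %||% length(p))
    model$adam_m <- lapply(model$params, zero_like)
    model$adam_v <- lapply(model$params, zero_like)  # independent buffers:
    model$adam_t <- 0L                               # updated in place
  }
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    k <- (s - 1L) %% length(images) + 1L
    tape <- nn_tape()
    ctx <- fwd_ctx(model, tape)
    probs <- bianquenet_forward(ctx, images[[k]])
    loss <- op_weighted_dice(probs, onehots[[k]], xi)
    losses[s] <- as.numeric(loss$value)
    nn_backward(tape, loss)
    model$adam_t <- model$adam_t + 1L
    lr_t <- if (lr_decay) {
      lr * (0.55 + 0.45 * cos(pi * (s - 1) / steps))
    } else lr
    for (nm in names(ctx$nodes)) {
      g <- ctx$nodes[[nm]]$grad
      if (is.null(g)) next
      adam_update(model$params[[nm]], model$adam_m[[nm]],
                  model$adam_v[[nm]], g, lr_t, betas[1], betas[2], eps,
                  model$adam_t)
    }
  }
  invisible(losses)
}

#' Save / load model weights
#'
#' Weights are serialized with the configuration in R's native RDS format.
#'
#' @param model Model environment.
#' @param path Checkpoint path (`.rds`).
#' @export
save_weights <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  ck <- readRDS(path)
  model <- build_bianquenet(ck$config)
  model$params <- ck$params
  model
}
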