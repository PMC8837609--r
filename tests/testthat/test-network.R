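test_that("network configuration enforces the downsampling contract", {
  expect_error(net_config(input_size = c(60, 64)), "divisible by 16")
  expect_silent(net_config(input_size = c(96, 64)))
  expect_error(net_config(reduction = 0), "reduction")
})

test_that("tiny forward pass emits per-pixel probabilities at input size", {
  model <- build_bianquenet(net_config(input_size = c(64, 64), seed = 1))
  img <- matrix(runif(64 * 64), 64)
  p <- predict_bianquenet(model, img)
  expect_equal(dim(p), c(64, 64, 14))
  sums <- apply(p, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
  # rebuilding with the same seed reproduces the same prediction
  model2 <- build_bianquenet(net_config(input_size = c(64, 64), seed = 1))
  expect_equal(predict_bianquenet(model2, img), p)
})

test_that("output follows input size for other 16-divisible shapes", {
  model <- build_bianquenet(net_config(input_size = c(32, 48), seed = 2))
  p <- predict_bianquenet(model, matrix(runif(32 * 48), 32))
  expect_equal(dim(p), c(32, 48, 14))
})

test_that("skip module reduces channels by 1/8 and fuses two paths", {
  set.seed(3)
  x <- array(rnorm(16 * 16 * 32), c(16, 16, 32))
  y <- st_sc_forward(x, window = 4, heads = 2, seed = 9)
  expect_equal(dim(y), c(16, 16, 4))
  expect_true(all(is.finite(y)))

  # zeroed attention/MLP weights: the module degenerates to its residual
  # and projection paths but stays finite
  mod <- attr(st_sc_forward(x, seed = 9), "module")
  for (nm in names(mod$params)) {
    if (grepl("\\.(q|k|v|o|mlp)", nm)) {
      mod$params[[nm]] <- mod$params[[nm]] * 0
    }
  }
  y0 <- st_sc_forward(x, weights = mod)
  expect_true(all(is.finite(y0)))
})

test_that("shifted and regular windows differ except on constant input", {
  mdl <- new.env(); mdl$params <- list()
  set.seed(4)
  ivdquant:::build_swin_block(mdl, "b", 8, 2)
  run <- function(x, shift) {
    tape <- ivdquant:::nn_tape()
    ctx <- ivdquant:::fwd_ctx(mdl, tape)
    out <- ivdquant:::fwd_swin_block(ctx, "b", ivdquant:::op_const(tape, x),
                                     ws = 4, heads = 2, shift = shift)
    out$value
  }
  xr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_gt(max(abs(run(xr, 0) - run(xr, 2))), 1e-6)
  xc <- array(1.7, c(8, 8, 8))
  expect_equal(run(xc, 0), run(xc, 2), tolerance = 1e-10)
})

test_that("window partition errors on indivisible maps", {
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  expect_error(st_sc_forward(x, window = 4), "divisible")
})

test_that("weighted dice loss honours the channel weighting", {
  # perfect one-hot prediction: zero loss
  mask <- matrix(sample(0:13, 16 * 16, TRUE), 16)
  oh <- one_hot_mask(mask)
  expect_equal(weighted_dice_loss(oh, oh), 0)

  # prediction disjoint on every channel: per-channel dice 0, so the loss
  # is the mean channel weight (5*0.9 + 5*0.8 + 4*1) / 14
  truth <- matrix(rep(0:13, each = 14), 14, 14)
  pred_lab <- (truth + 1) %% 14
  l <- weighted_dice_loss(one_hot_mask(pred_lab), one_hot_mask(truth))
  expect_equal(l, 12.5 / 14)

  # with unit weights the loss is 1 - mean per-class dice of the masks
  xi1 <- rep(1, 14)
  p <- matrix(sample(0:13, 400, TRUE), 20)
  g <- matrix(sample(0:13, 400, TRUE), 20)
  expect_equal(weighted_dice_loss(one_hot_mask(p), one_hot_mask(g), xi1),
               1 - mdice(p, g), tolerance = 1e-6)
  expect_error(weighted_dice_loss(oh, oh[1:8, , ]), "shape")
  expect_error(weighted_dice_loss(oh, oh, xi = c(1, 2)), "per channel")
})

test_that("loss and layer gradients match finite differences", {
  set.seed(10)
  oh <- one_hot_mask(matrix(sample(0:3, 64, TRUE), 8), 4)
  pr <- array(runif(8 * 8 * 4) + 0.05, c(8, 8, 4))
  xi <- c(1, 0.9, 0.8, 1)
  tape <- ivdquant:::nn_tape()
  pn <- ivdquant:::nn_node(tape, pr)
  loss <- ivdquant:::op_weighted_dice(pn, oh, xi)
  ivdquant:::nn_backward(tape, loss)
  fval <- function(pv) {
    t2 <- ivdquant:::nn_tape()
    as.numeric(ivdquant:::op_weighted_dice(ivdquant:::nn_node(t2, pv),
                                           oh, xi)$value)
  }
  num <- array(0, dim(pr))
  idx <- sample(length(pr), 40)
  for (i in idx) {
    e <- 1e-6
    up <- pr; up[i] <- up[i] + e
    dn <- pr; dn[i] <- dn[i] - e
    num[i] <- (fval(up) - fval(dn)) / (2 * e)
  }
  expect_lt(max(abs(pn$grad[idx] - num[idx])), 1e-6)

  # convolution gradient (weights) by finite differences
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  proj <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  tape <- ivdquant:::nn_tape()
  xn <- ivdquant:::nn_node(tape, x)
  wn <- ivdquant:::nn_node(tape, w)
  out <- ivdquant:::op_conv2d(xn, wn)
  loss <- ivdquant:::nn_node(tape, array(sum(out$value * proj), 1),
    local({
      o <- out
      function(g) ivdquant:::acc_grad(o, array(as.numeric(g) * proj,
                                               dim(o$value)))
    }))
  ivdquant:::nn_backward(tape, loss)
  fw <- function(wv) {
    t2 <- ivdquant:::nn_tape()
    sum(ivdquant:::op_conv2d(ivdquant:::nn_node(t2, x),
                             ivdquant:::nn_node(t2, wv))$value * proj)
  }
  for (i in sample(length(w), 10)) {
    e <- 1e-6
    up <- w; up[i] <- up[i] + e
    dn <- w; dn[i] <- dn[i] - e
    expect_lt(abs(wn$grad[i] - (fw(up) - fw(dn)) / (2 * e)), 1e-5)
  }
})

test_that("a few optimization steps reduce the loss and stay finite", {
  sp <- tiny_phantom_spec(noise_sd = 2)
  ph <- generate_phantom(sp)
  model <- build_bianquenet(net_config(seed = 42))
  losses <- train_bianquenet(model, ph$image,
                             matrix(as.integer(ph$mask), 64), steps = 12)
  expect_true(all(is.finite(losses)))
  expect_lt(losses[12], losses[1])
  grads_finite <- all(vapply(model$params, function(p) all(is.finite(p)),
                             logical(1)))
  expect_true(grads_finite)
})

test_that("weights survive a checkpoint round-trip", {
  model <- build_bianquenet(net_config(seed = 5))
  img <- matrix(runif(64 * 64), 64)
  p1 <- predict_bianquenet(model, img)
  ck <- tempfile(fileext = ".rds")
  save_weights(model, ck)
  p2 <- predict_bianquenet(load_weights(ck), img)
  expect_equal(p1, p2)
  lab <- segment_image(model, img)
  expect_true(all(lab %in% 0:13))
})
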