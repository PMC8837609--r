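test_that("corners of an axis-aligned rectangle get roles and positions", {
  x <- render_rect(40, 20, 0, nr = 60, nc = 80)
  cs <- detect_vb_corners(x$region)
  for (k in c("sa", "sp", "ia", "ip")) {
    expect_lt(sqrt(sum((cs[[k]] - x$vertices[k, ])^2)), 1.5)
  }
  expect_lt(cs$sa[1], cs$ia[1])
  expect_lt(cs$sa[2], cs$sp[2])
  expect_equal(cs$ma, (cs$sa + cs$ia) / 2)
})

test_that("corner roles survive rotation within tolerance", {
  for (th in c(5, 10, 15)) {
    x <- render_rect(40, 20, th, nr = 90, nc = 90)
    cs <- detect_vb_corners(x$region)
    for (k in c("sa", "sp", "ia", "ip")) {
      expect_lt(sqrt(sum((cs[[k]] - x$vertices[k, ])^2)), 1.5)
    }
  }
})

test_that("a disk has no admissible corners", {
  rr <- matrix(rep(1:60, 60), 60)
  cc <- matrix(rep(1:60, each = 60), 60)
  disk <- (rr - 30)^2 + (cc - 30)^2 < 20^2
  expect_error(detect_vb_corners(disk), "corner-detection error")
})

test_that("vertebral diameter is the midpoint distance", {
  cs <- make_corners(sa = c(0, 0), sp = c(0, 39), ia = c(19, 0),
                     ip = c(19, 39))
  expect_equal(vertebral_diameter(cs), 39)
  cs2 <- make_corners(sa = c(-1, -1), sp = c(2, 3), ia = c(1, 1),
                      ip = c(4, 5))   # midpoints (0,0) and (3,4)
  expect_equal(vertebral_diameter(cs2), 5)
  expect_equal(vertebral_diameter(cs, spacing = 0.5), 19.5)
})

test_that("vertebral height is area over diameter (Eq identity)", {
  x <- render_rect(40, 20, 0, nr = 60, nc = 80)
  expect_equal(vertebral_height(x$region, 39), 800 / 39)
  expect_equal(vertebral_height(x$region, sum(x$region)), 1)
  expect_error(vertebral_height(x$region, 0), "positive")
  # identity VH * VD = area for arbitrary regions and diameters
  set.seed(3)
  for (i in 1:20) {
    reg <- matrix(runif(400) < 0.4, 20, 20)
    vd <- runif(1, 1, 50)
    expect_equal(vertebral_height(reg, vd) * vd, sum(reg))
  }
})

# stacked scene: upper body, disc, lower body, all axis-aligned
stacked_scene <- function(disc_w = 50, disc_h = 12, vb_w = 50, vb_h = 20,
                          gap = 0, nr = 90, nc = 80, disc = "rect") {
  cc <- 40.5
  upper <- render_rect(vb_w, vb_h, 0, nr, nc, centre = c(15.5, cc))
  r0 <- 25.5 + gap + disc_h / 2
  if (disc == "rect") {
    dreg <- render_rect(disc_w, disc_h, 0, nr, nc, centre = c(r0, cc))$region
  } else {
    rr <- matrix(rep(1:nr, nc), nr); c2 <- matrix(rep(1:nc, each = nr), nr)
    dreg <- ((rr - r0) / (disc_h / 2))^2 + ((c2 - cc) / (disc_w / 2))^2 < 1
  }
  lower <- render_rect(vb_w, vb_h, 0, nr, nc,
                       centre = c(25.5 + gap * 2 + disc_h + vb_h / 2, cc))
  list(upper = detect_vb_corners(upper$region),
       lower = detect_vb_corners(lower$region),
       upper_reg = upper$region, lower_reg = lower$region, disc = dreg)
}

test_that("disc landmarks of a rectangular disc are the edge midpoints", {
  sc <- stacked_scene()
  lm <- disc_landmarks(sc$disc, sc$upper, sc$lower,
                       upper_region = sc$upper_reg,
                       lower_region = sc$lower_reg)
  expect_equal(lm$diameter, 49)
  expect_equal(lm$max_diameter, 49)
  # anterior/posterior midpoints at mid-height of the vertical edges
  expect_equal(lm$da[2], min(which(colSums(sc$disc) > 0)))
  expect_equal(lm$dp[2], max(which(colSums(sc$disc) > 0)))
  expect_equal(lm$da[1], lm$dp[1])
})

test_that("elliptical disc max diameter is the major axis", {
  sc <- stacked_scene(disc = "ellipse")
  lm <- disc_landmarks(sc$disc, sc$upper, sc$lower,
                       upper_region = sc$upper_reg,
                       lower_region = sc$lower_reg)
  expect_lt(abs(lm$max_diameter - 49), 1)
})

test_that("a background gap beyond tolerance raises an adjacency error", {
  sc <- stacked_scene(gap = 5)
  expect_error(disc_landmarks(sc$disc, sc$upper, sc$lower,
                              upper_region = sc$upper_reg,
                              lower_region = sc$lower_reg),
               "adjacency error")
  expect_silent(disc_landmarks(sc$disc, sc$upper, sc$lower,
                               adjacency_tol = 12,
                               upper_region = sc$upper_reg,
                               lower_region = sc$lower_reg))
})

test_that("disc height counts the central band (pixel oracle)", {
  sc <- stacked_scene()
  lm <- disc_landmarks(sc$disc, sc$upper, sc$lower)
  res <- disc_height(sc$disc, lm, mu = 0.8)
  # oracle: explicit count of pixels in the central 80% of the diameter
  px <- which(sc$disc, arr.ind = TRUE)
  t <- px[, 2] - lm$da[2]
  inband <- abs(t - 49 / 2) <= 0.8 * 49 / 2
  expect_equal(res$area_central, sum(inband))
  expect_equal(res$area_central, 480)
  expect_equal(res$dh, 480 / (0.8 * 49))

  res1 <- disc_height(sc$disc, lm, mu = 1)
  expect_equal(res1$dh, 600 / 49)

  # elliptical disc: mean central height below the maximal (minor-axis) height
  sce <- stacked_scene(disc = "ellipse")
  lme <- disc_landmarks(sce$disc, sce$upper, sce$lower,
                        upper_region = sce$upper_reg,
                        lower_region = sce$lower_reg)
  rese <- disc_height(sce$disc, lme, mu = 0.8)
  expect_lt(rese$dh, 12)
})

test_that("DHI and HDR are unit-free ratios", {
  expect_equal(disc_height_index(10, 20, 30), 0.4)
  expect_equal(disc_height_index(25, 25, 25), 1)
  expect_error(disc_height_index(10, 0, 0), "denominator")
  expect_equal(disc_hdr(12, 48), 0.25)
  expect_equal(disc_hdr(7, 7), 1)
  expect_error(disc_hdr(12, 0), "diameter")
  # doubling the spacing rescales DH but cancels in DHI
  expect_equal(disc_height_index(10 * 2, 20 * 2, 30 * 2),
               disc_height_index(10, 20, 30))
})

test_that("measure_spine recovers phantom truth on the healthy scene", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  m <- measure_spine(ph$image, ph$mask)
  expect_true(all(!is.na(m$discs$DH)))
  expect_identical(m$flags, "l5s1_dhi_uses_l5_only")
  tr <- ph$truth
  expect_true(all(abs(m$vertebrae$VD - tr$vertebrae$VD) /
                    tr$vertebrae$VD < 0.02))
  expect_true(all(abs(m$vertebrae$VH - tr$vertebrae$VH) /
                    tr$vertebrae$VH < 0.03))
  expect_true(all(abs(m$discs$DH - tr$discs$DH) / tr$discs$DH < 0.05))
})

test_that("missing CSF still yields geometry with a flag", {
  ph <- generate_phantom(phantom_spec())
  mask2 <- matrix(as.integer(ph$mask), nrow(ph$mask))
  mask2[mask2 == ivd_class_map()[["CSF"]]] <- 0L
  m <- measure_spine(ph$image, label_mask(mask2))
  expect_true(all(is.na(m$discs$delta_si)))
  expect_true(any(grepl("absent:CSF", m$flags)))
  expect_true(all(!is.na(m$discs$DH)))
})

test_that("pixel spacing scales lengths and leaves ratios unchanged", {
  ph <- generate_phantom(phantom_spec())
  m1 <- measure_spine(ph$image, ph$mask)
  m2 <- measure_spine(ph$image, ph$mask, quant_config(spacing = 0.6))
  expect_equal(m2$discs$DH, m1$discs$DH * 0.6)
  expect_equal(m2$vertebrae$VD, m1$vertebrae$VD * 0.6)
  expect_equal(m2$discs$DHI, m1$discs$DHI)
  expect_equal(m2$discs$HDR, m1$discs$HDR)
})

test_that("disc height is stable under whole-scene rotation", {
  base <- measure_spine_truth_err <- NULL
  m0 <- measure_spine(generate_phantom(phantom_spec())$image,
                      generate_phantom(phantom_spec())$mask)
  for (th in c(7, 15)) {
    ph <- generate_phantom(phantom_spec(tilt_deg = th))
    m <- measure_spine(ph$image, ph$mask)
    expect_true(all(abs(m$discs$DH - m0$discs$DH) / m0$discs$DH <= 0.02))
  }
})

test_that("shrinking the disc monotonically shrinks DH, DHI and HDR", {
  heights <- c(14, 11, 8, 5)
  vals <- t(vapply(heights, function(h) {
    ph <- generate_phantom(phantom_spec(disc_size = c(84, h)))
    m <- measure_spine(ph$image, ph$mask)
    c(m$discs$DH[2], m$discs$DHI[2], m$discs$HDR[2])
  }, numeric(3)))
  expect_true(all(diff(vals[, 1]) < 0))
  expect_true(all(diff(vals[, 2]) < 0))
  expect_true(all(diff(vals[, 3]) < 0))
})
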