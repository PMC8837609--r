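#' Synthetic sagittal lumbar spine phantom specification
#'
#' Describes a seeded synthetic mid-sagittal lumbar scene: five stacked
#' vertebral bodies (L1-L5) with five intervertebral discs between and below
#' them, a tilted sacrum block under the L5/S1 disc, a presacral fat blob
#' anterior to the sacrum, and a bright CSF band posterior to the column.
#' Anterior is the low-column-index (left) side by default. Every structure
#' is an analytic shape rendered by a pixel-center inclusion test, so all
#' quantitation parameters have closed-form ground truth.
#'
#' Discs are rendered with a two-component intensity model: a centered inner
#' nucleus region covering `nucleus_frac` of the disc area at `np_intensity`,
#' surrounded by an annulus at `af_intensity`. A healthy disc therefore has a
#' bimodal intensity histogram, the property the signal-intensity method
#' relies on.
#'
#' `tilt_deg` rotates the whole column rigidly about the scene centre, which
#' tilts every structure while preserving disc-vertebra adjacency; the sacrum
#' additionally carries its own tilt (`sacrum_tilt_deg`).
#'
#' @param image_size `(rows, cols)` of the output image, default `c(384, 256)`.
#' @param n_vertebrae Number of lumbar vertebral bodies (fixed at 5; the
#'   class map has exactly five vertebra and five disc classes).
#' @param vb_size `(width, height)` of each vertebral body in px.
#' @param disc_size `(width, height)` of each disc in px.
#' @param disc_shape One of `"rectangle"`, `"ellipse"`, `"rounded"` (stadium).
#' @param np_intensity,af_intensity Nucleus pulposus / annulus fibrosus
#'   signal intensities; healthy presets require `np > af`.
#' @param csf_intensity CSF band intensity (the normalization reference).
#' @param vb_intensity,sacrum_intensity,fat_intensity,bg_intensity Remaining
#'   tissue intensities.
#' @param nucleus_frac Fraction of disc area covered by the nucleus, default
#'   0.5 so the two histogram peaks have comparable mass.
#' @param noise_sd SD of additive Gaussian intensity noise (clipped at 0).
#' @param tilt_deg Rigid rotation of the whole column, degrees.
#' @param sacrum_tilt_deg Extra rotation of the sacrum about its own centre.
#' @param anterior_left If `FALSE`, the scene is mirrored so anterior is the
#'   high-column side.
#' @param seed Integer seed controlling the noise draw.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(image_size = c(384, 256),
                         n_vertebrae = 5,
                         vb_size = c(76, 40),
                         disc_size = c(84, 14),
                         disc_shape = c("rectangle", "ellipse", "rounded"),
                         np_intensity = 180,
                         af_intensity = 60,
                         csf_intensity = 200,
                         vb_intensity = 100,
                         sacrum_intensity = 95,
                         fat_intensity = 230,
                         bg_intensity = 5,
                         nucleus_frac = 0.5,
                         noise_sd = 0,
                         tilt_deg = 0,
                         sacrum_tilt_deg = 5,
                         anterior_left = TRUE,
                         seed = 1L) {
  disc_shape <- match.arg(disc_shape)
  spec <- list(
    image_size = as.numeric(image_size), n_vertebrae = as.integer(n_vertebrae),
    vb_size = as.numeric(vb_size), disc_size = as.numeric(disc_size),
    disc_shape = disc_shape,
    np_intensity = np_intensity, af_intensity = af_intensity,
    csf_intensity = csf_intensity, vb_intensity = vb_intensity,
    sacrum_intensity = sacrum_intensity, fat_intensity = fat_intensity,
    bg_intensity = bg_intensity, nucleus_frac = nucleus_frac,
    noise_sd = noise_sd, tilt_deg = tilt_deg,
    sacrum_tilt_deg = sacrum_tilt_deg,
    anterior_left = isTRUE(anterior_left), seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Phantom presets
#'
#' `"healthy"` is the default bright, tall-disc scene; `"degenerate"` has a
#' collapsed disc height and a nucleus intensity close to the annulus, so the
#' disc histogram peaks nearly merge.
#'
#' @param preset `"healthy"` or `"degenerate"`.
#' @param ... Overrides passed to [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("healthy", "degenerate"), ...) {
  preset <- match.arg(preset)
  if (preset == "healthy") return(phantom_spec(...))
  args <- list(np_intensity = 75, disc_size = c(84, 6), ...)
  do.call(phantom_spec, args[!duplicated(names(args))])
}

validate_phantom_spec <- function(spec) {
  if (spec$n_vertebrae != 5L) {
    stop("layout error: the 14-class map requires exactly 5 vertebral bodies")
  }
  if (any(c(spec$image_size, spec$vb_size, spec$disc_size) <= 0)) {
    stop("layout error: all sizes must be positive")
  }
  if (spec$np_intensity < spec$af_intensity || spec$af_intensity < 0) {
    stop("np_intensity must be >= af_intensity >= 0")
  }
  if (spec$nucleus_frac <= 0 || spec$nucleus_frac >= 1) {
    stop("nucleus_frac must lie in (0, 1)")
  }
  lay <- phantom_layout(spec)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  th <- spec$tilt_deg * pi / 180
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  for (s in lay) {
    ex <- s$extra_tilt %||% 0
    # rotated bounding half-extents about the scene centre
    vtx <- shape_vertices(s, extra_tilt = ex)
    vtx <- rotate_points(vtx, th, ctr)
    if (any(vtx[, 1] < 0.5) || any(vtx[, 1] > nr + 0.5) ||
        any(vtx[, 2] < 0.5) || any(vtx[, 2] > nc + 0.5)) {
      stop("layout error: structure '", s$role,
           "' does not fit inside the image")
    }
  }
  # pairwise overlap in the unrotated frame (rigid rotation preserves it);
  # tilted shapes use their rotated-vertex bounding box
  n <- length(lay)
  bboxes <- lapply(lay, function(s) {
    v <- shape_vertices(s, extra_tilt = s$extra_tilt %||% 0)
    c(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
  })
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (rect_overlap(bboxes[[i]], bboxes[[j]])) {
      stop("layout error: structures '", lay[[i]]$role, "' and '",
           lay[[j]]$role, "' overlap")
    }
  }
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rect_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

# Axis-aligned layout: list of shapes with centre (row, col), size (w, h),
# kind, role, class id, intensity. Centres sit on the half-integer grid so
# axis-aligned rendering covers exactly w x h pixel centres; all auxiliary
# structure sizes scale with the vertebra/disc dimensions so the same scene
# renders from thumbnail (64 px) to full size.
phantom_layout <- function(spec) {
  cm <- ivd_class_map()
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  wv <- spec$vb_size[1]; hv <- spec$vb_size[2]
  wd <- spec$disc_size[1]; hd <- spec$disc_size[2]
  col_c <- round(0.375 * nc) + 0.5
  top <- max(2, round(0.048 * nr))
  block <- hv + hd
  shapes <- list()
  for (i in 1:5) {
    vb_rc <- top + (i - 1) * block + hv / 2 + 0.5
    shapes[[length(shapes) + 1]] <- list(
      kind = "rectangle", role = vb_roles()[i], id = cm[[vb_roles()[i]]],
      centre = c(vb_rc, col_c), w = wv, h = hv,
      intensity = spec$vb_intensity)
    disc_rc <- top + (i - 1) * block + hv + hd / 2 + 0.5
    shapes[[length(shapes) + 1]] <- list(
      kind = spec$disc_shape, role = disc_roles()[i],
      id = cm[[disc_roles()[i]]],
      centre = c(disc_rc, col_c), w = wd, h = hd,
      intensity = spec$af_intensity, nucleus = TRUE)
  }
  stack_bottom <- top + 5 * block + 0.5   # last covered row + 0.5
  sac_h <- round(0.7 * hv); sac_w <- round(0.84 * wv)
  ts <- spec$sacrum_tilt_deg * pi / 180
  # place the sacrum so its rotated superior edge sits just under the
  # L5/S1 disc (within the 3 px adjacency tolerance, without overlap)
  rise <- (sac_h / 2) * cos(ts) + (sac_w / 2) * abs(sin(ts))
  shapes[[length(shapes) + 1]] <- list(
    kind = "rectangle", role = "SACRUM", id = cm[["SACRUM"]],
    centre = c(stack_bottom + rise + 0.5, col_c), w = sac_w, h = sac_h,
    intensity = spec$sacrum_intensity, extra_tilt = spec$sacrum_tilt_deg)
  shapes[[length(shapes) + 1]] <- list(
    kind = "ellipse", role = "PRESACRAL_FAT", id = cm[["PRESACRAL_FAT"]],
    centre = c(stack_bottom + round(0.6 * hv),
               col_c - sac_w / 2 - round(0.32 * wv)),
    w = round(0.37 * wv), h = round(0.6 * hv),
    intensity = spec$fat_intensity)
  csf_ext <- min(24, 2 * (top - 1))
  shapes[[length(shapes) + 1]] <- list(
    kind = "rectangle", role = "CSF", id = cm[["CSF"]],
    centre = c(top + 5 * block / 2 + 0.5,
               col_c + wd / 2 + round(wd / 6) + 0.5),
    w = max(4, round(nc / 15)), h = 5 * block + csf_ext,
    intensity = spec$csf_intensity)
  shapes
}

shape_bbox <- function(s) {
  c(s$centre[1] - s$h / 2, s$centre[2] - s$w / 2,
    s$centre[1] + s$h / 2, s$centre[2] + s$w / 2)
}

# corner vertices of a shape's bounding rectangle in its own frame,
# optionally rotated about its own centre (matrix n x 2 of (row, col))
shape_vertices <- function(s, extra_tilt = 0) {
  v <- rbind(
    c(s$centre[1] - s$h / 2, s$centre[2] - s$w / 2),
    c(s$centre[1] - s$h / 2, s$centre[2] + s$w / 2),
    c(s$centre[1] + s$h / 2, s$centre[2] - s$w / 2),
    c(s$centre[1] + s$h / 2, s$centre[2] + s$w / 2))
  if (extra_tilt != 0) v <- rotate_points(v, extra_tilt * pi / 180, s$centre)
  v
}

# rotate points (n x 2, (row, col)) by theta radians about ctr; image rows
# grow downward so a positive theta is a clockwise tilt on screen
rotate_points <- function(p, theta, ctr) {
  dr <- p[, 1] - ctr[1]; dc <- p[, 2] - ctr[2]
  cbind(ctr[1] + cos(theta) * dr - sin(theta) * dc,
        ctr[2] + sin(theta) * dr + cos(theta) * dc)
}

#' Generate a seeded phantom sample with analytic truth
#'
#' Renders the scene of a [phantom_spec()] into an intensity image and a
#' 14-class label mask, and returns the closed-form ground truth of every
#' quantitation parameter. Truth is a function of the spec alone (continuous
#' geometry, noiseless intensity model); it is never measured on the
#' rendered mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `image` (numeric
#'   matrix), `mask` (an `ivd_label_mask`), `truth` (list with `vertebrae`
#'   and `discs` data frames, per-vertebra `corners`, and scalars), and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' ph$truth$discs$delta_si[1]   # (180 - 60) / 200 * 255 = 153
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  lay <- phantom_layout(spec)
  th <- spec$tilt_deg * pi / 180
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)

  # inverse-rotate every pixel centre once; structures then test their
  # axis-aligned shape in the unrotated frame
  rr <- matrix(rep(seq_len(nr), nc), nr)
  cc <- matrix(rep(seq_len(nc), each = nr), nr)
  ur <- ctr[1] + cos(th) * (rr - ctr[1]) + sin(th) * (cc - ctr[2])
  uc <- ctr[2] - sin(th) * (rr - ctr[1]) + cos(th) * (cc - ctr[2])

  mask <- matrix(0L, nr, nc)
  img <- matrix(spec$bg_intensity, nr, nc)
  sf <- sqrt(spec$nucleus_frac)
  for (s in lay) {
    p <- cbind(as.vector(ur), as.vector(uc))
    if (!is.null(s$extra_tilt) && s$extra_tilt != 0) {
      p <- rotate_points(p, -s$extra_tilt * pi / 180, s$centre)
    }
    inside <- shape_inside(p, s, 1)
    mask[inside] <- s$id
    img[inside] <- s$intensity
    if (isTRUE(s$nucleus)) {
      img[shape_inside(p, s, sf)] <- spec$np_intensity
    }
  }
  if (!spec$anterior_left) {
    mask <- mask[, rev(seq_len(nc))]
    img <- img[, rev(seq_len(nc))]
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr), 0)
  }
  truth <- phantom_truth(spec)
  structure(list(image = img, mask = label_mask(mask),
                 truth = truth, spec = spec),
            class = "phantom_sample")
}

# inclusion test of points (n x 2, unrotated frame) in shape s scaled by f
shape_inside <- function(p, s, f) {
  dr <- p[, 1] - s$centre[1]; dc <- p[, 2] - s$centre[2]
  w <- s$w * f; h <- s$h * f
  inside <- switch(s$kind,
    rectangle = abs(dr) < h / 2 & abs(dc) < w / 2,
    ellipse = (dr / (h / 2))^2 + (dc / (w / 2))^2 < 1,
    rounded = {
      r <- h / 2
      straight <- abs(dc) <= w / 2 - r
      (straight & abs(dr) < r) |
        (!straight & (abs(dc) - (w / 2 - r))^2 + dr^2 < r^2)
    })
  inside
}

# closed-form analytic DH of a disc shape of width w, height h at band mu
analytic_dh <- function(shape, w, h, mu = 0.8) {
  switch(shape,
    rectangle = h,
    ellipse = {
      b <- h / 2
      b * (asin(mu) + mu * sqrt(1 - mu^2)) / mu
    },
    rounded = {
      r <- h / 2
      if (mu * w / 2 > w / 2 - r) {
        # band reaches into the circular caps: straight part + 2 segments
        x0 <- w / 2 - r               # cap centre offset
        x1 <- mu * w / 2              # band edge
        seg <- function(x) x * sqrt(pmax(r^2 - x^2, 0)) +
          r^2 * asin(pmin(pmax(x / r, -1), 1))
        area <- 2 * x0 * h + 2 * (seg(x1 - x0) - seg(0))
        area / (mu * w)
      } else h
    })
}

# ground truth for every structure, in final (possibly mirrored) coordinates
phantom_truth <- function(spec) {
  lay <- phantom_layout(spec)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  th <- spec$tilt_deg * pi / 180
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  mirror <- function(p) {
    if (!spec$anterior_left) cbind(p[, 1], nc + 1 - p[, 2]) else p
  }
  wv <- spec$vb_size[1]; hv <- spec$vb_size[2]
  wd <- spec$disc_size[1]; hd <- spec$disc_size[2]
  corners <- list()
  for (s in lay) {
    if (s$role %in% c(vb_roles(), "SACRUM")) {
      v <- shape_vertices(s, extra_tilt = s$extra_tilt %||% 0)
      v <- mirror(rotate_points(v, th, ctr))
      # rows of v: (sup,ant),(sup,post),(inf,ant),(inf,post); mirroring
      # moves the anterior side with the scene, so the labels are fixed
      rownames(v) <- c("sa", "sp", "ia", "ip")
      corners[[s$role]] <- v
    }
  }
  vb <- data.frame(
    role = vb_roles(),
    VD = wv, VH = hv, area = wv * hv,
    stringsAsFactors = FALSE)
  dh <- analytic_dh(spec$disc_shape, wd, hd)
  dsi <- if (spec$np_intensity > spec$af_intensity) {
    (spec$np_intensity - spec$af_intensity) / spec$csf_intensity * 255
  } else 0
  discs <- data.frame(
    role = disc_roles(), segment = disc_segments(),
    diameter = wd, max_diameter = wd,
    area = switch(spec$disc_shape,
                  rectangle = wd * hd,
                  ellipse = pi * wd * hd / 4,
                  rounded = (wd - hd) * hd + pi * (hd / 2)^2),
    DH = dh,
    DHI = 2 * dh / (2 * hv),
    HDR = dh / wd,
    delta_si = dsi,
    stringsAsFactors = FALSE)
  areas <- stats::setNames(vapply(lay, function(s) {
    switch(s$kind, rectangle = s$w * s$h, ellipse = pi * s$w * s$h / 4,
           rounded = (s$w - s$h) * s$h + pi * (s$h / 2)^2)
  }, numeric(1)), vapply(lay, function(s) s$role, character(1)))
  list(vertebrae = vb, discs = discs, corners = corners, areas = areas)
}

#' Generate a monotone degeneration series of phantoms
#'
#' Interpolates linearly from a healthy to a collapsed preset: the nucleus
#' intensity falls toward the annulus intensity (shrinking the histogram
#' peak separation) and the disc height collapses. Along the series the true
#' peak-difference signal intensity strictly decreases and the true disc
#' height is non-increasing, emulating progressive degeneration grades.
#'
#' @param spec Base (healthy-end) [phantom_spec()].
#' @param n_steps Number of samples, at least 2.
#' @param end_spec Collapsed-end spec; defaults to
#'   `phantom_preset("degenerate")` carrying over `spec`'s noise and seed.
#' @return List of `phantom_sample`, healthy first.
#' @export
degeneration_series <- function(spec = phantom_spec(), n_steps = 5,
                                end_spec = NULL) {
  stopifnot(n_steps >= 2)
  if (is.null(end_spec)) {
    end_spec <- phantom_preset("degenerate", noise_sd = spec$noise_sd,
                               seed = spec$seed, tilt_deg = spec$tilt_deg)
  }
  lapply(seq_len(n_steps), function(k) {
    t <- (k - 1) / (n_steps - 1)
    s <- spec
    s$np_intensity <- (1 - t) * spec$np_intensity + t * end_spec$np_intensity
    s$disc_size[2] <- (1 - t) * spec$disc_size[2] + t * end_spec$disc_size[2]
    s$seed <- spec$seed + k - 1L
    generate_phantom(s)
  })
}
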