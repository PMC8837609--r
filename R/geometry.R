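# Small separable convolution helpers (zero padding). Kernels are short
# (<= 7 taps), so shifting-and-adding whole matrices is fast in R.

conv_dim <- function(x, k, margin) {
  half <- (length(k) - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    off <- j - 1 - half
    if (k[j] == 0) next
    if (margin == 1) {
      src <- max(1, 1 - off):min(nr, nr - off)
      out[src + off, ] <- out[src + off, ] + k[j] * x[src, ]
    } else {
      src <- max(1, 1 - off):min(nc, nc - off)
      out[, src + off] <- out[, src + off] + k[j] * x[, src]
    }
  }
  out
}

gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Detect the four vertebral body corners (Shi-Tomasi)
#'
#' Runs minimum-eigenvalue (Shi-Tomasi) corner detection on the binary
#' region of a vertebral body and assigns the four anatomical roles
#' (superior-anterior `sa`, superior-posterior `sp`, inferior-anterior `ia`,
#' inferior-posterior `ip`) by proximity to the bounding-box vertices in the
#' orientation frame (anterior = low column index by default). Detected
#' response maxima are snapped to the nearby region boundary pixel farthest
#' from the centroid, which pins the corner onto the actual vertex of the
#' (convex) body outline.
#'
#' @param region Logical matrix, one roughly quadrilateral structure.
#' @param max_corners Maximum number of candidate corners kept.
#' @param quality Candidate threshold as a fraction of the maximum corner
#'   response.
#' @param min_dist Minimum distance between retained candidates (px).
#' @param min_response Absolute floor on the corner response. The response
#'   of a right-angle corner of a binary region is a scale-free constant
#'   (about 0.02 with the default smoothing), while smoothly curved
#'   boundaries (disks) stay well below 0.005; the floor rejects regions
#'   without true corners.
#' @param anterior_left Orientation convention flag.
#' @param snap_radius Radius (px) of the boundary snap; 0 disables it.
#' @return A list of class `corner_set`: points `sa`, `sp`, `ia`, `ip` and
#'   the derived anterior/posterior edge midpoints `ma`, `mp`, each a
#'   `(row, col)` vector.
#' @export
detect_vb_corners <- function(region, max_corners = 10, quality = 0.05,
                              min_dist = 5, min_response = 0.008,
                              anterior_left = TRUE, snap_radius = 2.5) {
  if (!any(region)) stop("corner-detection error: empty region")
  # crop to the region bounding box (plus filter margin): the structure
  # tensor is local, so the response is unchanged and the cost drops from
  # image size to structure size
  px <- which(region, arr.ind = TRUE)
  mar <- 8L
  r0 <- max(1L, min(px[, 1]) - mar); r1 <- min(nrow(region), max(px[, 1]) + mar)
  c0 <- max(1L, min(px[, 2]) - mar); c1 <- min(ncol(region), max(px[, 2]) + mar)
  off <- c(r0 - 1L, c0 - 1L)
  region <- region[r0:r1, c0:c1, drop = FALSE]
  f <- matrix(as.numeric(region), nrow(region))
  g1 <- gauss_kernel(1)
  f <- conv_dim(conv_dim(f, g1, 1), g1, 2)
  # Sobel derivatives (separable)
  ix <- conv_dim(conv_dim(f, c(1, 2, 1) / 4, 1), c(-1, 0, 1) / 2, 2)
  iy <- conv_dim(conv_dim(f, c(1, 2, 1) / 4, 2), c(-1, 0, 1) / 2, 1)
  g2 <- gauss_kernel(1.5)
  sm <- function(m) conv_dim(conv_dim(m, g2, 1), g2, 2)
  sxx <- sm(ix * ix); syy <- sm(iy * iy); sxy <- sm(ix * iy)
  resp <- (sxx + syy) / 2 - sqrt(((sxx - syy) / 2)^2 + sxy^2)
  if (max(resp) < min_response) {
    stop("corner-detection error: no corner-like response in region")
  }
  thr <- max(quality * max(resp), min_response)
  nr <- nrow(resp); nc <- ncol(resp)
  # 3x3 local maxima above threshold
  cand <- which(resp >= thr, arr.ind = TRUE)
  if (nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      nb <- resp[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      resp[r, c] >= max(nb)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) stop("corner-detection error: no corner response")
  vals <- resp[cand]
  ord <- order(vals, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_corners) break
    if (all(sqrt((cand[i, 1] - cand[sel, 1])^2 +
                 (cand[i, 2] - cand[sel, 2])^2) >= min_dist)) {
      sel <- c(sel, i)
    }
  }
  pts <- cand[sel, , drop = FALSE]
  bnd <- boundary_points(region)
  ctr <- c(mean(which(region, arr.ind = TRUE)[, 1]),
           mean(which(region, arr.ind = TRUE)[, 2]))
  if (snap_radius > 0) {
    pts <- t(apply(pts, 1, function(p) {
      d <- sqrt((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2)
      near <- bnd[d <= snap_radius, , drop = FALSE]
      if (nrow(near) == 0) return(p)
      dc <- sqrt((near[, 1] - ctr[1])^2 + (near[, 2] - ctr[2])^2)
      near[which.max(dc), ]
    }))
  }
  pts <- unique(pts)
  if (nrow(pts) < 4) {
    stop("corner-detection error: fewer than 4 admissible corners")
  }
  # assign roles by proximity to the bounding-box vertices
  rs <- range(bnd[, 1]); cs <- range(bnd[, 2])
  ant <- if (anterior_left) cs[1] else cs[2]
  post <- if (anterior_left) cs[2] else cs[1]
  vertices <- rbind(sa = c(rs[1], ant), sp = c(rs[1], post),
                    ia = c(rs[2], ant), ip = c(rs[2], post))
  d <- outer(seq_len(nrow(pts)), seq_len(4), Vectorize(function(i, j) {
    sqrt(sum((pts[i, ] - vertices[j, ])^2))
  }))
  assigned <- rep(NA_integer_, 4)
  used <- rep(FALSE, nrow(pts))
  for (k in order(d)) {
    i <- (k - 1) %% nrow(pts) + 1; j <- (k - 1) %/% nrow(pts) + 1
    if (is.na(assigned[j]) && !used[i]) {
      assigned[j] <- i; used[i] <- TRUE
    }
  }
  out <- lapply(seq_len(4), function(j) as.numeric(pts[assigned[j], ]))
  names(out) <- rownames(vertices)
  # anatomical sanity of the assignment
  if (!(out$sa[1] < out$ia[1] && out$sp[1] < out$ip[1])) {
    stop("corner-detection error: corner roles violate superior/inferior order")
  }
  lr <- if (anterior_left) 1 else -1
  if (!(lr * (out$sp[2] - out$sa[2]) > 0 && lr * (out$ip[2] - out$ia[2]) > 0)) {
    stop("corner-detection error: corner roles violate anterior/posterior order")
  }
  out <- lapply(out, function(p) p + off)
  out$ma <- (out$sa + out$ia) / 2
  out$mp <- (out$sp + out$ip) / 2
  structure(out, class = "corner_set")
}

# pixels of the region with at least one 4-neighbour outside it
boundary_points <- function(region) {
  nr <- nrow(region); nc <- ncol(region)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- region
  core <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(region & !core, arr.ind = TRUE)
}

#' Vertebral body diameter
#'
#' Euclidean distance between the anterior and posterior edge midpoints of
#' the corner set.
#'
#' @param corners A `corner_set` from [detect_vb_corners()].
#' @param spacing Pixel spacing (mm/px); 1 keeps pixel units.
#' @export
vertebral_diameter <- function(corners, spacing = 1) {
  sqrt(sum((corners$ma - corners$mp)^2)) * spacing
}

#' Vertebral body height
#'
#' Area divided by diameter: the region's pixel count (the sum of its
#' binary mask values) over `vd`. The product `vh * vd` therefore equals
#' the area identically.
#'
#' @param region Logical matrix of the vertebral body.
#' @param vd Vertebral diameter (same units as `spacing` implies).
#' @param spacing Pixel spacing (mm/px).
#' @export
vertebral_height <- function(region, vd, spacing = 1) {
  if (vd <= 0) stop("vertebral diameter must be positive")
  sum(region) * spacing^2 / vd
}

#' Disc feature-location points and diameters
#'
#' Derives the disc landmarks from the adjacent vertebral corner sets: the
#' disc boundary points nearest the upper body's inferior corners
#' (`d1a`, `d1p`) and the lower body's superior corners (`d2a`, `d2p`);
#' their anterior/posterior midpoints `da`, `dp`; the diameter `||da - dp||`;
#' and the extreme boundary points `dal`, `dpr` along the `da -> dp` axis,
#' whose distance is the maximum diameter.
#'
#' @param disc_region Logical matrix of the disc.
#' @param upper_vb,lower_vb `corner_set`s of the bodies above and below (for
#'   L5/S1 the lower set comes from the sacrum's superior boundary).
#' @param adjacency_tol Maximum background gap (px) tolerated between the
#'   disc and each adjacent body before an adjacency error is raised.
#' @param upper_region,lower_region Optional logical matrices of the
#'   adjacent structures; when given, adjacency is the minimum
#'   boundary-to-boundary distance between regions (otherwise the corner
#'   points stand in for the regions).
#' @return List of class `disc_landmarks` with the points above plus
#'   `diameter` and `max_diameter` (px).
#' @export
disc_landmarks <- function(disc_region, upper_vb, lower_vb,
                           adjacency_tol = 3, upper_region = NULL,
                           lower_region = NULL) {
  if (!any(disc_region)) stop("empty disc region")
  bnd <- boundary_points(disc_region)
  nearest <- function(p) {
    d <- sqrt((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2)
    list(pt = as.numeric(bnd[which.min(d), ]), dist = min(d))
  }
  n1a <- nearest(upper_vb$ia); n1p <- nearest(upper_vb$ip)
  n2a <- nearest(lower_vb$sa); n2p <- nearest(lower_vb$sp)
  region_gap <- function(reg) {
    ob <- boundary_points(reg)
    min(vapply(seq_len(nrow(ob)), function(i) {
      min(sqrt((bnd[, 1] - ob[i, 1])^2 + (bnd[, 2] - ob[i, 2])^2))
    }, numeric(1))) - 1
  }
  gaps <- c(
    if (!is.null(upper_region)) region_gap(upper_region) else
      min(n1a$dist, n1p$dist) - 1,
    if (!is.null(lower_region)) region_gap(lower_region) else
      min(n2a$dist, n2p$dist) - 1)
  if (max(gaps) > adjacency_tol) {
    stop("adjacency error: disc separated from an adjacent structure by ",
         round(max(gaps), 1), " px (> ", adjacency_tol, ")")
  }
  d1a <- n1a$pt; d1p <- n1p$pt; d2a <- n2a$pt; d2p <- n2p$pt
  da <- (d1a + d2a) / 2; dp <- (d1p + d2p) / 2
  diameter <- sqrt(sum((dp - da)^2))
  if (diameter <= 0) stop("degenerate disc landmarks: zero diameter")
  u <- (dp - da) / diameter
  t <- (bnd[, 1] - da[1]) * u[1] + (bnd[, 2] - da[2]) * u[2]
  dal <- as.numeric(bnd[which.min(t), ])
  dpr <- as.numeric(bnd[which.max(t), ])
  structure(list(d1a = d1a, d1p = d1p, d2a = d2a, d2p = d2p,
                 da = da, dp = dp, dal = dal, dpr = dpr,
                 diameter = diameter,
                 max_diameter = sqrt(sum((dpr - dal)^2))),
            class = "disc_landmarks")
}

#' Average disc height from the central band
#'
#' Counts the disc pixels whose projection onto the `da -> dp` axis falls in
#' the central `mu` fraction of the diameter, and divides by `mu` times the
#' diameter: the mean height of the central band of the disc. The band
#' restriction (default `mu = 0.8`) excludes the tapering anterior/posterior
#' margins so the value reflects the load-bearing central height.
#'
#' @param disc_region Logical matrix of the disc.
#' @param landmarks A [disc_landmarks()] result.
#' @param mu Central band fraction in `(0, 1]`, default 0.8.
#' @param spacing Pixel spacing (mm/px).
#' @return List with `area_central` (px count) and `dh`.
#' @export
disc_height <- function(disc_region, landmarks, mu = 0.8, spacing = 1) {
  stopifnot(mu > 0, mu <= 1)
  d <- landmarks$diameter
  if (d <= 0) stop("disc diameter must be positive")
  px <- which(disc_region, arr.ind = TRUE)
  u <- (landmarks$dp - landmarks$da) / d
  t <- (px[, 1] - landmarks$da[1]) * u[1] + (px[, 2] - landmarks$da[2]) * u[2]
  inband <- abs(t - d / 2) <= mu * d / 2
  area_central <- sum(inband)
  list(area_central = area_central,
       dh = area_central * spacing / (mu * d))
}

#' Disc height index
#'
#' Twice the disc height over the sum of the adjacent vertebral body
#' heights; unit-free and invariant to pixel spacing.
#'
#' @param dh Disc height.
#' @param vh_upper,vh_lower Heights of the adjacent vertebral bodies.
#' @export
disc_height_index <- function(dh, vh_upper, vh_lower) {
  if (vh_upper + vh_lower <= 0) {
    stop("nonpositive vertebral height sum in DHI denominator")
  }
  2 * dh / (vh_upper + vh_lower)
}

#' Disc height-to-diameter ratio
#'
#' Disc height over the maximum disc diameter; unit-free. Carries both
#' height and shape information.
#'
#' @param dh Disc height.
#' @param max_diameter Maximum disc diameter.
#' @export
disc_hdr <- function(dh, max_diameter) {
  if (max_diameter <= 0) stop("nonpositive maximum diameter")
  dh / max_diameter
}
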