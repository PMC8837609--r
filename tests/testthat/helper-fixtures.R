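# Shared fixtures: all synthetic, generated in code.

# render an axis-aligned or rotated rectangle by pixel-centre inclusion,
# returning the region and the continuous (rotated) vertex coordinates
render_rect <- function(w, h, theta_deg = 0, nr = 120, nc = 120,
                        centre = c((nr + 1) / 2, (nc + 1) / 2)) {
  rr <- matrix(rep(seq_len(nr), nc), nr)
  cc <- matrix(rep(seq_len(nc), each = nr), nr)
  t <- theta_deg * pi / 180
  ur <- centre[1] + cos(t) * (rr - centre[1]) + sin(t) * (cc - centre[2])
  uc <- centre[2] - sin(t) * (rr - centre[1]) + cos(t) * (cc - centre[2])
  reg <- abs(ur - centre[1]) < h / 2 & abs(uc - centre[2]) < w / 2
  v <- rbind(sa = c(centre[1] - h / 2, centre[2] - w / 2),
             sp = c(centre[1] - h / 2, centre[2] + w / 2),
             ia = c(centre[1] + h / 2, centre[2] - w / 2),
             ip = c(centre[1] + h / 2, centre[2] + w / 2))
  dr <- v[, 1] - centre[1]; dc <- v[, 2] - centre[2]
  vr <- cbind(centre[1] + cos(t) * dr - sin(t) * dc,
              centre[2] + sin(t) * dr + cos(t) * dc)
  rownames(vr) <- rownames(v)
  list(region = reg, vertices = vr)
}

# hand-built corner set (bypassing detection) for landmark/height oracles
make_corners <- function(sa, sp, ia, ip) {
  structure(list(sa = sa, sp = sp, ia = ia, ip = ip,
                 ma = (sa + ia) / 2, mp = (sp + ip) / 2),
            class = "corner_set")
}

# phantom spec small enough for fast tests but with every class present
tiny_phantom_spec <- function(...) {
  phantom_spec(image_size = c(64, 64), vb_size = c(24, 7),
               disc_size = c(28, 3), sacrum_tilt_deg = 3, ...)
}

# maximum distance between measured vertebra corners and the analytic
# phantom corner truth, over all five vertebrae
max_corner_error <- function(measured, truth) {
  max(unlist(lapply(paste0("VB_L", 1:5), function(r) {
    tc <- truth$corners[[r]]
    mc <- measured$corners[[r]]
    vapply(c("sa", "sp", "ia", "ip"), function(k) {
      sqrt(sum((mc[[k]] - tc[k, ])^2))
    }, numeric(1))
  })))
}

# histogram bin width expressed on the delta-SI scale for a phantom spec
dsi_bin_tol <- function(spec, n_bins = 64) {
  img_max <- max(spec$np_intensity, spec$csf_intensity, spec$fat_intensity,
                 spec$vb_intensity)
  (img_max / n_bins) * 255 / spec$csf_intensity
}
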