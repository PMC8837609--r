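test_that("region histograms conserve counts and honour binning", {
  img <- matrix(100, 25, 20)
  reg <- matrix(TRUE, 25, 20)
  h <- region_histogram(img, reg, n_bins = 32, range = c(0, 200))
  expect_equal(sum(h$counts), 500)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[findInterval(100, h$bin_edges)], 500)

  img2 <- matrix(c(rep(60, 300), rep(180, 200)), 25, 20)
  h2 <- region_histogram(img2, reg, n_bins = 64, range = c(0, 255))
  nz <- which(h2$counts > 0)
  expect_length(nz, 2)
  expect_equal(sort(h2$counts[nz]), c(200, 300))

  ph <- generate_phantom(phantom_spec(noise_sd = 5))
  disc <- extract_structure(ph$mask, "DISC_L2L3")
  h3 <- region_histogram(ph$image, disc)
  expect_equal(sum(h3$counts), sum(disc))

  expect_error(region_histogram(img, matrix(FALSE, 25, 20)), "empty region")
  expect_error(region_histogram(img, reg, n_bins = 8), "n_bins")
})

test_that("two-peak detection finds exact noiseless modes", {
  img <- matrix(c(rep(60, 300), rep(180, 200)), 25, 20)
  reg <- matrix(TRUE, 25, 20)
  pk <- find_two_peaks(region_histogram(img, reg, range = c(0, 255)))
  expect_false(pk$degenerate)
  expect_equal(pk$si1, 60)
  expect_equal(pk$si2, 180)
})

test_that("unimodal and flat histograms follow the degenerate/error rules", {
  img <- matrix(90, 20, 20)
  reg <- matrix(TRUE, 20, 20)
  pk <- find_two_peaks(region_histogram(img, reg, range = c(0, 255)))
  expect_true(pk$degenerate)
  expect_equal(pk$si1, 90)
  expect_equal(pk$si2, pk$si1)

  # perfectly flat histogram: every bin equally filled, prominence zero
  flat <- matrix(seq(0.5, 255.5, length.out = 400), 20, 20)
  hf <- region_histogram(flat, reg, n_bins = 64, range = c(0, 256))
  expect_error(find_two_peaks(hf), "no-peak")
})

test_that("noisy bimodal peaks are recovered within one bin (oracle scan)", {
  set.seed(11)
  n1 <- 700; n2 <- 500
  vals <- c(rnorm(n1, 60, 5), rnorm(n2, 180, 5))
  img <- matrix(vals, 40, 30)
  reg <- matrix(TRUE, 40, 30)
  h <- region_histogram(img, reg, n_bins = 64, range = c(0, max(img)))
  pk <- find_two_peaks(h, refine = FALSE)
  bw <- diff(h$bin_edges[1:2])
  # oracle: exhaustive scan of the smoothed counts
  sm <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- h$counts[is.na(sm)]
  ord <- order(sm, decreasing = TRUE)
  top <- ord[1]
  second <- ord[which(abs(ord - top) >= 4)[1]]
  expect_equal(sort(c(pk$si1, pk$si2)),
               sort(h$bin_centers[c(top, second)]))
  expect_lt(abs(pk$si1 - 60), bw)
  expect_lt(abs(pk$si2 - 180), bw)
  # refined locations are at least as close
  pkr <- find_two_peaks(h)
  expect_lte(abs(pkr$si1 - 60), abs(pk$si1 - 60) + 1e-9)
})

test_that("CSF reference peak matches the argmax oracle", {
  img <- matrix(200, 30, 10)
  reg <- matrix(TRUE, 30, 10)
  expect_equal(as.numeric(csf_reference(img, reg, range = c(0, 255))), 200)

  set.seed(5)
  imgn <- matrix(rnorm(300, 200, 3), 30, 10)
  got <- csf_reference(imgn, reg, range = c(0, max(imgn)), refine = FALSE)
  bw <- attr(got, "bin_width")
  expect_lt(abs(as.numeric(got) - 200), bw)

  zero <- matrix(0, 30, 10)
  si0 <- csf_reference(zero, reg, range = c(0, 1))
  expect_error(delta_si(find_two_peaks(region_histogram(img, reg,
                                                        range = c(0, 255))),
                        as.numeric(si0)),
               "normalization error")
})

test_that("delta_si implements the CSF-normalized peak difference", {
  pk <- structure(list(si1 = 60, si2 = 180, degenerate = FALSE),
                  class = "peak_pair")
  expect_equal(delta_si(pk, 200), 153)
  dg <- structure(list(si1 = 90, si2 = 90, degenerate = TRUE),
                  class = "peak_pair")
  expect_equal(delta_si(dg, 123.4), 0)
  expect_error(delta_si(pk, 0), "normalization error")
  expect_error(delta_si(pk, -3), "normalization error")
})

test_that("delta_si is invariant to global intensity rescaling", {
  ph <- generate_phantom(phantom_spec(noise_sd = 3))
  measure_dsi <- function(img) {
    disc <- extract_structure(ph$mask, "DISC_L3L4")
    csf <- extract_structure(ph$mask, "CSF")
    rng <- c(0, max(img))
    delta_si(find_two_peaks(region_histogram(img, disc, range = rng)),
             csf_reference(img, csf, range = rng))
  }
  base <- measure_dsi(ph$image)
  tol <- dsi_bin_tol(ph$spec)
  for (c in c(0.5, 2, 10)) {
    expect_lt(abs(measure_dsi(ph$image * c) - base), tol)
  }
  expect_gte(base, 0)
})
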