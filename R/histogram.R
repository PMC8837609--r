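#' Intensity histogram of a masked region
#'
#' Histograms the image intensities of the pixels of one anatomical region.
#' Bins are equal-width over `range` (default `[0, max(image)]`), so the bin
#' grid is shared by every region of the same image — the disc peaks and the
#' CSF reference peak are then directly comparable.
#'
#' @param image Numeric intensity matrix.
#' @param region Logical matrix of the same shape selecting the region.
#' @param n_bins Number of bins, at least 16 (default 64).
#' @param range Intensity range covered by the bins.
#' @return A list of class `ivd_histogram`: `counts`, `bin_edges` (length
#'   `n_bins + 1`), `bin_centers`, `n_pixels`, `class_id` (from the region
#'   attribute, if any).
#' @export
region_histogram <- function(image, region, n_bins = 64,
                             range = c(0, max(image))) {
  stopifnot(n_bins >= 16)
  if (!any(region)) stop("empty region: cannot compute a histogram")
  if (!all(dim(image) == dim(region))) stop("image/region shape mismatch")
  vals <- image[region]
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(vals, idx)
  sums[as.integer(rownames(agg))] <- agg
  structure(list(counts = counts, bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 bin_sums = sums,
                 n_pixels = length(vals),
                 class_id = attr(region, "class_id")),
            class = "ivd_histogram")
}

# sub-bin peak location: intensity-weighted mean of the raw values in the
# peak bin and its immediate neighbours; falls back to the bin centre
peak_location <- function(hist, bin, refine = TRUE) {
  if (!refine || is.null(hist$bin_sums)) return(hist$bin_centers[bin])
  w <- max(1L, bin - 1L):min(length(hist$counts), bin + 1L)
  tot <- sum(hist$counts[w])
  if (tot == 0) return(hist$bin_centers[bin])
  sum(hist$bin_sums[w]) / tot
}

# centred moving average; window is forced odd, edges use partial windows
smooth_counts <- function(counts, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(as.numeric(counts))
  half <- window %/% 2L
  n <- length(counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(counts[lo:hi])
  }
  out
}

# topographic prominence of a local maximum at index i: height minus the
# highest of the two valley floors separating it from higher terrain
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i == 1) y[i] else {
    j <- i - 1; m <- y[i]
    while (j >= 1 && y[j] <= y[i]) { m <- min(m, y[j]); j <- j - 1 }
    if (j < 1) min(y[1:i]) else m
  }
  right <- if (i == n) y[i] else {
    j <- i + 1; m <- y[i]
    while (j <= n && y[j] <= y[i]) { m <- min(m, y[j]); j <- j + 1 }
    if (j > n) min(y[i:n]) else m
  }
  y[i] - max(left, right)
}

#' Locate the two dominant peaks of a disc histogram
#'
#' A healthy disc has a bimodal intensity histogram: the bright nucleus
#' pulposus and the darker annulus fibrosus each contribute a peak. Counts
#' are smoothed by a centred moving average; local maxima whose topographic
#' prominence reaches `min_prominence` and that are mutually separated by at
#' least `min_separation` bins are candidates, of which the two with the
#' highest smoothed counts are returned in order of location. If only one
#' admissible peak exists (a degenerated, effectively unimodal disc) the
#' pair is degenerate with `si1 == si2`.
#'
#' @param hist An [region_histogram()] result.
#' @param smoothing_window Moving-average window in bins (default 3).
#' @param min_separation Minimum candidate separation in bins (default 4).
#' @param min_prominence Minimum prominence in pixel counts; default 2\% of
#'   the region pixel count.
#' @param refine If `TRUE` (default) each peak location is the
#'   intensity-weighted mean of the raw pixel values in the peak bin and its
#'   two neighbours, removing the bin-centre quantization; `FALSE` reports
#'   raw bin centres.
#' @return List of class `peak_pair`: `si1 <= si2` (peak intensities),
#'   `prominence` (length 2), `degenerate` flag, `bin_width`.
#' @export
find_two_peaks <- function(hist, smoothing_window = 3, min_separation = 4,
                           min_prominence = 0.02 * hist$n_pixels,
                           refine = TRUE) {
  y <- smooth_counts(hist$counts, smoothing_window)
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > 0 && y[i] >= l && y[i] >= r
  }, logical(1))
  # collapse plateaus to their centre bin
  cand <- which(is_max)
  if (length(cand) > 1) {
    keep <- logical(length(cand))
    i <- 1
    while (i <= length(cand)) {
      j <- i
      while (j < length(cand) && cand[j + 1] == cand[j] + 1 &&
             y[cand[j + 1]] == y[cand[i]]) j <- j + 1
      mid <- cand[(i + j) %/% 2]
      keep[which(cand == mid)[1]] <- TRUE
      i <- j + 1
    }
    cand <- cand[keep]
  }
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  ok <- prom >= min_prominence
  cand <- cand[ok]; prom <- prom[ok]
  if (length(cand) == 0) stop("no-peak error: histogram has no admissible peak")
  # enforce separation greedily from the highest peak down
  ord <- order(y[cand], decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - cand[sel]) >= min_separation)) sel <- c(sel, i)
  }
  sel <- sel[seq_len(min(2L, length(sel)))]
  bins <- cand[sel]; proms <- prom[sel]
  bw <- diff(hist$bin_edges[1:2])
  if (length(bins) == 1L) {
    loc <- peak_location(hist, bins, refine)
    return(structure(list(si1 = loc, si2 = loc,
                          prominence = rep(proms, 2),
                          degenerate = TRUE, bin_width = bw),
                     class = "peak_pair"))
  }
  o <- order(bins)
  structure(list(si1 = peak_location(hist, bins[o[1]], refine),
                 si2 = peak_location(hist, bins[o[2]], refine),
                 prominence = proms[o], degenerate = FALSE, bin_width = bw),
            class = "peak_pair")
}

#' CSF reference peak intensity
#'
#' The CSF signal is bright and stable across scanners, so the location of
#' the single highest smoothed-histogram bin of the CSF region serves as the
#' intensity normalization reference.
#'
#' @inheritParams region_histogram
#' @inheritParams find_two_peaks
#' @param csf_region Logical matrix selecting the CSF pixels.
#' @param smoothing_window Moving-average window in bins.
#' @return Peak intensity, with the bin width as attribute `bin_width`.
#' @export
csf_reference <- function(image, csf_region, n_bins = 64,
                          range = c(0, max(image)), smoothing_window = 3,
                          refine = TRUE) {
  h <- region_histogram(image, csf_region, n_bins = n_bins, range = range)
  y <- smooth_counts(h$counts, smoothing_window)
  structure(peak_location(h, which.max(y), refine),
            bin_width = diff(h$bin_edges[1:2]))
}

#' Normalized peak signal-intensity difference of a disc
#'
#' The difference between the two disc histogram peak intensities,
#' normalized by the CSF peak intensity and amplified by 255:
#' `delta_si = (si2 - si1) / si_csf * 255`. Normalizing by CSF removes the
#' arbitrary global intensity scale of the scanner, and the factor 255 puts
#' the value on a familiar 8-bit-like scale. A degenerate (single-peak) pair
#' yields 0 — maximal blurring of the nucleus/annulus boundary.
#'
#' @param peaks A `peak_pair` from [find_two_peaks()].
#' @param si_csf CSF reference intensity from [csf_reference()]; must be
#'   positive.
#' @return Nonnegative `delta_si` value.
#' @examples
#' h <- list(si1 = 60, si2 = 180, degenerate = FALSE)
#' class(h) <- "peak_pair"
#' delta_si(h, 200)  # 153
#' @export
delta_si <- function(peaks, si_csf) {
  if (si_csf <= 0) stop("normalization error: CSF reference must be positive")
  if (isTRUE(peaks$degenerate)) return(0)
  (peaks$si2 - peaks$si1) / as.numeric(si_csf) * 255
}
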