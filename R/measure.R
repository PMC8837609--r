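#' Default quantitation configuration
#'
#' Parameter block shared by [measure_spine()] and the pipeline: central
#' band fraction `mu`, histogram binning and peak detection settings, corner
#' detection settings, disc-vertebra adjacency tolerance, orientation, and
#' optional pixel spacing (mm/px).
#'
#' @param ... Overrides of the defaults.
#' @export
quant_config <- function(...) {
  cfg <- list(
    mu = 0.8,
    n_bins = 64,
    smoothing_window = 3,
    min_separation = 4,
    min_prominence_frac = 0.02,
    corner_quality = 0.05,
    corner_min_dist = 5,
    adjacency_tol = 3,
    clean_radius = 0,        # 0 = no morphological cleanup
    anterior_left = TRUE,
    spacing = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Measure every vertebra and disc of a segmented spine
#'
#' Orchestrates the full quantitation of one image/mask pair: per-vertebra
#' corner detection, diameter and height; per-disc landmarks, central-band
#' height, height index, height-to-diameter ratio; and the CSF-normalized
#' peak signal-intensity difference per disc. The L5/S1 disc uses the L5
#' corners above and the sacrum's superior corners below; because the
#' sacrum has no comparable height, its height index uses twice the L5
#' height in the denominator (flagged `l5s1_dhi_uses_l5_only`).
#'
#' Per-structure failures (absent class, corner failure, missing CSF) are
#' collected as flags and leave `NA` in the affected fields rather than
#' aborting the whole measurement.
#'
#' @param image Numeric intensity matrix.
#' @param mask An `ivd_label_mask` of the same shape.
#' @param config A [quant_config()].
#' @return List of class `spine_measure`: `vertebrae` and `discs` data
#'   frames, `corners` (per structure), `landmarks` (per disc), `si_csf`,
#'   and a character vector `flags`.
#' @export
measure_spine <- function(image, mask, config = quant_config()) {
  stopifnot(all(dim(image) == dim(mask)))
  if (config$clean_radius >= 1) mask <- clean_mask(mask, config$clean_radius)
  sp <- if (is.null(config$spacing)) 1 else as.numeric(config$spacing)[1]
  flags <- character(0)
  flag <- function(...) flags <<- c(flags, paste0(...))

  corners <- list()
  regions <- list()
  for (role in c(vb_roles(), "SACRUM")) {
    reg <- tryCatch(extract_structure(mask, role), error = function(e) NULL)
    if (is.null(reg)) { flag("absent:", role); next }
    regions[[role]] <- reg
    cs <- tryCatch(
      detect_vb_corners(reg, quality = config$corner_quality,
                        min_dist = config$corner_min_dist,
                        anterior_left = config$anterior_left),
      error = function(e) NULL)
    if (is.null(cs)) flag("corner_failure:", role) else corners[[role]] <- cs
  }

  vb <- data.frame(role = vb_roles(), VD = NA_real_, VH = NA_real_,
                   area = NA_real_, stringsAsFactors = FALSE)
  for (i in 1:5) {
    role <- vb_roles()[i]
    if (is.null(corners[[role]])) next
    vd <- vertebral_diameter(corners[[role]], spacing = sp)
    vb$VD[i] <- vd
    vb$area[i] <- sum(regions[[role]]) * sp^2
    vb$VH[i] <- vertebral_height(regions[[role]], vd / sp, spacing = 1) * sp
  }

  csf_region <- tryCatch(extract_structure(mask, "CSF"),
                         error = function(e) NULL)
  si_csf <- NA_real_
  rng <- c(0, max(image))
  if (is.null(csf_region)) {
    flag("absent:CSF")
  } else {
    si_csf <- tryCatch(
      as.numeric(csf_reference(image, csf_region, n_bins = config$n_bins,
                               range = rng,
                               smoothing_window = config$smoothing_window)),
      error = function(e) { flag("csf_reference_failure"); NA_real_ })
  }

  discs <- data.frame(role = disc_roles(), segment = disc_segments(),
                      diameter = NA_real_, max_diameter = NA_real_,
                      area = NA_real_, area_central = NA_real_,
                      DH = NA_real_, DHI = NA_real_, HDR = NA_real_,
                      delta_si = NA_real_, degenerate_peaks = NA,
                      stringsAsFactors = FALSE)
  landmarks <- list()
  for (i in 1:5) {
    role <- disc_roles()[i]
    reg <- tryCatch(extract_structure(mask, role), error = function(e) NULL)
    if (is.null(reg)) { flag("absent:", role); next }
    discs$area[i] <- sum(reg) * sp^2

    upper <- corners[[vb_roles()[i]]]
    lower <- if (i < 5) corners[[vb_roles()[i + 1]]] else corners[["SACRUM"]]
    if (!is.null(upper) && !is.null(lower)) {
      lower_role <- if (i < 5) vb_roles()[i + 1] else "SACRUM"
      lm <- tryCatch(
        disc_landmarks(reg, upper, lower,
                       adjacency_tol = config$adjacency_tol,
                       upper_region = regions[[vb_roles()[i]]],
                       lower_region = regions[[lower_role]]),
        error = function(e) { flag("landmark_failure:", role); NULL })
      if (!is.null(lm)) {
        landmarks[[role]] <- lm
        discs$diameter[i] <- lm$diameter * sp
        discs$max_diameter[i] <- lm$max_diameter * sp
        dhres <- disc_height(reg, lm, mu = config$mu, spacing = sp)
        discs$area_central[i] <- dhres$area_central
        discs$DH[i] <- dhres$dh
        vh_up <- vb$VH[i]
        vh_lo <- if (i < 5) vb$VH[i + 1] else NA_real_
        if (i == 5) {
          if (!is.na(vh_up)) {
            discs$DHI[i] <- disc_height_index(dhres$dh, vh_up, vh_up)
            flag("l5s1_dhi_uses_l5_only")
          }
        } else if (!is.na(vh_up) && !is.na(vh_lo)) {
          discs$DHI[i] <- disc_height_index(dhres$dh, vh_up, vh_lo)
        }
        discs$HDR[i] <- disc_hdr(dhres$dh, lm$max_diameter * sp)
      }
    } else {
      flag("landmark_skipped:", role)
    }

    if (!is.na(si_csf) && si_csf > 0) {
      pk <- tryCatch({
        h <- region_histogram(image, reg, n_bins = config$n_bins, range = rng)
        find_two_peaks(h, smoothing_window = config$smoothing_window,
                       min_separation = config$min_separation,
                       min_prominence = config$min_prominence_frac *
                         h$n_pixels)
      }, error = function(e) { flag("peak_failure:", role); NULL })
      if (!is.null(pk)) {
        discs$delta_si[i] <- delta_si(pk, si_csf)
        discs$degenerate_peaks[i] <- pk$degenerate
      }
    }
  }
  if (is.na(si_csf)) flag("delta_si_unavailable")

  structure(list(vertebrae = vb, discs = discs, corners = corners,
                 landmarks = landmarks, si_csf = si_csf,
                 flags = unique(flags), config = config),
            class = "spine_measure")
}
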