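#' Per-grade signal-intensity grading criteria
#'
#' The degeneration grade of a disc is decided from its normalized peak
#' signal-intensity difference against per-grade reference distributions:
#' grade `g` has a mean `mu_g` and standard deviation `sigma_g` of the
#' peak difference among discs of that grade. On the modified Pfirrmann
#' scale the signal-based grades are 1, 2, 3, 4 and the collapsed band 5-8.
#' Reference values are an input (a fitted population table); the package
#' ships a synthetic, non-clinical example table for testing.
#'
#' @param mu Numeric vector of per-grade means, strictly decreasing (a
#'   darker, more degenerated disc has a smaller peak difference).
#' @param sigma Per-grade standard deviations, all positive.
#' @param grades Grade labels (default `seq_along(mu)`).
#' @return Object of class `grading_criteria`.
#' @export
grading_criteria <- function(mu, sigma, grades = seq_along(mu)) {
  stopifnot(length(mu) == length(sigma), length(mu) >= 2)
  if (any(diff(mu) >= 0)) {
    stop("grade means must be strictly decreasing with grade")
  }
  if (any(sigma <= 0)) stop("grade standard deviations must be positive")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 grades = grades), class = "grading_criteria")
}

#' Read grading criteria from CSV or JSON
#'
#' CSV columns: `grade`, `mu`, `sigma` (one row per grade, ordered or not);
#' JSON: an object with arrays `grade`, `mu`, `sigma`.
#'
#' @param path File path.
#' @export
read_grading_criteria <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- data.frame(grade = x$grade, mu = x$mu, sigma = x$sigma)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df <- df[order(df$grade), ]
  grading_criteria(df$mu, df$sigma, grades = df$grade)
}

#' Grade-deviation statistic between adjacent grades
#'
#' For adjacent grades `i` and `i + 1`, the difference of sigma-normalized
#' distances of the disc's peak signal-intensity difference to the two
#' grade means:
#' `Delta = |dsi - mu[i+1]| / sigma[i+1] - |dsi - mu[i]| / sigma[i]`.
#' Positive values mean the disc is closer (in normalized distance) to
#' grade `i`; the sign change over `i = 1..G-1` localizes the grade.
#'
#' @param dsi Measured peak signal-intensity difference.
#' @param criteria A [grading_criteria()].
#' @param i Lower grade index of the adjacent pair, `1 <= i <= G - 1`.
#' @export
grade_delta <- function(dsi, criteria, i) {
  g <- length(criteria$mu)
  if (i < 1 || i > g - 1) stop("adjacent-grade index out of range: ", i)
  abs(dsi - criteria$mu[i + 1]) / criteria$sigma[i + 1] -
    abs(dsi - criteria$mu[i]) / criteria$sigma[i]
}

#' Assign a degeneration grade from the signal-intensity difference
#'
#' The grade minimizing the sigma-normalized distance
#' `|dsi - mu_g| / sigma_g`; ties are broken toward the more severe (higher)
#' grade. With equal sigmas this is equivalent to scanning the adjacent
#' [grade_delta()] statistic for its sign change, and the decision
#' boundaries sit at the midpoints of adjacent grade means.
#'
#' @inheritParams grade_delta
#' @return The grade label (element of `criteria$grades`).
#' @export
assign_grade <- function(dsi, criteria) {
  d <- abs(dsi - criteria$mu) / criteria$sigma
  # which.min takes the first minimum; reverse so ties fall on the higher
  # (more severe) grade
  k <- length(d) + 1 - which.min(rev(d))
  criteria$grades[k]
}

#' Signed standardized deviation from a healthy baseline
#'
#' `beta = (x - mu) / sigma`: how many baseline standard deviations the
#' measured parameter lies from the healthy population mean for the
#' subject's gender and disc position. Smaller (more negative) values mean
#' stronger degeneration or collapse.
#'
#' @param x Measured parameter value.
#' @param mu,sigma Baseline mean and standard deviation (`sigma > 0`).
#' @export
beta_deviation <- function(x, mu, sigma) {
  if (sigma <= 0) stop("baseline standard deviation must be positive")
  (x - mu) / sigma
}

#' Disc-height collapse percentage
#'
#' `(1 - dh / healthy_mean_dh) * 100`, floored at 0 when the measured
#' height exceeds the healthy baseline (flagged `above_baseline`).
#'
#' @param dh Measured disc height.
#' @param healthy_mean_dh Baseline mean healthy disc height (positive).
#' @return Percentage with attribute `above_baseline`.
#' @export
collapse_percentage <- function(dh, healthy_mean_dh) {
  if (healthy_mean_dh <= 0) stop("nonpositive healthy baseline height")
  raw <- (1 - dh / healthy_mean_dh) * 100
  structure(max(0, raw), above_baseline = raw < 0)
}

#' Population baseline table
#'
#' Long-format baseline of healthy parameter distributions keyed by gender
#' (0 or 1), age band and disc segment: one row per parameter with its mean
#' and standard deviation. Parameters are `delta_si`, `DHI`, `HDR` (used for
#' standardized deviations) and `DH` (its mean is the healthy height used
#' for the collapse percentage).
#'
#' @param df Data frame with columns `gender`, `age_band`, `segment`,
#'   `param`, `mu`, `sigma`.
#' @export
baseline_table <- function(df) {
  need <- c("gender", "age_band", "segment", "param", "mu", "sigma")
  if (!all(need %in% names(df))) {
    stop("baseline table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$sigma[df$param != "DH"] <= 0)) {
    stop("baseline standard deviations must be positive")
  }
  structure(df, class = c("baseline_table", class(df)))
}

#' @rdname baseline_table
#' @param path CSV file with the columns above.
#' @export
read_baseline_table <- function(path) {
  baseline_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

baseline_lookup <- function(baseline, gender, age_band, segment, param) {
  rows <- baseline$gender == gender & baseline$age_band == age_band &
    baseline$segment == segment & baseline$param == param
  if (!any(rows)) {
    fb <- baseline$gender == gender & baseline$age_band == "all" &
      baseline$segment == segment & baseline$param == param
    if (any(fb)) rows <- fb else {
      stop("lookup error: no baseline row for (gender=", gender,
           ", age_band=", age_band, ", segment=", segment,
           ", param=", param, ")")
    }
  }
  as.list(baseline[which(rows)[1], c("mu", "sigma")])
}

#' Build a per-disc degeneration report
#'
#' Combines the measured parameters with the grading criteria and the
#' population baseline into the per-disc degeneration summary: assigned
#' grade, the adjacent-grade deviation statistic at the assigned boundary,
#' signed standardized deviations (beta) for the normalized parameters, and
#' the disc-height collapse percentage.
#'
#' @param measures A [measure_spine()] result.
#' @param criteria A [grading_criteria()].
#' @param baseline A [baseline_table()] (or `NULL` to skip baseline
#'   deviations).
#' @param subject List with `gender` (0 or 1) and `age_band` (e.g.
#'   `"20-30"`); required when `baseline` is given.
#' @return List of class `degeneration_report` with `discs` (data frame),
#'   `vertebrae`, `flags`.
#' @export
build_report <- function(measures, criteria, baseline = NULL,
                         subject = list(gender = 0, age_band = "all")) {
  d <- measures$discs
  n <- nrow(d)
  d$grade <- NA
  d$grade_delta <- NA_real_
  d$beta_delta_si <- NA_real_
  d$beta_DHI <- NA_real_
  d$beta_HDR <- NA_real_
  d$collapse_pct <- NA_real_
  d$above_baseline <- NA
  flags <- measures$flags
  if (!is.null(baseline)) {
    if (!subject$gender %in% unique(baseline$gender)) {
      stop("lookup error: no baseline rows for gender=", subject$gender)
    }
  }
  for (i in seq_len(n)) {
    dsi <- d$delta_si[i]
    if (!is.na(dsi)) {
      d$grade[i] <- assign_grade(dsi, criteria)
      k <- match(d$grade[i], criteria$grades)
      kk <- min(max(k, 1), length(criteria$mu) - 1)
      d$grade_delta[i] <- grade_delta(dsi, criteria, kk)
    }
    if (!is.null(baseline)) {
      seg <- d$segment[i]
      for (p in c("delta_si", "DHI", "HDR")) {
        x <- d[[if (p == "delta_si") "delta_si" else p]][i]
        if (is.na(x)) next
        b <- baseline_lookup(baseline, subject$gender, subject$age_band,
                             seg, p)
        d[[paste0("beta_", if (p == "delta_si") "delta_si" else p)]][i] <-
          beta_deviation(x, b$mu, b$sigma)
      }
      if (!is.na(d$DH[i])) {
        b <- baseline_lookup(baseline, subject$gender, subject$age_band,
                             seg, "DH")
        cp <- collapse_percentage(d$DH[i], b$mu)
        d$collapse_pct[i] <- as.numeric(cp)
        d$above_baseline[i] <- attr(cp, "above_baseline")
      }
    }
  }
  structure(list(discs = d, vertebrae = measures$vertebrae,
                 subject = subject, flags = flags),
            class = "degeneration_report")
}

#' Synthetic (non-clinical) grading criteria and baseline
#'
#' Example tables generated from the phantom presets, for tests and demos
#' only — they are not population values. The criteria place five grade
#' means linearly between the healthy and collapsed phantom peak
#' differences; the baseline centres each parameter on the healthy phantom
#' truth.
#'
#' @param spec Healthy phantom spec the tables are centred on.
#' @export
synthetic_criteria <- function(spec = phantom_spec()) {
  hi <- (spec$np_intensity - spec$af_intensity) / spec$csf_intensity * 255
  mu <- seq(hi - 3, hi * 0.15, length.out = 5)
  grading_criteria(mu, rep(10, 5), grades = 1:5)
}

#' @rdname synthetic_criteria
#' @export
synthetic_baseline <- function(spec = phantom_spec()) {
  tr <- phantom_truth(spec)$discs
  rows <- do.call(rbind, lapply(seq_len(5), function(i) {
    data.frame(
      gender = rep(0:1, each = 4),
      age_band = "all",
      segment = tr$segment[i],
      param = rep(c("delta_si", "DHI", "HDR", "DH"), 2),
      mu = rep(c(tr$delta_si[i], tr$DHI[i], tr$HDR[i], tr$DH[i]), 2),
      sigma = rep(c(10, 0.05, 0.02, 1.5), 2),
      stringsAsFactors = FALSE)
  }))
  baseline_table(rows)
}
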