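eq_sigma_criteria <- function() {
  grading_criteria(mu = c(150, 120, 90, 60, 30), sigma = rep(10, 5),
                   grades = 1:5)
}

test_that("criteria validation enforces ordering and positive spread", {
  expect_silent(eq_sigma_criteria())
  expect_error(grading_criteria(c(100, 110, 90), rep(5, 3)),
               "strictly decreasing")
  expect_error(grading_criteria(c(100, 90), c(5, 0)), "positive")
})

test_that("grade_delta is the difference of normalized distances", {
  cr <- grading_criteria(c(120, 90), c(10, 10))
  # at the lower-grade mean the first term carries the full separation
  expect_equal(grade_delta(120, cr, 1), 30 / 10)
  # at the upper-grade mean the statistic is negative by symmetry
  expect_equal(grade_delta(90, cr, 1), -3)
  # equidistant with equal sigmas: exactly zero
  expect_equal(grade_delta(105, cr, 1), 0)
  expect_error(grade_delta(100, cr, 2), "out of range")
  cr5 <- eq_sigma_criteria()
  # unequal sigmas shift the crossing point accordingly
  cr_uneq <- grading_criteria(c(120, 90), c(20, 5))
  x <- seq(90, 120, by = 0.01)
  d <- vapply(x, grade_delta, numeric(1), criteria = cr_uneq, i = 1)
  crossing <- x[which(diff(sign(d)) != 0)[1]]
  # closed form: |x-90|/5 = |x-120|/20 => x = 96
  expect_lt(abs(crossing - 96), 0.02)
})

test_that("grades minimize normalized distance with severe tie-break", {
  cr <- eq_sigma_criteria()
  expect_equal(assign_grade(150, cr), 1)
  expect_equal(assign_grade(29, cr), 5)
  # midpoint of grades 2 and 3: tie resolved toward the more severe grade
  expect_equal(assign_grade(105, cr), 3)
})

test_that("grade assignment is a non-decreasing step function of severity", {
  cr <- eq_sigma_criteria()
  sweep <- seq(160, 20, by = -0.5)
  g <- vapply(sweep, assign_grade, numeric(1), criteria = cr)
  expect_true(all(diff(g) >= 0))
  # exactly G plateaus with boundaries at adjacent-mean midpoints
  expect_setequal(unique(g), 1:5)
  bounds <- sweep[which(diff(g) != 0)]
  expect_true(all(abs(sort(bounds) - c(45, 75, 105, 135)) <= 0.5))
  # at the exact midpoint the tie falls to the severe side, just above it
  # the milder grade holds
  for (b in c(135, 105, 75, 45)) {
    expect_equal(assign_grade(b, cr), assign_grade(b - 0.25, cr))
    expect_equal(assign_grade(b + 0.25, cr), assign_grade(b, cr) - 1)
  }
})

test_that("grade assignment matches a brute-force distance oracle", {
  cr <- grading_criteria(c(140, 100, 70, 45, 25), c(8, 12, 9, 7, 6))
  # oracle: enumerate the normalized distances, most severe minimizer wins
  brute <- function(dsi) {
    d <- abs(dsi - cr$mu) / cr$sigma
    max(which(d == min(d)))
  }
  for (dsi in seq(10, 160, by = 2.5)) {
    expect_equal(assign_grade(dsi, cr), brute(dsi))
  }
})

test_that("grading is invariant to joint affine rescaling", {
  cr <- eq_sigma_criteria()
  for (dsi in c(150, 107, 88, 52, 31)) {
    cr2 <- grading_criteria(cr$mu * 3 + 7, cr$sigma * 3, cr$grades)
    expect_equal(assign_grade(dsi * 3 + 7, cr2), assign_grade(dsi, cr))
  }
})

test_that("beta deviation is the signed z-score", {
  expect_equal(beta_deviation(50, 50, 5), 0)
  expect_equal(beta_deviation(40, 50, 5), -2)
  xs <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(vapply(xs, beta_deviation, numeric(1),
                              mu = 1, sigma = 2)) > 0))
  expect_error(beta_deviation(1, 0, 0), "positive")
})

test_that("collapse percentage floors at zero above baseline", {
  expect_equal(as.numeric(collapse_percentage(12, 12)), 0)
  expect_equal(as.numeric(collapse_percentage(6, 12)), 50)
  cp <- collapse_percentage(13.2, 12)
  expect_equal(as.numeric(cp), 0)
  expect_true(attr(cp, "above_baseline"))
  expect_error(collapse_percentage(10, 0), "baseline")
})

test_that("criteria and baseline tables round-trip through files", {
  cr <- eq_sigma_criteria()
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(grade = rev(cr$grades), mu = rev(cr$mu),
                              sigma = rev(cr$sigma)), csv, row.names = FALSE)
  back <- read_grading_criteria(csv)     # unordered rows get sorted
  expect_equal(back$mu, cr$mu)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(grade = cr$grades, mu = cr$mu,
                            sigma = cr$sigma), js)
  expect_equal(read_grading_criteria(js)$sigma, cr$sigma)

  bl <- synthetic_baseline()
  bcsv <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(bl), bcsv, row.names = FALSE)
  expect_equal(read_baseline_table(bcsv)$mu, bl$mu)
})

test_that("healthy phantom reports grade 1 with near-zero deviations", {
  ph <- generate_phantom(phantom_spec(noise_sd = 2))
  m <- measure_spine(ph$image, ph$mask)
  rep <- build_report(m, synthetic_criteria(), synthetic_baseline(),
                      subject = list(gender = 0, age_band = "all"))
  expect_equal(rep$discs$grade, rep(1, 5))
  expect_true(all(abs(rep$discs$beta_delta_si) < 1))
  expect_true(all(abs(rep$discs$beta_DHI) < 1))
  expect_true(all(rep$discs$collapse_pct < 5))
})

test_that("collapsed series endpoint grades worst with negative betas", {
  series <- degeneration_series(phantom_spec(noise_sd = 0), n_steps = 5)
  last <- series[[5]]
  m <- measure_spine(last$image, last$mask)
  rep <- build_report(m, synthetic_criteria(), synthetic_baseline(),
                      subject = list(gender = 1, age_band = "all"))
  expect_equal(rep$discs$grade, rep(5, 5))
  expect_true(all(rep$discs$beta_DHI < 0))
  expect_true(all(rep$discs$beta_HDR < 0))
  expect_true(all(rep$discs$collapse_pct > 40))
})

test_that("unknown subject keys raise lookup errors", {
  ph <- generate_phantom(phantom_spec())
  m <- measure_spine(ph$image, ph$mask)
  expect_error(build_report(m, synthetic_criteria(), synthetic_baseline(),
                            subject = list(gender = 9, age_band = "all")),
               "lookup error")
})
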