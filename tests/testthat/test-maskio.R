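test_that("class map validates shape and ids", {
  cm <- ivd_class_map()
  expect_length(cm, 14)
  expect_identical(cm[["background"]], 0L)
  expect_error(ivd_class_map(cm[1:13]), "exactly 14")
  bad <- stats::setNames(c(0L, rep(1L, 13)), names(cm))
  expect_error(ivd_class_map(bad), "unique")
  tmp <- tempfile(fileext = ".json")
  write_class_map(cm, tmp)
  expect_identical(as.integer(read_class_map(tmp)), as.integer(cm))
})

test_that("PNG intensities are read on their stored scale", {
  tmp <- tempfile(fileext = ".png")
  png::writePNG(matrix(120 / 255, 10, 8), tmp)
  img <- read_image(tmp)
  expect_equal(dim(img), c(10, 8))
  expect_true(all(img == 120))
  # 16-bit values survive without rescaling to 255
  write_image(matrix(c(0, 300, 40000, 65535), 2, 2), tmp)
  expect_identical(as.vector(read_image(tmp)), c(0, 300, 40000, 65535))
})

test_that("NIfTI volumes yield the middle sagittal slice by default", {
  tmp <- tempfile(fileext = ".nii.gz")
  vol <- array(0, c(6, 5, 9))
  for (k in 1:9) vol[, , k] <- k * 10
  RNifti::writeNifti(RNifti::asNifti(vol), tmp)
  img <- read_image(tmp)            # slice 5 of 9 (index 4, 0-based)
  expect_true(all(img == 50))
  expect_true(all(read_image(tmp, slice = 2) == 20))
  expect_error(read_image(tmp, slice = 10), "out of range")
})

test_that("label masks round-trip through PNG and validate ids", {
  ph <- generate_phantom(phantom_spec())
  tmp <- tempfile(fileext = ".png")
  write_label_mask(ph$mask, tmp)
  back <- read_label_mask(tmp)
  expect_identical(as.integer(back), as.integer(ph$mask))

  bad <- matrix(0L, 4, 4); bad[2, 2] <- 17L
  png::writePNG(bad / 255, tmp)
  expect_error(read_label_mask(tmp), "17")
  expect_silent(label_mask(matrix(0L, 5, 5)))
})

test_that("clean_mask removes burrs and matches a morphological oracle", {
  m <- matrix(0L, 30, 40)
  m[8:20, 5:25] <- 1L
  m[14, 26:27] <- 1L               # 1-px spur on the right edge
  m[3, 10] <- 1L                   # isolated island
  cleaned <- clean_mask(label_mask(m), radius = 1)
  expect_equal(sum(cleaned == 1L & m == 0L), 0)   # nothing added
  expect_identical(as.integer(cleaned[14, 26:27]), c(0L, 0L))
  expect_identical(cleaned[3, 10], 0L)
  expect_true(all(cleaned[9:19, 6:24] == 1L))     # interior intact

  # independent oracle: erosion-then-dilation with the 3x3 box (the disc
  # structuring element of radius 1), written as plain shift logic
  shift_all <- function(b, combine) {
    nr <- nrow(b); nc <- ncol(b)
    p <- matrix(!combine, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- b
    out <- p[2:(nr + 1), 2:(nc + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      s <- p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
      out <- if (combine) out | s else out & s
    }
    out
  }
  erode1 <- function(b) shift_all(b, FALSE)
  dilate1 <- function(b) shift_all(b, TRUE)
  m2 <- matrix(0L, 25, 25)
  m2[5:15, 4:20] <- 2L
  m2[16, 9] <- 2L; m2[4, 4:5] <- 2L
  oracle <- dilate1(erode1(m2 == 2L))
  got <- clean_mask(label_mask(m2), radius = 1) == 2L
  expect_identical(got, oracle)
})

test_that("clean_mask cleans classes independently and is idempotent", {
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L; m[15, 9] <- 1L     # burr of class 1 toward class 2
  m[16:25, 5:14] <- 2L; m[15, 10] <- 2L   # burr of class 2 toward class 1
  lm <- label_mask(m)
  c1 <- clean_mask(lm, radius = 1)
  expect_identical(c1[15, 9], 0L)
  expect_identical(c1[15, 10], 0L)
  expect_identical(as.integer(clean_mask(c1, radius = 1)), as.integer(c1))
  # classes still partition the image
  counts <- table(factor(as.integer(c1), levels = 0:13))
  expect_equal(sum(counts), length(c1))
})

test_that("extract_structure keeps the largest component and flags others", {
  m <- matrix(0L, 20, 40)
  m[5:14, 2:11] <- 3L                     # 100 px
  m[17, 30:32] <- 3L                      # 3 px fragment
  lm <- label_mask(m)
  expect_warning(reg <- extract_structure(lm, 3L), "2 connected components")
  expect_equal(sum(reg), 100)
  expect_error(extract_structure(lm, 4L), "absent-structure")
  expect_error(extract_structure(lm, 99L), "not in the class map")
})

test_that("phantom structure pixel counts match extract_structure", {
  ph <- generate_phantom(phantom_spec())
  reg <- extract_structure(ph$mask, "VB_L3")
  expect_equal(sum(reg), sum(ph$mask == ivd_class_map()[["VB_L3"]]))
})
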