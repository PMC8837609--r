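#' Canonical 14-class anatomical label map
#'
#' The quantitation pipeline works on sagittal lumbar label masks with 14
#' anatomical classes: background, the five lumbar vertebral bodies (L1-L5),
#' the five intervertebral discs (L1/L2-L5/S1), the sacrum, the presacral fat
#' area and the cerebrospinal fluid (CSF) band in the spinal canal.
#'
#' Class ids are fixed so that mask files written by one tool are readable by
#' another: 0 background, 1-5 vertebral bodies superior to inferior, 6-10
#' discs L1/L2 to L5/S1, 11 sacrum, 12 presacral fat, 13 CSF. A different
#' assignment can be supplied wherever a `class_map` argument is accepted.
#'
#' @param roles Named integer vector mapping role name to class id. Defaults
#'   to the canonical assignment described above.
#' @return An object of class `ivd_class_map`: a named integer vector with
#'   exactly 14 unique ids, id 0 being `background`.
#' @examples
#' cm <- ivd_class_map()
#' cm[["DISC_L4L5"]]
#' @export
ivd_class_map <- function(roles = NULL) {
  if (is.null(roles)) {
    roles <- c(
      background = 0L,
      VB_L1 = 1L, VB_L2 = 2L, VB_L3 = 3L, VB_L4 = 4L, VB_L5 = 5L,
      DISC_L1L2 = 6L, DISC_L2L3 = 7L, DISC_L3L4 = 8L, DISC_L4L5 = 9L,
      DISC_L5S1 = 10L,
      SACRUM = 11L, PRESACRAL_FAT = 12L, CSF = 13L
    )
  }
  roles <- vapply(roles, as.integer, integer(1))
  if (length(roles) != 14L) {
    stop("class map must have exactly 14 entries, got ", length(roles))
  }
  if (anyDuplicated(roles)) stop("class map ids must be unique")
  if (is.null(names(roles)) || any(!nzchar(names(roles)))) {
    stop("class map entries must be named by role")
  }
  if (!"background" %in% names(roles) || roles[["background"]] != 0L) {
    stop("class map must assign id 0 to 'background'")
  }
  structure(roles, class = "ivd_class_map")
}

#' @export
print.ivd_class_map <- function(x, ...) {
  cat("14-class anatomical label map:\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# Role name groups used repeatedly downstream.
vb_roles <- function() paste0("VB_L", 1:5)
disc_roles <- function() c("DISC_L1L2", "DISC_L2L3", "DISC_L3L4",
                           "DISC_L4L5", "DISC_L5S1")
disc_segments <- function() c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")

#' Read or write a class map as JSON
#'
#' @param path File path of a JSON object mapping role names to integer ids.
#' @return `read_class_map` returns an [ivd_class_map()].
#' @export
read_class_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ivd_class_map(unlist(x))
}

#' @rdname read_class_map
#' @param class_map An [ivd_class_map()].
#' @export
write_class_map <- function(class_map, path) {
  jsonlite::write_json(as.list(stats::setNames(as.integer(class_map),
                                               names(class_map))),
                       path, auto_unbox = TRUE)
  invisible(path)
}
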