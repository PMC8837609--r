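#' End-to-end quantitation of one image/mask pair
#'
#' Runs the full pipeline: optional morphological cleanup, structure
#' extraction, corner detection, disc landmarks, geometric parameters,
#' disc/CSF histograms, the normalized peak signal-intensity difference,
#' and deviation-based grading. Per-structure failures are collected as
#' flags; the report is partial rather than absent.
#'
#' @param image Numeric intensity matrix (see [read_image()]).
#' @param mask An `ivd_label_mask` (see [read_label_mask()]).
#' @param criteria A [grading_criteria()].
#' @param baseline Optional [baseline_table()].
#' @param subject List with `gender` and `age_band` (used with `baseline`).
#' @param config A [quant_config()].
#' @return A `degeneration_report` (see [build_report()]) with the
#'   underlying `spine_measure` attached as attribute `measures`.
#' @export
quantify <- function(image, mask, criteria, baseline = NULL,
                     subject = list(gender = 0, age_band = "all"),
                     config = quant_config()) {
  meas <- measure_spine(image, mask, config)
  rep <- build_report(meas, criteria, baseline, subject)
  attr(rep, "measures") <- meas
  rep
}

#' @rdname quantify
#' @export
pipeline_end_to_end <- quantify

report_schema_version <- "1"

#' Write a degeneration report as JSON / CSV
#'
#' The JSON report contains a `schema_version`, a provenance block (package
#' version, configuration, generation time), per-vertebra diameters and
#' heights, and the per-disc parameter/grading table. The CSV holds one row
#' per disc. Apart from the timestamp the output is a pure function of its
#' inputs.
#'
#' @param report A `degeneration_report` from [quantify()].
#' @param path Output file path.
#' @param config The [quant_config()] used (stored as provenance).
#' @export
write_report_json <- function(report, path, config = quant_config()) {
  obj <- list(
    schema_version = report_schema_version,
    provenance = list(
      package = "ivdquant",
      version = as.character(utils::packageVersion("ivdquant")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = config[order(names(config))]
    ),
    subject = report$subject,
    vertebrae = report$vertebrae,
    discs = report$discs,
    flags = as.list(report$flags)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$discs, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate predicted masks against reference masks
#'
#' Convenience wrapper computing per-class dice/IoU and their means for
#' paired mask files or matrices.
#'
#' @param pred,truth Label matrices (or paths readable by
#'   [read_label_mask()]).
#' @param classes Class ids to evaluate.
#' @return List with `per_class`, `mdice`, `miou`.
#' @export
evaluate_masks <- function(pred, truth, classes = 0:13) {
  if (is.character(pred)) pred <- read_label_mask(pred)
  if (is.character(truth)) truth <- read_label_mask(truth)
  pc <- dice_per_class(pred, truth, classes)
  list(per_class = pc, mdice = mean(pc$dice), miou = mean(pc$iou))
}
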