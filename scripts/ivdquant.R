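#!/usr/bin/env Rscript
# Command-line front end for the ivdquant package.
#
# Usage:
#   Rscript scripts/ivdquant.R phantom  --preset healthy|degenerate --n 10 \
#       --seed 7 --out DIR [--noise-sd 3]
#   Rscript scripts/ivdquant.R quantify --image I.png --mask M.png \
#       --criteria C.csv [--baseline B.csv --gender 0 --age-band all] \
#       [--spacing MM] [--config CFG.yaml] --out DIR
#   Rscript scripts/ivdquant.R evaluate --pred DIR --truth DIR --out metrics.csv
#   Rscript scripts/ivdquant.R segment  --weights W.rds --image I.png --out M.png
#
# Exit codes: 0 success, 2 success with flags (partial results), 1 failure.

suppressMessages({
  library(ivdquant)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("usage: ivdquant.R <phantom|quantify|evaluate|segment> [options]")
  quit(status = 1)
}
cmd <- args[1]
rest <- args[-1]

die <- function(...) { message("error: ", ...); quit(status = 1) }

opt_list <- list(
  make_option("--preset", default = "healthy"),
  make_option("--n", type = "integer", default = 1L),
  make_option("--seed", type = "integer", default = 7L),
  make_option("--noise-sd", dest = "noise_sd", type = "double", default = 3),
  make_option("--image", default = NULL),
  make_option("--mask", default = NULL),
  make_option("--criteria", default = NULL),
  make_option("--baseline", default = NULL),
  make_option("--gender", type = "integer", default = 0L),
  make_option("--age-band", dest = "age_band", default = "all"),
  make_option("--spacing", type = "double", default = NULL),
  make_option("--config", default = NULL),
  make_option("--pred", default = NULL),
  make_option("--truth", default = NULL),
  make_option("--weights", default = NULL),
  make_option("--out", default = ".")
)
opt <- parse_args(OptionParser(option_list = opt_list), args = rest)

load_config <- function(opt) {
  cfg <- quant_config()
  if (!is.null(opt$config)) {
    y <- yaml::read_yaml(opt$config)
    for (blk in c("histogram", "geometry")) {
      if (!is.null(y[[blk]])) cfg[names(y[[blk]])] <- y[[blk]]
    }
    if (length(y$quant)) cfg[names(y$quant)] <- y$quant
  }
  if (!is.null(opt$spacing)) {
    if (opt$spacing <= 0) die("spacing must be positive")
    cfg$spacing <- opt$spacing
  }
  cfg
}

if (cmd == "phantom") {
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(opt$n)) {
    spec <- phantom_preset(opt$preset, seed = opt$seed + k - 1L,
                           noise_sd = opt$noise_sd)
    ph <- generate_phantom(spec)
    write_image(ph$image, file.path(opt$out, sprintf("sample_%d_img.png", k)))
    write_label_mask(ph$mask,
                     file.path(opt$out, sprintf("sample_%d_mask.png", k)))
    jsonlite::write_json(ph$truth,
                         file.path(opt$out,
                                   sprintf("sample_%d_truth.json", k)),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  message("wrote ", opt$n, " phantom sample(s) to ", opt$out)
  quit(status = 0)
}

if (cmd == "quantify") {
  if (is.null(opt$image) || is.null(opt$mask)) die("--image and --mask required")
  for (p in c(opt$image, opt$mask, opt$criteria, opt$baseline, opt$config)) {
    if (!is.null(p) && !file.exists(p)) die("file not found: ", p)
  }
  cfg <- load_config(opt)
  criteria <- if (!is.null(opt$criteria)) read_grading_criteria(opt$criteria)
    else synthetic_criteria()
  baseline <- if (!is.null(opt$baseline)) read_baseline_table(opt$baseline)
    else NULL
  img <- read_image(opt$image)
  msk <- read_label_mask(opt$mask)
  rep <- quantify(img, msk, criteria, baseline,
                  subject = list(gender = opt$gender,
                                 age_band = opt$age_band),
                  config = cfg)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  write_report_json(rep, file.path(opt$out, "report.json"), config = cfg)
  write_report_csv(rep, file.path(opt$out, "report.csv"))
  message("report written to ", opt$out)
  flags <- setdiff(rep$flags, "l5s1_dhi_uses_l5_only")
  quit(status = if (length(flags)) 2 else 0)
}

if (cmd == "evaluate") {
  if (is.null(opt$pred) || is.null(opt$truth)) die("--pred and --truth required")
  list_masks <- function(dir) {
    m <- sort(list.files(dir, pattern = "_mask\\.png$", full.names = TRUE))
    if (length(m)) m else sort(list.files(dir, pattern = "\\.png$",
                                          full.names = TRUE))
  }
  preds <- list_masks(opt$pred)
  truths <- list_masks(opt$truth)
  if (length(preds) != length(truths) || length(preds) == 0) {
    die("pred/truth directories must contain matching PNG masks")
  }
  rows <- lapply(seq_along(preds), function(i) {
    ev <- evaluate_masks(preds[i], truths[i])
    data.frame(file = basename(preds[i]), mdice = ev$mdice, miou = ev$miou)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(file = "mean", mdice = mean(out$mdice),
                               miou = mean(out$miou)))
  utils::write.csv(out, opt$out, row.names = FALSE)
  message("metrics written to ", opt$out)
  quit(status = 0)
}

if (cmd == "segment") {
  if (is.null(opt$weights) || is.null(opt$image)) {
    die("--weights and --image required (no weights ship with the package)")
  }
  model <- load_weights(opt$weights)
  img <- read_image(opt$image)
  mask <- segment_image(model, img)
  write_label_mask(label_mask(mask), opt$out)
  message("mask written to ", opt$out)
  quit(status = 0)
}

die("unknown command: ", cmd)
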