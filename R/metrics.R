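#' Per-class dice and IoU between two label masks
#'
#' For each class `c` in `0..C-1`, dice is `2|G∩P| / (|G| + |P|)` and IoU
#' (the Jaccard index) is `|G∩P| / |G∪P|`, where `G` and `P` are the pixel
#' sets of the class in the truth and predicted masks. A class absent from
#' both masks agrees vacuously and scores 1 (flagged in the `vacuous`
#' column); the evaluated scenes normally contain all 14 classes, but
#' phantoms and crops may not.
#'
#' @param pred,truth Integer label matrices of the same shape.
#' @param classes Integer vector of class ids to evaluate (default
#'   `0:13`).
#' @return Data frame with columns `class`, `dice`, `iou`, `vacuous`.
#' @export
dice_per_class <- function(pred, truth, classes = 0:13) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch between masks")
  p <- as.integer(pred); g <- as.integer(truth)
  out <- data.frame(class = classes, dice = NA_real_, iou = NA_real_,
                    vacuous = FALSE)
  for (k in seq_along(classes)) {
    cl <- classes[k]
    np <- sum(p == cl); ng <- sum(g == cl)
    if (np == 0 && ng == 0) {
      out$dice[k] <- 1; out$iou[k] <- 1; out$vacuous[k] <- TRUE
      next
    }
    inter <- sum(p == cl & g == cl)
    out$dice[k] <- 2 * inter / (np + ng)
    out$iou[k] <- inter / (np + ng - inter)
  }
  out
}

#' Mean dice over classes
#' @inheritParams dice_per_class
#' @export
mdice <- function(pred, truth, classes = 0:13) {
  mean(dice_per_class(pred, truth, classes)$dice)
}

#' Mean intersection-over-union over classes
#' @inheritParams dice_per_class
#' @export
miou <- function(pred, truth, classes = 0:13) {
  mean(dice_per_class(pred, truth, classes)$iou)
}

#' Macro-averaged F1 from a confusion table
#'
#' Rows are true grades, columns predicted grades. Per-class precision is
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 their harmonic mean (0 where
#' undefined). The macro F1 averages the F1 of the classes with nonzero
#' support (at least one true instance); grades absent from the evaluated
#' cohort do not dilute the mean.
#'
#' @param table Square numeric matrix of counts `[true, predicted]`.
#' @return List: `per_class` data frame (`precision`, `recall`, `f1`,
#'   `support`), `macro_f1`.
#' @export
macro_f1 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) stop("confusion table must be square")
  if (sum(table) <= 0) stop("empty confusion table")
  g <- nrow(table)
  tp <- diag(table)
  support <- rowSums(table)
  pred_n <- colSums(table)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = seq_len(g), precision = precision,
                          recall = recall, f1 = f1, support = support)
  list(per_class = per_class,
       macro_f1 = mean(f1[support > 0]))
}

#' Single-measure absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way model with random subjects and fixed raters, absolute-agreement
#' definition, single measures: the consistency statistic used to compare
#' automated and manual parameter measurements. Computed from the two-way
#' mean squares with the F-based 95\% confidence interval.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, at least 5 subjects and 2 raters.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return List: `icc`, `lower`, `upper`, `n`, `k`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells in the ratings matrix")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("need at least 5 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((sweep(sweep(ratings, 1, row_m), 2, col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    return(list(icc = icc, lower = icc, upper = icc, n = n, k = k))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, n = n, k = k)
}
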