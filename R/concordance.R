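#' Compare two variant call sets over a region of known size
#'
#' Site-level confusion matrix at base resolution: sites are matched
#' on the exact (chrom, pos, ref, alt) key, with no normalization of
#' alternate indel representations. TP are shared sites, FP sites
#' only in the test set, FN sites only in the truth set, and every
#' remaining base of the region counts as a true negative, so
#' tp + fp + fn + tn always equals `region_len`.
#'
#' @param test,truth data frames with columns chrom, pos, ref, alt
#'   (duplicate sites are collapsed).
#' @param region_len region size in bases; must be at least the size
#'   of the union of the two call sets.
#' @return List of class `confusion_matrix` with tp, fp, fn, tn and
#'   region_len.
#' @export
compare_callsets <- function(test, truth, region_len) {
  key <- function(x) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
    unique(paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  }
  a <- key(test); b <- key(truth)
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  confusion_matrix(tp, fp, fn, region_len = region_len)
}

#' Construct a confusion matrix over a region
#'
#' @param tp,fp,fn non-negative site counts.
#' @param tn true-negative count; derived as
#'   `region_len - tp - fp - fn` when omitted.
#' @param region_len total bases in the evaluated region.
#' @return List of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn = NULL, region_len = NULL) {
  if (is.null(tn)) {
    if (is.null(region_len)) stop("give either tn or region_len")
    tn <- region_len - tp - fp - fn
    if (tn < 0)
      stop("region_len (", region_len,
           ") smaller than the union of call sets (", tp + fp + fn, ")")
  } else if (is.null(region_len)) {
    region_len <- tp + fp + fn + tn
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0,
            tp + fp + fn + tn == region_len)
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn, region_len = region_len)
  class(out) <- "confusion_matrix"
  out
}

#' Accuracy metrics from a confusion matrix
#'
#' Sensitivity (true positive rate) TP/(TP+FN); specificity (true
#' negative rate) TN/(FP+TN); precision (positive predictive value)
#' TP/(TP+FP); accuracy (TP+TN)/(TP+FP+FN+TN). The maximum false
#' positive rate is FP over the test-set size FP/(TP+FP) and the
#' maximum false negative rate FN/(TP+FN) — "maximum" because every
#' discordant site is charged as an error of the respective set. A
#' metric whose denominator is zero is returned as NA (undefined).
#'
#' @param cm a [confusion_matrix()].
#' @return List of class `metric_set` with sensitivity, specificity,
#'   precision, accuracy, max_fp_rate, max_fn_rate (fractions in
#'   [0, 1] or NA).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$fp + cm$tn),
    precision = safe_div(cm$tp, cm$tp + cm$fp),
    accuracy = safe_div(cm$tp + cm$tn, cm$region_len),
    max_fp_rate = safe_div(cm$fp, cm$tp + cm$fp),
    max_fn_rate = safe_div(cm$fn, cm$tp + cm$fn))
  class(out) <- "metric_set"
  out
}

#' Round half-up to a number of decimals
#'
#' Commercial rounding (0.5 always rounds away from zero), as used
#' when reporting percentages; base R's `round()` rounds half to
#' even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a metric set as printed percentages
#'
#' Sensitivity, precision and the FP/FN rates are printed to one
#' decimal; specificity and accuracy to three decimals (they sit so
#' close to 100% that one decimal would hide all information).
#' Rounding is half-up.
#'
#' @param ms a [metric_set()].
#' @return Named character vector like `"95.3%"`.
#' @export
format_percent <- function(ms) {
  stopifnot(inherits(ms, "metric_set"))
  digits <- c(sensitivity = 1, specificity = 3, precision = 1,
              accuracy = 3, max_fp_rate = 1, max_fn_rate = 1)
  out <- vapply(names(digits), function(k) {
    x <- ms[[k]]
    if (is.na(x)) return(NA_character_)
    paste0(formatC(round_half_up(100 * x, digits[k]),
                   format = "f", digits = digits[k]), "%")
  }, character(1))
  out
}

#' Write a concordance report as JSON
#'
#' @param cm a [confusion_matrix()].
#' @param path output JSON path.
#' @return The report list, invisibly.
#' @export
write_concordance_report <- function(cm, path) {
  ms <- metrics(cm)
  report <- list(counts = unclass(cm), fractions = unclass(ms),
                 percent = as.list(format_percent(ms)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(report)
}
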