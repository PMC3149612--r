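#' Per-condition summed abundances
#'
#' Sums a layer over a condition's replicate runs, the per-protein
#' condition summary used for fold ratios ("sum of RSpC values of three
#' independent measurements").
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param condition condition label.
#' @param layer assay to sum (default `"RSpC"`).
#' @return named numeric vector of per-protein sums.
#' @export
summarizeCondition <- function(x, condition, layer = "RSpC") {
  if (!layer %in% assayNames(x)) .stop("no layer '", layer, "'")
  runs <- conditionRuns(x, condition)
  m <- assay(x, layer)[, runs, drop = FALSE]
  rowSums(m)
}

#' Fold ratio with censoring sentinels
#'
#' `numerator / denominator` at full precision, with the censoring used in
#' spectral-count reporting: a zero denominator yields the sentinel
#' `">50"` (detected only in the numerator sample, ratio off-scale), a
#' zero numerator yields ratio 0 (displayed at the chosen precision), and
#' 0/0 is an error. `digits` controls only the display string; published
#' tables use one decimal for moderate ratios, integers for large
#' up-regulation ratios, and two decimals for small down-regulation
#' ratios, so the precision is the caller's choice.
#'
#' @param numerator,denominator non-negative numeric vectors.
#' @param digits decimal places for the display strings (default 1).
#' @return list of class `"fold_ratio"` with components `value` (numeric;
#'   `Inf` when censored) and `display` (character; `">50"` when censored).
#' @examples
#' foldRatio(4106, 2119)$display  # "1.9"
#' foldRatio(77, 0)$display       # ">50"
#' @export
foldRatio <- function(numerator, denominator, digits = 1) {
  if (length(numerator) != length(denominator))
    .stop("numerator and denominator lengths differ")
  if (any(numerator < 0 | denominator < 0))
    .stop("fold ratio inputs must be non-negative")
  if (any(numerator == 0 & denominator == 0))
    .stop("fold ratio undefined for 0/0")
  value <- ifelse(denominator == 0, Inf, numerator / denominator)
  display <- ifelse(is.infinite(value), ">50",
                    formatC(round(value, digits), format = "f", digits = digits))
  structure(list(value = value, display = display), class = "fold_ratio")
}

#' @export
print.fold_ratio <- function(x, ...) {
  print(setNames(x$display, format(x$value, digits = 4)), ...)
  invisible(x)
}

#' Symmetric fold-change classification
#'
#' Classifies a ratio into the fold bands used for reporting relative
#' abundance changes: `ge3` (>= 3-fold), `two_to_three` (2-3 fold),
#' `1p5_to_2` (1.5-2 fold) and `lt1p5` (< 1.5-fold, "unchanged"). The
#' classification is symmetric: `r` and `1/r` fall in the same band with
#' opposite direction. Censored ratios (`Inf`, or 0 with a non-zero
#' denominator) map to `ge3`.
#'
#' @param ratio numeric vector of fold ratios (target / reference).
#' @param thresholds increasing band boundaries (default `c(1.5, 2, 3)`).
#' @return data.frame with columns `fold_class` and `direction`
#'   (`up` / `down` / `unchanged`).
#' @examples
#' classifyChange(c(5, 1, 0.4))
#' @export
classifyChange <- function(ratio, thresholds = c(1.5, 2, 3)) {
  if (length(thresholds) != 3L || is.unsorted(thresholds))
    .stop("thresholds must be three increasing values")
  if (any(ratio < 0, na.rm = TRUE)) .stop("ratios must be non-negative")
  m <- pmax(ratio, ifelse(ratio == 0, Inf, 1 / ratio))  # fold magnitude
  cls <- cut(m, c(-Inf, thresholds, Inf),
             labels = c("lt1p5", "1p5_to_2", "two_to_three", "ge3"),
             right = FALSE, include.lowest = TRUE)
  # cut() puts m == threshold into the upper band (right = FALSE), as wanted
  dir <- ifelse(cls == "lt1p5", "unchanged", ifelse(ratio > 1, "up", "down"))
  data.frame(fold_class = as.character(cls), direction = dir,
             stringsAsFactors = FALSE)
}

# pooled- or Welch-variance two-sample t on log2 values; returns p
.t_log2 <- function(a, b, var_equal = TRUE) {
  if (any(a <= 0) || any(b <= 0)) return(NA_real_)  # not testable
  x <- log2(a); y <- log2(b)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) return(if (m1 == m2) 1 else 0)
  2 * pt(-abs((m1 - m2) / se), df)
}

#' Two-sample t-test on log2 spectral counts
#'
#' Student's (pooled-variance) two-sided t-test on log2-transformed
#' counts, the standard significance test for spectral-count data; Welch's
#' unequal-variance variant is available with `var_equal = FALSE`. A
#' protein is testable only when detected (value > 0) in every replicate
#' of both conditions; otherwise `NA` is returned rather than an error.
#'
#' @param x a \linkS4class{SpectralCountExperiment} or a numeric vector
#'   (first group).
#' @param ... method arguments: for the experiment method, `accession`,
#'   `condition_a`, `condition_b`, optional `layer` (default `"RSpC"`) and
#'   `var_equal`; for the numeric method, `y` (second group) and
#'   `var_equal`.
#' @return two-sided p-value in (0, 1\], or `NA` when not testable.
#' @examples
#' ttestLog2(c(4, 4.0001, 4), y = c(8, 8.0001, 8))
#' @export
setGeneric("ttestLog2", function(x, ...) standardGeneric("ttestLog2"))

#' @rdname ttestLog2
#' @param y numeric vector, second group (numeric method).
#' @param var_equal pooled variance (TRUE, Student) or Welch (FALSE).
#' @export
setMethod("ttestLog2", "numeric", function(x, y, var_equal = TRUE) {
  .t_log2(x, y, var_equal)
})

#' @rdname ttestLog2
#' @param accession protein accession to test.
#' @param condition_a,condition_b condition labels.
#' @param layer assay holding the values (default `"RSpC"`).
#' @export
setMethod("ttestLog2", "SpectralCountExperiment",
  function(x, accession, condition_a, condition_b, layer = "RSpC",
           var_equal = TRUE) {
    if (!accession %in% rownames(x)) .stop("unknown accession: ", accession)
    m <- assay(x, layer)
    a <- m[accession, conditionRuns(x, condition_a)]
    b <- m[accession, conditionRuns(x, condition_b)]
    .t_log2(a, b, var_equal)
  })

#' Differential-abundance table between two conditions
#'
#' One row per detected protein of the analyzed organism, with
#' per-condition summed abundances, the (possibly censored) fold ratio
#' target/reference, its symmetric fold-class and direction, the log2
#' t-test p-value for proteins detected in every replicate of both
#' conditions, and a detection class (`both`, `reference_only`,
#' `target_only`). Rows are sorted by decreasing |log2 ratio| (censored
#' ratios first). Raw p-values are compared against `alpha` by default;
#' `p_adjust = "BH"` applies Benjamini-Hochberg correction first.
#'
#' @param x a \linkS4class{SpectralCountExperiment} with an `RSpC` layer.
#' @param reference_condition,target_condition condition labels; the ratio
#'   is target / reference.
#' @param organism organism to analyze (default `"host"`).
#' @param alpha significance level (default 0.05).
#' @param layer assay to summarize (default `"RSpC"`).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @param digits display precision for the ratio strings.
#' @return data.frame with columns `accession`, `sum_reference`,
#'   `sum_target`, `ratio`, `ratio_display`, `fold_class`, `direction`,
#'   `p_value`, `significant`, `detection`.
#' @export
differentialTable <- function(x, reference_condition = "pure_host",
                              target_condition = "coculture",
                              organism = "host", alpha = 0.05,
                              layer = "RSpC", p_adjust = "none",
                              var_equal = TRUE, digits = 1) {
  ref <- summarizeCondition(x, reference_condition, layer)
  tgt <- summarizeCondition(x, target_condition, layer)
  org <- proteinOrganism(x) == organism
  detected <- org & (ref > 0 | tgt > 0)
  acc <- rownames(x)[detected]
  if (!length(acc)) .stop("no detected proteins of organism '", organism, "'")
  ref <- ref[acc]; tgt <- tgt[acc]

  fr <- foldRatio(tgt, ref, digits = digits)
  cls <- classifyChange(fr$value)
  m <- assay(x, layer)
  ref_runs <- conditionRuns(x, reference_condition)
  tgt_runs <- conditionRuns(x, target_condition)
  pvals <- vapply(acc, function(a)
    .t_log2(m[a, ref_runs], m[a, tgt_runs], var_equal), numeric(1))
  padj <- if (p_adjust == "none") pvals else p.adjust(pvals, method = p_adjust)
  detection <- ifelse(ref > 0 & tgt > 0, "both",
                      ifelse(tgt > 0, "target_only", "reference_only"))
  out <- data.frame(
    accession = acc,
    sum_reference = unname(ref), sum_target = unname(tgt),
    ratio = unname(fr$value), ratio_display = unname(fr$display),
    fold_class = cls$fold_class, direction = cls$direction,
    p_value = unname(pvals),
    significant = !is.na(padj) & padj <= alpha,
    detection = detection,
    stringsAsFactors = FALSE
  )
  mag <- abs(log2(ifelse(out$ratio == 0, Inf, out$ratio)))
  out <- out[order(-mag, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
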