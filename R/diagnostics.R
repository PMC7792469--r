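#' Paired virtual/invasive FFR table
#'
#' @param patient_id,vessel_id identifiers; the (patient, vessel) pair must
#'   be unique.
#' @param virtual_ffr,invasive_ffr values in (0, 1.2].
#' @return data.frame of class `paired_ffr`.
#' @export
paired_ffr <- function(patient_id, vessel_id, virtual_ffr, invasive_ffr) {
  df <- data.frame(patient_id = as.character(patient_id),
                   vessel_id = as.character(vessel_id),
                   virtual_ffr = as.numeric(virtual_ffr),
                   invasive_ffr = as.numeric(invasive_ffr),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("paired FFR table must be non-empty")
  bad <- !is.finite(df$virtual_ffr) | df$virtual_ffr <= 0 |
    df$virtual_ffr > 1.2 | !is.finite(df$invasive_ffr) |
    df$invasive_ffr <= 0 | df$invasive_ffr > 1.2
  if (any(bad)) stop("FFR values must lie in (0, 1.2]")
  if (anyDuplicated(df[c("patient_id", "vessel_id")]))
    stop("duplicate (patient, vessel) pair")
  class(df) <- c("paired_ffr", "data.frame")
  df
}

#' Confusion table of virtual vs invasive calls
#'
#' Invasive FFR < threshold (strict) defines ground-truth positive; virtual
#' FFR < threshold defines a positive test.  At `level = "patient"` both
#' sides are first aggregated with the any-ischemic-vessel rule.
#'
#' @param paired a [paired_ffr()] table.
#' @param threshold decision threshold (default 0.80).
#' @param level `"vessel"` (default) or `"patient"`.
#' @return list of class `confusion_table` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(paired, threshold = 0.8,
                            level = c("vessel", "patient")) {
  stopifnot(inherits(paired, "paired_ffr"))
  level <- match.arg(level)
  if (level == "patient") {
    truth <- tapply(paired$invasive_ffr, paired$patient_id,
                    function(v) classify_patient(v, threshold))
    call <- tapply(paired$virtual_ffr, paired$patient_id,
                   function(v) classify_patient(v, threshold))
  } else {
    truth <- paired$invasive_ffr < threshold
    call <- paired$virtual_ffr < threshold
  }
  structure(list(tp = sum(call & truth), fp = sum(call & !truth),
                 fn = sum(!call & truth), tn = sum(!call & !truth),
                 level = level, threshold = threshold),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table per %s> tp=%d fp=%d fn=%d tn=%d\n",
              x$level, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Wilson score interval (no continuity correction), as proportions in [0,1].
.wilson <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- n + z^2
  center <- (x + z^2 / 2) / denom
  hw <- z * sqrt(x * (n - x) / n + z^2 / 4) / denom
  c(lower = max(0, center - hw), upper = min(1, center + hw),
    estimate = p)
}

.round2 <- function(x) floor(x * 100 + 0.5) / 100   # half-up at 2 decimals

#' Diagnostic proportions with Wilson score intervals
#'
#' Sensitivity, specificity, PPV and NPV of a 2x2 table, each with a
#' two-sided Wilson score confidence interval (no continuity correction).
#' Estimates and bounds are percentages at full precision; the print method
#' rounds half-up to 2 decimals.  A metric with a zero denominator is
#' flagged undefined rather than propagating NaN.
#'
#' @param table a [confusion_table()].
#' @param level confidence level (default 0.95).
#' @return list of class `proportion_metrics`; each element is a
#'   `proportion_ci` with `estimate`, `lower`, `upper` (percent), `x`, `n`,
#'   `level`, `defined`.
#' @examples
#' m <- proportion_metrics(structure(list(tp = 16, fp = 4, fn = 8, tn = 15),
#'                                   class = "confusion_table"))
#' round(m$sensitivity$estimate, 2)  # 66.67
#' @export
proportion_metrics <- function(table, level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  one <- function(x, n) {
    if (n == 0)
      return(structure(list(estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, x = x, n = n, level = level,
                            defined = FALSE), class = "proportion_ci"))
    w <- .wilson(x, n, level)
    structure(list(estimate = 100 * w[["estimate"]],
                   lower = 100 * w[["lower"]], upper = 100 * w[["upper"]],
                   x = x, n = n, level = level, defined = TRUE),
              class = "proportion_ci")
  }
  structure(list(sensitivity = one(table$tp, table$tp + table$fn),
                 specificity = one(table$tn, table$tn + table$fp),
                 ppv = one(table$tp, table$tp + table$fp),
                 npv = one(table$tn, table$tn + table$fn),
                 level = level),
            class = "proportion_metrics")
}

#' @export
print.proportion_ci <- function(x, ...) {
  if (!x$defined) cat("undefined (zero denominator)\n")
  else cat(sprintf("%.2f%% (%g%% CI: %.2f-%.2f), %d/%d\n",
                   .round2(x$estimate), 100 * x$level, .round2(x$lower),
                   .round2(x$upper), x$x, x$n))
  invisible(x)
}

#' @export
print.proportion_metrics <- function(x, ...) {
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(format(nm, width = 12), ": ")
    print(x[[nm]])
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Labels are invasive FFR < threshold; scores are 1 - virtual FFR (higher
#' score = more ischemic).  AUC is the Mann-Whitney concordance with ties
#' counted 1/2, identical to the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param paired a [paired_ffr()] table.
#' @param threshold ground-truth threshold on invasive FFR.
#' @return list of class `roc_curve`: `auc` (fraction in [0,1]), and the
#'   empirical curve (`fpr`, `tpr`).
#' @export
roc_auc <- function(paired, threshold = 0.8) {
  stopifnot(inherits(paired, "paired_ffr"))
  label <- paired$invasive_ffr < threshold
  if (all(label) || !any(label)) stop("ROC requires both classes present")
  score <- 1 - paired$virtual_ffr
  n1 <- sum(label); n0 <- sum(!label)
  r <- rank(score)                       # midranks handle ties
  auc <- (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(score[label] >= s), 1)
  fpr <- vapply(thr, function(s) mean(score[!label] >= s), 1)
  structure(list(auc = auc, fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                 n_pos = n1, n_neg = n0), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Differences are virtual minus invasive; `bias` is their mean, `sd` the
#' sample standard deviation (n - 1), and the limits of agreement are
#' `bias +- 1.96 sd`.
#'
#' @param paired a [paired_ffr()] table with at least 2 rows.
#' @return list with `bias`, `sd`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(paired) {
  stopifnot(inherits(paired, "paired_ffr"))
  if (nrow(paired) < 2) stop("Bland-Altman requires at least 2 pairs")
  d <- paired$virtual_ffr - paired$invasive_ffr
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa_lower = bias - 1.96 * s,
       loa_upper = bias + 1.96 * s, n = length(d))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties) between virtual
#' and invasive FFR.
#'
#' @param paired a [paired_ffr()] table with at least 3 rows.
#' @return the correlation coefficient.
#' @export
spearman_rho <- function(paired) {
  stopifnot(inherits(paired, "paired_ffr"))
  if (nrow(paired) < 3) stop("Spearman correlation requires at least 3 pairs")
  if (stats::sd(paired$virtual_ffr) == 0 || stats::sd(paired$invasive_ffr) == 0)
    stop("constant column: rank correlation undefined")
  stats::cor(rank(paired$virtual_ffr), rank(paired$invasive_ffr))
}

#' Full concordance report
#'
#' Convenience wrapper computing the per-vessel and per-patient confusion
#' metrics, ROC/AUC, Bland-Altman and Spearman statistics of a cohort.
#'
#' @param paired a [paired_ffr()] table.
#' @param threshold decision threshold.
#' @param level confidence level for the Wilson intervals.
#' @return nested list of the individual results.
#' @export
concordance_report <- function(paired, threshold = 0.8, level = 0.95) {
  list(per_vessel = proportion_metrics(
         confusion_table(paired, threshold, "vessel"), level),
       per_patient = proportion_metrics(
         confusion_table(paired, threshold, "patient"), level),
       confusion_vessel = confusion_table(paired, threshold, "vessel"),
       confusion_patient = confusion_table(paired, threshold, "patient"),
       roc = tryCatch(roc_auc(paired, threshold), error = function(e) NULL),
       bland_altman = bland_altman(paired),
       spearman = tryCatch(spearman_rho(paired), error = function(e) NULL),
       n_pairs = nrow(paired))
}
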