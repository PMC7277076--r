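# Screening efficacy against a binary diagnostic reference: 2x2 indices,
# ROC/AUC, the integer cutoff scan, and the multi-index optimal-cutoff
# selection rule.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the table-formatting convention),
#' unlike base \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Confusion table of a score cutoff against a binary reference
#'
#' Screen-positive means \code{score >= cutoff}.
#'
#' @param scores per-person integer scores.
#' @param reference per-person binary (0/1) reference diagnosis.
#' @param cutoff integer threshold.
#' @return object of class \code{"confusion_table"}: list with integer
#'   counts \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
confusion_table <- function(scores, reference, cutoff) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(reference)) stop("unequal lengths")
  if (anyNA(scores) || anyNA(reference)) stop("missing values")
  if (!all(reference %in% c(0, 1))) stop("reference must be binary 0/1")
  pos <- scores >= cutoff
  new_confusion(tp = sum(pos & reference == 1), fp = sum(pos & reference == 0),
                fn = sum(!pos & reference == 1), tn = sum(!pos & reference == 0))
}

new_confusion <- function(tp, fp, fn, tn) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(screen = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Screening efficacy indices of a 2x2 table
#'
#' Sensitivity, specificity, positive/negative predictive rates (as
#' percentages), Cohen's kappa, Youden's J, and the diagnostic odds
#' ratio. DOR uses the cross-product \eqn{(tp \cdot tn)/(fp \cdot fn)};
#' when any cell is zero the Haldane correction adds 0.5 to all four
#' cells. Undefined ratios (empty margin) are returned as \code{NaN} and
#' flagged in \code{undefined}.
#'
#' @param t a \code{"confusion_table"}.
#' @return object of class \code{"efficacy_indices"}: list with
#'   \code{sensitivity}, \code{specificity}, \code{ppr}, \code{npr}
#'   (percent), \code{kappa}, \code{youden}, \code{dor},
#'   \code{undefined} (character vector of flagged ratios).
#' @export
efficacy_indices <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  n <- t$tp + t$fp + t$fn + t$tn
  if (n <= 0) stop("empty table")
  ratio <- function(num, den) if (den > 0) num / den else NaN
  sens <- ratio(t$tp, t$tp + t$fn)
  spec <- ratio(t$tn, t$tn + t$fp)
  ppr <- ratio(t$tp, t$tp + t$fp)
  npr <- ratio(t$tn, t$tn + t$fn)
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  kap <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  j <- sens + spec - 1
  cells <- c(t$tp, t$fp, t$fn, t$tn)
  dor <- if (any(cells == 0)) {
    h <- cells + 0.5
    (h[1] * h[4]) / (h[2] * h[3])
  } else {
    (t$tp * t$tn) / (t$fp * t$fn)
  }
  und <- c("ppr", "npr", "sensitivity", "specificity")[is.nan(c(ppr, npr, sens, spec))]
  structure(list(sensitivity = 100 * sens, specificity = 100 * spec,
                 ppr = 100 * ppr, npr = 100 * npr, kappa = kap,
                 youden = j, dor = dor, undefined = und),
            class = "efficacy_indices")
}

#' @export
print.efficacy_indices <- function(x, ...) {
  cat(sprintf("sens %.1f%%  spec %.1f%%  PPR %.1f%%  NPR %.1f%%  kappa %.2f  J %.2f  DOR %.2f\n",
              x$sensitivity, x$specificity, x$ppr, x$npr, x$kappa, x$youden, x$dor))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Trapezoidal area over all distinct score thresholds; identical (to
#' numerical precision) to the rank statistic \eqn{P(S_+ > S_-) +
#' \frac12 P(S_+ = S_-)}.
#'
#' @param scores per-person scores (higher = more severe).
#' @param reference per-person binary reference.
#' @return list with \code{auc} and \code{points} (data frame of
#'   \code{threshold}, \code{fpr}, \code{tpr}).
#' @export
roc_auc <- function(scores, reference) {
  if (length(scores) != length(reference)) stop("unequal lengths")
  if (!all(reference %in% c(0, 1))) stop("reference must be binary 0/1")
  npos <- sum(reference == 1)
  nneg <- sum(reference == 0)
  if (npos == 0L || nneg == 0L) stop("both reference classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(scores >= c & reference == 1) / npos, 0)
  fpr <- vapply(thr, function(c) sum(scores >= c & reference == 0) / nneg, 0)
  fpr_all <- c(0, fpr, 1)
  tpr_all <- c(0, tpr, 1)
  auc <- sum(diff(fpr_all) * (utils::head(tpr_all, -1) + utils::tail(tpr_all, -1)) / 2)
  list(auc = auc, points = data.frame(threshold = c(Inf, thr, -Inf),
                                      fpr = fpr_all, tpr = tpr_all))
}

#' Scan integer cutoffs against the reference
#'
#' Builds one [confusion_table()] + [efficacy_indices()] row per integer
#' cutoff. Sensitivity is non-increasing and specificity non-decreasing
#' along the scan by construction.
#'
#' @param scores per-person integer scores.
#' @param reference per-person binary reference.
#' @param range integer vector (or length-2 bounds) of cutoffs to scan.
#' @return object of class \code{"cutoff_scan"}: data frame-backed list;
#'   see [select_optimal_cutoff()].
#' @export
scan_cutoffs <- function(scores, reference, range) {
  cutoffs <- if (length(range) == 2L) seq(range[1], range[2]) else as.integer(range)
  if (length(cutoffs) == 0L) stop("empty cutoff range")
  cutoffs <- sort(unique(as.integer(cutoffs)))
  tables <- lapply(cutoffs, function(c) confusion_table(scores, reference, c))
  scan_from_tables(cutoffs, tables)
}

#' Assemble a cutoff scan from precomputed 2x2 tables
#'
#' @param cutoffs strictly increasing integer cutoffs.
#' @param tables list of matching \code{"confusion_table"} objects.
#' @return a \code{"cutoff_scan"}.
#' @export
scan_from_tables <- function(cutoffs, tables) {
  stopifnot(length(cutoffs) == length(tables), !is.unsorted(cutoffs, strictly = TRUE))
  idx <- lapply(tables, efficacy_indices)
  rows <- data.frame(
    cutoff = as.integer(cutoffs),
    tp = vapply(tables, `[[`, 0L, "tp"), fp = vapply(tables, `[[`, 0L, "fp"),
    fn = vapply(tables, `[[`, 0L, "fn"), tn = vapply(tables, `[[`, 0L, "tn"),
    sensitivity = vapply(idx, `[[`, 0, "sensitivity"),
    specificity = vapply(idx, `[[`, 0, "specificity"),
    ppr = vapply(idx, `[[`, 0, "ppr"), npr = vapply(idx, `[[`, 0, "npr"),
    kappa = vapply(idx, `[[`, 0, "kappa"),
    youden = vapply(idx, `[[`, 0, "youden"),
    dor = vapply(idx, `[[`, 0, "dor"))
  structure(list(rows = rows, tables = tables), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, digits = NULL, ...) {
  r <- x$rows
  out <- data.frame(cutoff = r$cutoff,
                    sensitivity = round_half_up(r$sensitivity, 1),
                    specificity = round_half_up(r$specificity, 1),
                    ppr = round_half_up(r$ppr, 1), npr = round_half_up(r$npr, 1),
                    kappa = round_half_up(r$kappa, 2),
                    youden = round_half_up(r$youden, 2),
                    dor = round_half_up(r$dor, 2))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Plot a cutoff scan
#'
#' Sensitivity and specificity (percent) against the cutoff, with the
#' admissibility floor drawn.
#'
#' @param x a \code{"cutoff_scan"}.
#' @param min_sens,min_spec admissibility floor to draw (percent).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cutoff_scan <- function(x, min_sens = 75, min_spec = 75, ...) {
  r <- x$rows
  graphics::matplot(r$cutoff, cbind(r$sensitivity, r$specificity),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "cutoff (score >=)", ylab = "percent", ...)
  graphics::abline(h = c(min_sens, min_spec), lty = 3)
  graphics::legend("right", c("sensitivity", "specificity"), pch = c(1, 2), lty = 1,
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Select the optimal screening cutoff
#'
#' Three-step rule. Step 1 keeps cutoffs whose sensitivity and
#' specificity are both strictly above the floors. Step 2 keeps the rows
#' whose kappa, rounded half-up to 2 decimals, ties the maximum rounded
#' kappa. Step 3 breaks remaining ties by higher sensitivity, then
#' higher Youden's J, then higher DOR, then the lowest cutoff. Every
#' step is recorded in the audit trail.
#'
#' @param scan a \code{"cutoff_scan"}.
#' @param min_sens,min_spec admissibility floors in percent (default 75).
#' @return object of class \code{"cutoff_selection"}: list with
#'   \code{selected} (integer cutoff, or NA when no row is admissible),
#'   \code{candidates}, \code{kappa_max_set}, \code{audit} (character
#'   trail), \code{scan}.
#' @export
select_optimal_cutoff <- function(scan, min_sens = 75, min_spec = 75) {
  stopifnot(inherits(scan, "cutoff_scan"))
  r <- scan$rows
  if (nrow(r) == 0L) stop("empty scan")
  audit <- sprintf("scan: cutoffs %d-%d", min(r$cutoff), max(r$cutoff))
  adm <- r$sensitivity > min_sens & r$specificity > min_spec
  candidates <- r$cutoff[adm]
  audit <- c(audit, sprintf(
    "step 1 (sens > %g%% and spec > %g%%, strict): {%s}", min_sens, min_spec,
    paste(candidates, collapse = ", ")))
  if (!length(candidates)) {
    return(structure(list(selected = NA_integer_, candidates = integer(),
                          kappa_max_set = integer(),
                          audit = c(audit, "no admissible cutoff"), scan = scan),
                     class = "cutoff_selection"))
  }
  rc <- r[adm, , drop = FALSE]
  k2 <- round_half_up(rc$kappa, 2)
  kmax_set <- rc$cutoff[k2 == max(k2)]
  audit <- c(audit, sprintf(
    "step 2 (max kappa rounded to 2 dp = %.2f): {%s} (unrounded: %s)",
    max(k2), paste(kmax_set, collapse = ", "),
    paste(sprintf("%d:%.4f", rc$cutoff, rc$kappa), collapse = " ")))
  rk <- rc[k2 == max(k2), , drop = FALSE]
  ord <- order(-rk$sensitivity, -rk$youden, -rk$dor, rk$cutoff)
  sel <- rk$cutoff[ord[1]]
  audit <- c(audit, sprintf(
    "step 3 (higher sensitivity, then Youden, then DOR, then lowest cutoff): %d", sel))
  structure(list(selected = as.integer(sel), candidates = candidates,
                 kappa_max_set = kmax_set, audit = audit, scan = scan),
            class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  for (line in x$audit) cat(line, "\n")
  invisible(x)
}

#' Classify persons by a score cutoff
#'
#' @param scores per-person scores.
#' @param cutoff threshold; label 1 iff \code{score >= cutoff}.
#' @return integer 0/1 vector with attribute \code{"group_sizes"}.
#' @export
classify <- function(scores, cutoff) {
  lab <- as.integer(scores >= cutoff)
  structure(lab, group_sizes = c(positive = sum(lab), negative = sum(!lab)))
}

#' Reconstruct a 2x2 table from printed efficacy percentages
#'
#' Exhaustively searches all integer tables with the given reference
#' margins for the one whose sensitivity, specificity, PPR and NPR all
#' round (half-up, 1 decimal) to the printed values. Errors unless the
#' solution is unique -- i.e. the printed row pins down the counts
#' exactly.
#'
#' @param sensitivity,specificity,ppr,npr printed percentages (1 dp).
#' @param n_pos,n_neg reference-positive and reference-negative margins.
#' @return a \code{"confusion_table"}.
#' @export
reconstruct_counts <- function(sensitivity, specificity, ppr, npr,
                               n_pos, n_neg) {
  hits <- list()
  for (tp in 0:n_pos) {
    fn <- n_pos - tp
    s1 <- round_half_up(100 * tp / n_pos, 1)
    if (s1 != sensitivity) next
    for (tn in 0:n_neg) {
      fp <- n_neg - tn
      if (round_half_up(100 * tn / n_neg, 1) != specificity) next
      if (tp + fp == 0L || tn + fn == 0L) next
      if (round_half_up(100 * tp / (tp + fp), 1) != ppr) next
      if (round_half_up(100 * tn / (tn + fn), 1) != npr) next
      hits[[length(hits) + 1L]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    }
  }
  if (length(hits) == 0L) stop("no integer table matches the printed row")
  if (length(hits) > 1L) stop("printed row does not pin down the counts uniquely")
  h <- hits[[1L]]
  new_confusion(h["tp"], h["fp"], h["fn"], h["tn"])
}
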