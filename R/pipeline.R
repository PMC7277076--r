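# End-to-end orchestration: simulate (or load) -> polychoric -> CFA ->
# item reduction -> scoring -> reliability/validity -> cutoff scan ->
# selection -> report.

#' Read a survey CSV written by [write_igdc_csv()]
#'
#' Validates codes cell by cell: checklist items must be 0/1/2, the nine
#' reference criteria 0/1. Rows with missing checklist responses are
#' dropped listwise with a message.
#'
#' @param path CSV path with header \code{person_id, <items...>,
#'   dsm_1..dsm_9, ia, dep, freq, spend, device}.
#' @param items expected item labels (default: the 34-item blueprint).
#' @return list mirroring an \code{"igdc_data"} object (class included).
#' @export
read_responses <- function(path, items = unlist(cigdc_factor_map(), use.names = FALSE)) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  missing_cols <- setdiff(c(items, paste0("dsm_", 1:9)), names(df))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), c("person_id", items, paste0("dsm_", 1:9),
                                  "ia", "dep", "freq", "spend", "device"))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  X <- as.matrix(df[, items, drop = FALSE])
  bad <- which(!(is.na(X) | (X %in% 0:2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("out-of-range code %s at row %d, column %s",
                 X[bad[1, 1], bad[1, 2]], bad[1, 1], items[bad[1, 2]]))
  }
  drop <- rowSums(is.na(X)) > 0L
  if (any(drop)) {
    message(sum(drop), " row(s) with missing checklist items dropped (listwise)")
    df <- df[!drop, , drop = FALSE]
    X <- X[!drop, , drop = FALSE]
  }
  storage.mode(X) <- "integer"
  D <- as.matrix(df[, paste0("dsm_", 1:9), drop = FALSE])
  badd <- which(matrix(!(D %in% 0:1), nrow(D)), arr.ind = TRUE)
  if (nrow(badd)) {
    stop(sprintf("out-of-range reference code at row %d, column dsm_%d",
                 badd[1, 1], badd[1, 2]))
  }
  storage.mode(D) <- "integer"
  structure(list(responses = X, dsm_items = D,
                 ia_score = df$ia, depression_score = df$dep,
                 gameplay_frequency = df$freq, expenditure_band = df$spend,
                 device = if (is.null(df$device)) NULL else factor(df$device),
                 config = NULL),
            class = "igdc_data")
}

#' Run the full validation pipeline
#'
#' Stages: polychoric estimation and second-order + one-factor CFA on
#' the full item set; top-\code{k} item reduction; reduced-scale CFA;
#' sum scoring; reliability (alpha per scale and subscale, KR-20 for the
#' reference); criterion validity correlations; ROC/AUC against the
#' reference; integer cutoff scan and optimal-cutoff selection; group
#' contrasts at the selected cutoff. Deterministic given the dataset.
#'
#' @param data an \code{"igdc_data"} object (from [generate_dataset()] or
#'   [read_responses()]).
#' @param factor_map subconstruct blueprint (default: the 34-item one).
#' @param estimator CFA estimator, \code{"dwls"} or \code{"uls"}.
#' @param k items retained per subconstruct (default 3).
#' @param scan_range integer cutoffs to scan (default 1 below to 1 above
#'   the admissible sum-score range intersected with observed scores).
#' @param min_sens,min_spec admissibility floors in percent.
#' @return object of class \code{"igdc_report"}.
#' @export
run_validation <- function(data, factor_map = cigdc_factor_map(),
                           estimator = c("dwls", "uls"), k = 3L,
                           scan_range = NULL, min_sens = 75, min_spec = 75) {
  stopifnot(inherits(data, "igdc_data"))
  estimator <- match.arg(estimator)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  warnings_log <- character()
  withCallingHandlers({
    pc <- stage("polychoric", polychoric_matrix(data$responses))
    spec_full <- igdc_model(factor_map)
    fit_full <- stage("cfa", fit_model(pc, spec_full, estimator))
    fit_one <- stage("cfa", fit_model(pc, igdc_model(factor_map, "one_factor"),
                                      estimator))
    scale27 <- stage("reduce", select_top_items(fit_full, k = k))
    pc_red <- stage("polychoric",
                    polychoric_matrix(data$responses[, scale27$items, drop = FALSE]))
    fit_red <- stage("cfa", fit_model(pc_red, igdc_model(scale27$factor_map),
                                      estimator))
    scores <- stage("score", sum_score(data$responses, scale27))
    ref <- as.integer(rowSums(data$dsm_items) >= 5L)

    alpha_total <- stage("reliability", cronbach_alpha(data$responses[, scale27$items]))
    alpha_sub <- vapply(scale27$factor_map, function(it) {
      cronbach_alpha(data$responses[, it, drop = FALSE])
    }, 0)
    kr <- stage("reliability", kr20(data$dsm_items))

    sub_scores <- vapply(scale27$factor_map, function(it) {
      rowSums(data$responses[, it, drop = FALSE])
    }, numeric(nrow(data$responses)))
    validity <- stage("validity", data.frame(
      criterion = c("internet_addiction", "gameplay_frequency", "depression"),
      r = c(pearson_r(scores, data$ia_score),
            pearson_r(scores, data$gameplay_frequency),
            pearson_r(scores, data$depression_score))))

    roc <- stage("screen", roc_auc(scores, ref))
    if (is.null(scan_range)) {
      scan_range <- max(min(scores), 1L):max(scores)
    }
    scan <- stage("screen", scan_cutoffs(scores, ref, scan_range))
    sel <- stage("screen", select_optimal_cutoff(scan, min_sens, min_spec))

    contrasts <- NULL
    if (!is.na(sel$selected)) {
      grp <- classify(scores, sel$selected)
      contrasts <- stage("contrast", list(
        ia = two_sample_t(data$ia_score[grp == 1], data$ia_score[grp == 0]),
        depression = two_sample_t(data$depression_score[grp == 1],
                                  data$depression_score[grp == 0]),
        dsm = two_sample_t(rowSums(data$dsm_items)[grp == 1],
                           rowSums(data$dsm_items)[grp == 0]),
        frequency_u = mann_whitney_u(data$gameplay_frequency[grp == 1],
                                     data$gameplay_frequency[grp == 0]),
        expenditure_u = mann_whitney_u(data$expenditure_band[grp == 1],
                                       data$expenditure_band[grp == 0]),
        device_chisq = if (!is.null(data$device)) {
          chi_square_independence(table(grp, data$device))
        }))
    }
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  structure(list(
    polychoric = pc, fit_full = fit_full, fit_one_factor = fit_one,
    fit_reduced = fit_red, scale = scale27, scores = scores, reference = ref,
    reliability = list(alpha_total = alpha_total, alpha_subscales = alpha_sub,
                       kr20_reference = kr),
    validity = validity, auc = roc$auc, roc = roc, scan = scan,
    selection = sel, contrasts = contrasts, estimator = estimator,
    warnings = warnings_log),
    class = "igdc_report")
}

#' @export
print.igdc_report <- function(x, ...) {
  cat("== Scale validation report ==\n")
  cat("Items:", length(x$scale$items), "retained of",
      length(unlist(x$fit_full$spec$factor_map)), "\n")
  cat("Second-order model: ")
  print(fit_indices(x$fit_full))
  cat("One-factor model:   ")
  print(fit_indices(x$fit_one_factor))
  cat(sprintf("Reduced scale alpha = %.2f (subscales %.2f-%.2f); reference KR-20 = %.2f\n",
              x$reliability$alpha_total, min(x$reliability$alpha_subscales),
              max(x$reliability$alpha_subscales), x$reliability$kr20_reference))
  cat(sprintf("Criterion correlations: %s\n",
              paste(sprintf("%s %.2f", x$validity$criterion, x$validity$r),
                    collapse = ", ")))
  cat(sprintf("AUC vs reference = %.2f\n", x$auc))
  if (is.na(x$selection$selected)) {
    cat("No admissible cutoff under the sensitivity/specificity floors\n")
  } else {
    cat(sprintf("Selected cutoff: >= %d (screen-positive %.1f%%)\n",
                x$selection$selected,
                100 * mean(x$scores >= x$selection$selected)))
  }
  if (length(x$warnings)) {
    cat("Warnings during the run:\n")
    for (w in unique(x$warnings)) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Emits \code{loadings.csv} (item, factor, loading, second-order
#' loading, R-squared), \code{scan.csv} (the cutoff table),
#' \code{selection.json} (audit trail), and \code{report.json} (all
#' headline numbers).
#'
#' @param report an \code{"igdc_report"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "igdc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- report$fit_full
  fac <- rep(names(fit$spec$factor_map), lengths(fit$spec$factor_map))
  loadings <- data.frame(item = names(fit$lambda), factor = fac,
                         loading = round_half_up(unname(fit$lambda), 4),
                         second_order = round_half_up(unname(fit$gamma[fac]), 4),
                         r_squared = round_half_up(unname(fit$gamma[fac])^2, 4),
                         retained = names(fit$lambda) %in% report$scale$items)
  utils::write.csv(loadings, file.path(dir, "loadings.csv"), row.names = FALSE)
  r <- report$scan$rows
  scan_out <- data.frame(cutoff = r$cutoff,
                         sensitivity = round_half_up(r$sensitivity, 1),
                         specificity = round_half_up(r$specificity, 1),
                         ppr = round_half_up(r$ppr, 1),
                         npr = round_half_up(r$npr, 1),
                         kappa = round_half_up(r$kappa, 2),
                         youden = round_half_up(r$youden, 2),
                         dor = round_half_up(r$dor, 2))
  utils::write.csv(scan_out, file.path(dir, "scan.csv"), row.names = FALSE)
  jsonlite::write_json(list(selected = report$selection$selected,
                            candidates = report$selection$candidates,
                            kappa_max_set = report$selection$kappa_max_set,
                            audit = report$selection$audit),
                       file.path(dir, "selection.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  fi <- fit_indices(report$fit_full)
  jsonlite::write_json(list(
    n = fit$n, estimator = report$estimator,
    items_retained = length(report$scale$items),
    fit = list(chi_square = fi$chi_square, df = fi$df, cfi = fi$cfi,
               tli = fi$tli, rmsea = fi$rmsea, srmr = fi$srmr),
    reliability = report$reliability,
    validity = stats::setNames(as.list(report$validity$r), report$validity$criterion),
    auc = report$auc, selected_cutoff = report$selection$selected,
    warnings = report$warnings),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
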