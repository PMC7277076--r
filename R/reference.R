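# Published reference values for the C-IGDC validation study (N = 464):
# the 34-item standardized loading pattern of the second-order model and
# the printed cutoff-scan statistics. These are inputs to the package --
# the loading column drives both the item-reduction rule and the default
# simulation config; the scan statistics let the 2x2 tables behind them
# be reconstructed exactly.

#' Subconstruct blueprint of the 34-item C-IGDC
#'
#' The nine DSM-5-aligned first-order subconstructs (preoccupation,
#' withdrawal, tolerance, unsuccessful control, loss of interests,
#' continued gaming, deception, escape/relief, problems) and the items
#' assigned to each.
#'
#' @return named list mapping factor labels F1..F9 to item label vectors.
#' @export
cigdc_factor_map <- function() {
  list(
    F1 = paste0("F1_", 1:4),
    F2 = paste0("F2_", 1:4),
    F3 = paste0("F3_", 1:3),
    F4 = paste0("F4_", 1:4),
    F5 = paste0("F5_", 1:4),
    F6 = paste0("F6_", 1:4),
    F7 = paste0("F7_", 1:3),
    F8 = paste0("F8_", 1:3),
    F9 = paste0("F9_", 1:5)
  )
}

#' Published standardized loadings of the 34-item C-IGDC
#'
#' First-order item loadings (\code{lambda}) and second-order
#' subconstruct loadings (\code{gamma}) of the validated second-order
#' model, as reported for the development sample.
#'
#' @return list with named numeric vectors \code{lambda} (34 items) and
#'   \code{gamma} (9 subconstructs).
#' @export
cigdc_loadings <- function() {
  lambda <- c(
    F1_1 = 0.88, F1_2 = 0.83, F1_3 = 0.82, F1_4 = 0.81,
    F2_1 = 0.75, F2_2 = 0.80, F2_3 = 0.62, F2_4 = 0.90,
    F3_1 = 0.83, F3_2 = 0.86, F3_3 = 0.65,
    F4_1 = 0.78, F4_2 = 0.73, F4_3 = 0.68, F4_4 = 0.73,
    F5_1 = 0.83, F5_2 = 0.83, F5_3 = 0.73, F5_4 = 0.76,
    F6_1 = 0.76, F6_2 = 0.62, F6_3 = 0.79, F6_4 = 0.74,
    F7_1 = 0.80, F7_2 = 0.95, F7_3 = 0.79,
    F8_1 = 0.81, F8_2 = 0.93, F8_3 = 0.89,
    F9_1 = 0.73, F9_2 = 0.76, F9_3 = 0.77, F9_4 = 0.90, F9_5 = 0.71)
  gamma <- c(F1 = 0.75, F2 = 0.90, F3 = 0.91, F4 = 0.93, F5 = 0.86,
             F6 = 0.84, F7 = 0.71, F8 = 0.67, F9 = 0.84)
  list(lambda = lambda, gamma = gamma)
}

#' Published cutoff-scan statistics of the C-IGDC
#'
#' Screening efficacy indices of the sum score against the DSM-5
#' reference (9 binary criteria, positive at >= 5) for integer cutoffs
#' 16 to 22, as printed for the development sample: 60 reference
#' positives and 404 reference negatives. Percentages are rounded to one
#' decimal, kappa and Youden's J to two.
#'
#' @return data frame with columns \code{cutoff}, \code{sensitivity},
#'   \code{specificity}, \code{ppr}, \code{npr}, \code{kappa},
#'   \code{youden}, \code{dor}.
#' @export
cigdc_cutoff_reference <- function() {
  data.frame(
    cutoff = 16:22,
    sensitivity = c(91.7, 90.0, 90.0, 86.7, 81.7, 76.7, 68.3),
    specificity = c(73.0, 78.5, 80.4, 82.7, 85.4, 87.1, 90.3),
    ppr = c(33.5, 38.3, 40.6, 42.6, 45.4, 46.9, 51.3),
    npr = c(98.3, 98.1, 98.2, 97.7, 96.9, 96.2, 95.1),
    kappa = c(0.37, 0.43, 0.46, 0.48, 0.50, 0.50, 0.51),
    youden = c(0.65, 0.69, 0.70, 0.69, 0.67, 0.64, 0.59),
    dor = c(30.91, 32.15, 38.33, 31.25, 26.62, 22.07, 20.23)
  )
}
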