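# Synthetic survey generator. Emulates the development sample: N past-year
# gamers answering the 34 ordinal checklist items (second-order factor
# structure), the 9 binary DSM-5 criteria, and the criterion measures
# (internet-addiction score, depression score, weekly gameplay frequency,
# monthly expenditure band, preferred device).

# Calibration constants, fixed once from a large quadrature/simulation run
# (see the methods vignette). They map the published sum-score criterion
# correlations and the DSM-5 prevalence/reliability onto generator-level
# latent parameters.
.cal <- list(
  dsm_loading = 0.6461,   # per-criterion discrimination; implies KR-20 = 0.74
  dsm_threshold = 0.8111, # common criterion cutpoint; P(sum >= 5) = 0.129
  sum_g_cor = 0.9392,     # cor(27-item sum, G) under the default config
  ord4_atten = 0.8277     # ordinalization loss for the 4-band frequency
)

#' Generator configuration
#'
#' Bundles every parameter of the data-generating model: the item ->
#' subconstruct blueprint, first-order loadings \code{lambda},
#' second-order loadings \code{gamma}, per-item threshold pairs
#' partitioning the standard-normal latent response into codes 0/1/2,
#' the binary-reference parameters, and the target product-moment
#' correlations of the reduced-scale sum score with the three criterion
#' measures. Defaults reproduce the development sample: the published
#' 34-item loading pattern, response thresholds (-0.25, 0.84) (right-skewed
#' symptom endorsement), a DSM-5 reference calibrated to 12.9 percent
#' prevalence at the >= 5 rule, and criterion correlations 0.45
#' (internet addiction), 0.40 (gameplay frequency), 0.28 (depression).
#'
#' @param n_persons sample size (default 464, the development sample).
#' @param seed integer root seed; all component substreams derive from it.
#' @param factor_map named list of item labels per subconstruct.
#' @param lambda named per-item first-order loadings in (0, 1).
#' @param gamma named per-factor second-order loadings in (0, 1).
#' @param thresholds per-item list of ordered cutpoint pairs, or a single
#'   pair recycled to all items.
#' @param dsm_loading per-criterion discriminations in (0, 1) (length 9,
#'   recycled).
#' @param dsm_threshold per-criterion latent cutpoints (length 9, recycled).
#' @param criterion_targets named numeric: desired correlations of the
#'   27-item sum with \code{ia}, \code{freq}, \code{dep}.
#' @return object of class \code{"igdc_config"}.
#' @export
igdc_config <- function(n_persons = 464L, seed = 1L,
                        factor_map = cigdc_factor_map(),
                        lambda = cigdc_loadings()$lambda,
                        gamma = cigdc_loadings()$gamma,
                        thresholds = c(-0.25, 0.84),
                        dsm_loading = .cal$dsm_loading,
                        dsm_threshold = .cal$dsm_threshold,
                        criterion_targets = c(ia = 0.45, freq = 0.40, dep = 0.28)) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons <= 0L) stop("n_persons must be positive")
  items <- unlist(factor_map, use.names = FALSE)
  if (anyDuplicated(items)) stop("an item appears in more than one subconstruct")
  if (any(lengths(factor_map) < 3L)) stop("every subconstruct needs >= 3 items")
  if (!setequal(names(lambda), items)) {
    stop("lambda must name exactly the items in factor_map")
  }
  if (!setequal(names(gamma), names(factor_map))) {
    stop("gamma must name exactly the subconstructs in factor_map")
  }
  lambda <- lambda[items]
  gamma <- gamma[names(factor_map)]
  if (any(lambda <= 0 | lambda >= 1)) stop("lambda must lie strictly in (0, 1)")
  if (any(gamma <= 0 | gamma >= 1)) stop("gamma must lie strictly in (0, 1)")
  if (is.numeric(thresholds)) thresholds <- rep(list(thresholds), length(items))
  if (length(thresholds) != length(items)) stop("one threshold pair per item")
  names(thresholds) <- items
  bad <- vapply(thresholds, function(t) length(t) != 2L || t[1] >= t[2], logical(1))
  if (any(bad)) stop("thresholds must be ordered pairs tau1 < tau2")
  dsm_loading <- rep_len(dsm_loading, 9L)
  dsm_threshold <- rep_len(dsm_threshold, 9L)
  if (any(dsm_loading <= 0 | dsm_loading >= 1)) {
    stop("dsm_loading must lie strictly in (0, 1)")
  }
  if (any(abs(criterion_targets) >= 1)) stop("criterion targets must be in (-1, 1)")
  ct <- criterion_targets[c("ia", "freq", "dep")]
  if (anyNA(ct)) stop("criterion_targets must name ia, freq, dep")
  structure(list(n_persons = n_persons, seed = as.integer(seed),
                 factor_map = factor_map, lambda = lambda, gamma = gamma,
                 thresholds = thresholds, dsm_loading = dsm_loading,
                 dsm_threshold = dsm_threshold, criterion_targets = ct),
            class = "igdc_config")
}

# One root seed spawns a fixed set of component substreams, so each data
# component is reproducible on its own and insensitive to the others.
.substreams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("latent", "items", "dsm", "ia", "dep", "freq", "spend", "device")
  s
}

#' Draw second-order latent factor scores
#'
#' Column \code{G} is the standard-normal general factor; each
#' first-order factor is \eqn{F_j = \gamma_j G + d_j} with disturbance
#' variance \eqn{1 - \gamma_j^2}, so every factor is marginally standard
#' normal.
#'
#' @param config an [igdc_config()].
#' @return \code{n_persons} x (1 + 9) matrix with columns \code{G},
#'   \code{F1}, ..., \code{F9}.
#' @export
generate_latent <- function(config) {
  stopifnot(inherits(config, "igdc_config"))
  set.seed(.substreams(config$seed)[["latent"]])
  n <- config$n_persons
  g <- stats::rnorm(n)
  gam <- config$gamma
  F <- sweep(matrix(stats::rnorm(n * length(gam)), n), 2,
             sqrt(1 - gam^2), `*`) + outer(g, gam)
  out <- cbind(G = g, F)
  colnames(out) <- c("G", names(gam))
  out
}

#' Generate ordinal item responses from latent factors
#'
#' Each item's latent response is \eqn{y^* = \lambda_i F_{j(i)} + e} with
#' residual variance \eqn{1 - \lambda_i^2}; codes are 0, 1, 2 as
#' \eqn{y^*} falls below \eqn{\tau_1}, between the cutpoints, or above
#' \eqn{\tau_2}.
#'
#' @param factors matrix from [generate_latent()].
#' @param config the matching [igdc_config()].
#' @return person x item integer matrix with codes in \{0, 1, 2\}.
#' @export
generate_item_responses <- function(factors, config) {
  stopifnot(inherits(config, "igdc_config"))
  items <- names(config$lambda)
  fac_of <- rep(names(config$factor_map), lengths(config$factor_map))
  if (!all(fac_of %in% colnames(factors))) stop("item mapped to a factor absent from `factors`")
  set.seed(.substreams(config$seed)[["items"]])
  n <- nrow(factors)
  lam <- config$lambda
  ystar <- sweep(factors[, fac_of, drop = FALSE], 2, lam, `*`) +
    sweep(matrix(stats::rnorm(n * length(items)), n), 2, sqrt(1 - lam^2), `*`)
  X <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  for (j in seq_along(items)) {
    t <- config$thresholds[[j]]
    X[, j] <- (ystar[, j] > t[1]) + (ystar[, j] > t[2])
  }
  X
}

#' Generate the diagnostic reference and criterion measures
#'
#' The 9 binary DSM-5-style criteria fire when
#' \eqn{a_k G + e > c_k} (residual variance \eqn{1 - a_k^2}). The
#' continuous criteria are affine transforms of \eqn{\rho G + e} clipped
#' to their scale ranges; the latent \eqn{\rho} values are back-computed
#' from \code{criterion_targets} through the frozen sum-score/G
#' correlation so the observable sum-score correlations land on target.
#' Gameplay frequency uses 4 ordinal bands (23.3 percent below one day a
#' week, 59.5 percent above three), expenditure 3 bands (67.7 percent
#' spend nothing, 11.4 percent over 100 MOP monthly), and device 4
#' categories (smartphone 59.3, computer 31.5, tablet 6.7, console 2.6
#' percent) independent of severity.
#'
#' @param factors matrix from [generate_latent()].
#' @param config the matching [igdc_config()].
#' @return list with \code{dsm_items} (person x 9 binary matrix),
#'   \code{ia_score}, \code{depression_score}, \code{gameplay_frequency}
#'   (1-4), \code{expenditure_band} (1-3), \code{device} (factor).
#' @export
generate_criteria <- function(factors, config) {
  stopifnot(inherits(config, "igdc_config"))
  ss <- .substreams(config$seed)
  g <- factors[, "G"]
  n <- length(g)
  tgt <- config$criterion_targets
  rho <- c(ia = unname(tgt["ia"]) / .cal$sum_g_cor,
           freq = unname(tgt["freq"]) / (.cal$sum_g_cor * .cal$ord4_atten),
           dep = unname(tgt["dep"]) / .cal$sum_g_cor)
  if (any(abs(rho) >= 1)) stop("criterion target too large for the latent model")
  mix <- function(r, key) {
    set.seed(ss[[key]])
    r * g + sqrt(1 - r^2) * stats::rnorm(n)
  }
  set.seed(ss[["dsm"]])
  a <- config$dsm_loading
  lat <- sweep(matrix(stats::rnorm(n * 9L), n), 2, sqrt(1 - a^2), `*`) +
    outer(g, a)
  dsm <- matrix(0L, n, 9L, dimnames = list(NULL, paste0("dsm_", 1:9)))
  dsm[sweep(lat, 2, config$dsm_threshold, `>`)] <- 1L
  ia <- pmin(pmax(45 + 12 * mix(rho[["ia"]], "ia"), 20), 100)
  dep <- pmin(pmax(9.5 + 5.5 * mix(rho[["dep"]], "dep"), 0), 30)
  freq_cuts <- stats::qnorm(c(0.233, 0.319, 0.405))
  zf <- mix(rho[["freq"]], "freq")
  freq <- 1L + (zf > freq_cuts[1]) + (zf > freq_cuts[2]) + (zf > freq_cuts[3])
  spend_cuts <- stats::qnorm(c(0.677, 0.886))
  zs <- mix(0.30, "spend")
  spend <- 1L + (zs > spend_cuts[1]) + (zs > spend_cuts[2])
  set.seed(ss[["device"]])
  device <- factor(sample(c("smartphone", "computer", "tablet", "console"),
                          n, replace = TRUE,
                          prob = c(0.593, 0.315, 0.067, 0.026)),
                   levels = c("smartphone", "computer", "tablet", "console"))
  list(dsm_items = dsm, ia_score = ia, depression_score = dep,
       gameplay_frequency = as.integer(freq),
       expenditure_band = as.integer(spend), device = device)
}

#' Generate a complete synthetic survey dataset
#'
#' Composes [generate_latent()], [generate_item_responses()] and
#' [generate_criteria()] into one deterministic dataset.
#'
#' @param config an [igdc_config()].
#' @return object of class \code{"igdc_data"}: list with \code{responses}
#'   (person x 34 integer matrix), \code{dsm_items}, the criterion
#'   vectors, and \code{config} (the generating truth).
#' @export
generate_dataset <- function(config = igdc_config()) {
  fac <- generate_latent(config)
  resp <- generate_item_responses(fac, config)
  crit <- generate_criteria(fac, config)
  structure(c(list(responses = resp), crit, list(config = config)),
            class = "igdc_data")
}

#' @export
print.igdc_data <- function(x, ...) {
  cat("Synthetic gamer survey: n =", nrow(x$responses), "persons,",
      ncol(x$responses), "checklist items\n")
  cat("DSM-5 reference positives (>= 5 criteria):",
      sum(rowSums(x$dsm_items) >= 5), "\n")
  invisible(x)
}

#' @export
as.data.frame.igdc_data <- function(x, ...) {
  data.frame(person_id = seq_len(nrow(x$responses)), x$responses,
             x$dsm_items, ia = x$ia_score, dep = x$depression_score,
             freq = x$gameplay_frequency, spend = x$expenditure_band,
             device = x$device, check.names = FALSE)
}

#' Write a synthetic dataset as CSV
#'
#' One UTF-8 CSV with header \code{person_id, F1_1..F9_5, dsm_1..dsm_9,
#' ia, dep, freq, spend, device}.
#'
#' @param x an \code{igdc_data} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_igdc_csv <- function(x, path) {
  stopifnot(inherits(x, "igdc_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
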