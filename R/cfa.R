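# Second-order ordinal CFA on a polychoric correlation matrix.
#
# The measurement model: items load on nine first-order subconstructs
# (loadings lambda), which load on one general factor (loadings gamma);
# all factors standardized. Implied correlation:
#   Sigma = Lambda Phi Lambda' + Theta,  Phi = gamma gamma' + diag(1-gamma^2),
#   Theta = diag(1 - lambda^2)
# so a same-factor pair is lambda_i*lambda_k and a cross-factor pair is
# lambda_i*lambda_k*gamma_j*gamma_l. Estimation minimizes the (diagonally)
# weighted least-squares discrepancy on the lower triangle; the chi-square
# is the naive (n-1)*F_min without a mean-and-variance adjustment, which
# keeps model ordering and parameter recovery meaningful but is not
# bit-compatible with full WLSMV software.

#' Model specification for the ordinal CFA
#'
#' @param factor_map named list of item labels per first-order factor.
#' @param model \code{"second_order"} (items -> factors -> one general
#'   factor), \code{"one_factor"} (all items on a single factor), or
#'   \code{"independence"} (no free parameters; the null baseline).
#' @return object of class \code{"igdc_model"}.
#' @export
igdc_model <- function(factor_map, model = c("second_order", "one_factor",
                                             "independence")) {
  model <- match.arg(model)
  items <- unlist(factor_map, use.names = FALSE)
  if (anyDuplicated(items)) stop("factor_map must partition the item set")
  if (model == "second_order" && any(lengths(factor_map) < 3L)) {
    stop("identification requires >= 3 items per factor")
  }
  structure(list(factor_map = factor_map, items = items, model = model),
            class = "igdc_model")
}

#' Model-implied item correlation matrix
#'
#' @param lambda named per-item loadings.
#' @param gamma named per-factor second-order loadings (ignored for the
#'   one-factor model).
#' @param spec an [igdc_model()].
#' @return item x item correlation matrix with unit diagonal.
#' @export
implied_correlation <- function(lambda, gamma, spec) {
  items <- spec$items
  lambda <- lambda[items]
  if (spec$model == "independence") {
    return(diag(1, length(items), length(items)))
  }
  if (spec$model == "one_factor") {
    S <- outer(lambda, lambda)
  } else {
    fac <- rep(names(spec$factor_map), lengths(spec$factor_map))
    g <- gamma[fac]
    u <- lambda * g
    S <- outer(u, u)
    same <- outer(fac, fac, "==")
    LL <- outer(lambda, lambda)
    S[same] <- LL[same]
  }
  diag(S) <- 1
  dimnames(S) <- list(items, items)
  S
}

# pack/unpack free parameters
.par_vec <- function(lambda, gamma, spec) {
  if (spec$model == "second_order") c(lambda, gamma) else lambda
}

.par_split <- function(theta, spec) {
  p <- length(spec$items)
  lambda <- stats::setNames(theta[seq_len(p)], spec$items)
  gamma <- if (spec$model == "second_order") {
    stats::setNames(theta[p + seq_along(spec$factor_map)], names(spec$factor_map))
  } else NULL
  list(lambda = lambda, gamma = gamma)
}

#' Fit an ordinal CFA by (weighted) least squares
#'
#' Minimizes \eqn{F(\theta) = \sum_{i>k} w_{ik} (s_{ik} -
#' \sigma_{ik}(\theta))^2} over the strict lower triangle. Under
#' \code{estimator = "dwls"} the weights are the inverse unit-information
#' asymptotic variances of the polychoric estimates carried by the
#' \code{polycor} object; \code{"uls"} sets every weight to 1. A
#' non-positive-semidefinite input matrix is repaired by clipping
#' eigenvalues at 1e-6 (warning).
#'
#' @param s a \code{"polycor"} object from [polychoric_matrix()], or a
#'   plain correlation matrix (then \code{n} must be given and weights
#'   default to 1).
#' @param spec an [igdc_model()].
#' @param estimator \code{"dwls"} (default) or \code{"uls"}.
#' @param n sample size when \code{s} is a plain matrix.
#' @param start starting value for all loadings (default 0.7).
#' @return object of class \code{"igdc_cfa"}: estimates, minimized
#'   discrepancy, convergence flag, fit indices (see [fit_indices()]).
#' @export
fit_model <- function(s, spec, estimator = c("dwls", "uls"), n = NULL,
                      start = 0.7) {
  estimator <- match.arg(estimator)
  if (inherits(s, "polycor")) {
    W <- s$weights
    n <- s$n
    S <- s$rho
  } else {
    S <- as.matrix(s)
    W <- NULL
    if (is.null(n)) stop("n must be supplied with a plain correlation matrix")
  }
  items <- spec$items
  if (!all(items %in% colnames(S))) stop("model names items absent from s")
  S <- S[items, items]
  S <- .repair_psd(S)
  Wm <- if (estimator == "dwls" && !is.null(W)) {
    Wi <- W[items, items]
    diag(Wi) <- 0
    Wi
  } else {
    matrix(1, length(items), length(items))
  }
  lt <- lower.tri(S)
  w <- Wm[lt]
  sv <- S[lt]

  if (spec$model == "independence") {
    fmin <- sum(w * sv^2)
    fit <- structure(list(lambda = NULL, gamma = NULL, spec = spec,
                          discrepancy = fmin, converged = TRUE,
                          n_iterations = 0L, n = n, s = S, weights = Wm,
                          estimator = estimator, heywood = FALSE,
                          df = .model_df(spec)),
                     class = "igdc_cfa")
    return(fit)
  }

  objective <- function(theta) {
    pr <- .par_split(theta, spec)
    sig <- implied_correlation(pr$lambda, pr$gamma, spec)
    sum(w * (sv - sig[lt])^2)
  }
  npar <- length(items) + if (spec$model == "second_order") length(spec$factor_map) else 0L
  theta0 <- rep(start, npar)
  opt <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      lower = -0.999, upper = 0.999,
                      control = list(maxit = 500L, factr = 1e4, pgtol = 1e-8))
  pr <- .par_split(opt$par, spec)
  converged <- opt$convergence == 0L
  heywood <- any(abs(opt$par) >= 0.998)
  if (heywood) warning("loading at the admissibility bound (Heywood-adjacent)")
  if (!converged) warning("CFA did not converge; fit indices withheld")
  structure(list(lambda = pr$lambda, gamma = pr$gamma, spec = spec,
                 discrepancy = opt$value, converged = converged,
                 n_iterations = opt$counts[["function"]], n = n, s = S,
                 weights = Wm, estimator = estimator, heywood = heywood,
                 df = .model_df(spec)),
            class = "igdc_cfa")
}

.model_df <- function(spec) {
  p <- length(spec$items)
  npar <- switch(spec$model,
                 independence = 0L,
                 one_factor = p,
                 second_order = p + length(spec$factor_map))
  as.integer(p * (p - 1) / 2 - npar)
}

.repair_psd <- function(S, tol = 1e-6) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) >= tol) return(S)
  warning("correlation matrix not positive definite; eigenvalues clipped")
  V <- ev$vectors
  S2 <- V %*% diag(pmax(ev$values, tol)) %*% t(V)
  d <- sqrt(diag(S2))
  S2 <- S2 / outer(d, d)
  dimnames(S2) <- dimnames(S)
  S2
}

#' Fit the zero-correlation baseline model
#'
#' The independence model (all off-diagonal correlations zero) needed by
#' the incremental fit indices: \eqn{\chi^2_b = (n-1) \sum w s^2},
#' \eqn{df_b = p(p-1)/2}.
#'
#' @inheritParams fit_model
#' @return an \code{"igdc_cfa"} object.
#' @export
fit_independence_baseline <- function(s, spec, estimator = c("dwls", "uls"),
                                      n = NULL) {
  base_spec <- igdc_model(spec$factor_map, model = "independence")
  fit_model(s, base_spec, estimator = match.arg(estimator), n = n)
}

#' Fit indices for an ordinal CFA
#'
#' Computes \eqn{\chi^2 = (n-1) F_{min}}, CFI, TLI, RMSEA (point and 90
#' percent interval by noncentral chi-square inversion) and SRMR (root
#' mean square correlation residual over the strict lower triangle).
#' CFI is floored through \eqn{\max(\cdot, 0)} protection so a baseline
#' no better than the model yields CFI = 0.
#'
#' @param object a converged \code{"igdc_cfa"}.
#' @param baseline the matching independence fit; computed on the spot
#'   when omitted.
#' @return object of class \code{"igdc_fit_indices"} (a list).
#' @export
fit_indices <- function(object, baseline = NULL) {
  stopifnot(inherits(object, "igdc_cfa"))
  if (!object$converged) stop("model did not converge; no fit indices")
  if (object$df <= 0L) stop("non-positive degrees of freedom")
  n <- object$n
  if (is.null(baseline)) {
    base_spec <- igdc_model(object$spec$factor_map, model = "independence")
    baseline <- structure(list(discrepancy = sum(object$weights[lower.tri(object$s)] *
                                                   object$s[lower.tri(object$s)]^2),
                               df = .model_df(base_spec), n = n),
                          class = "igdc_cfa")
  }
  chi_m <- (n - 1) * object$discrepancy
  chi_b <- (n - 1) * baseline$discrepancy
  df_m <- object$df
  df_b <- baseline$df
  num <- max(chi_m - df_m, 0)
  cfi <- 1 - num / max(chi_b - df_b, chi_m - df_m, 0)
  if (!is.finite(cfi)) cfi <- 1   # 0/0: saturated baseline and model
  tli <- ((chi_b / df_b) - (chi_m / df_m)) / ((chi_b / df_b) - 1)
  rmsea <- sqrt(num / (df_m * (n - 1)))
  sig <- if (object$spec$model == "independence") {
    diag(1, nrow(object$s))
  } else {
    implied_correlation(object$lambda, object$gamma, object$spec)
  }
  res <- (object$s - sig)[lower.tri(object$s)]
  srmr <- sqrt(mean(res^2))
  ci <- .rmsea_ci(chi_m, df_m, n)
  structure(list(chi_square = chi_m, df = df_m, cfi = cfi, tli = tli,
                 rmsea = rmsea, rmsea_ci = ci, srmr = srmr,
                 discrepancy_min = object$discrepancy,
                 baseline_chi_square = chi_b, baseline_df = df_b, n = n),
            class = "igdc_fit_indices")
}

# 90% RMSEA interval by inverting the noncentral chi-square (best effort;
# degenerate cases return 0 bounds).
.rmsea_ci <- function(chi, df, n, level = 0.90) {
  lo_p <- (1 + level) / 2
  hi_p <- (1 - level) / 2
  bound <- function(p) {
    if (stats::pchisq(chi, df) < p) return(0)
    f <- function(ncp) stats::pchisq(chi, df, ncp) - p
    up <- max(chi * 2, df + 10)
    while (f(up) > 0 && up < 1e8) up <- up * 2
    ncp <- tryCatch(stats::uniroot(f, c(0, up))$root, error = function(e) 0)
    sqrt(ncp / (df * (n - 1)))
  }
  c(lower = bound(lo_p), upper = bound(hi_p))
}

#' @export
print.igdc_fit_indices <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, CFI = %.3f, TLI = %.3f\n",
              x$df, x$chi_square, x$cfi, x$tli))
  cat(sprintf("RMSEA = %.3f (90%% CI [%.3f, %.3f]), SRMR = %.3f\n",
              x$rmsea, x$rmsea_ci["lower"], x$rmsea_ci["upper"], x$srmr))
  invisible(x)
}

#' @export
print.igdc_cfa <- function(x, ...) {
  cat("Ordinal CFA (", x$spec$model, ", ", x$estimator, "): ",
      length(x$spec$items), " items, n = ", x$n, "\n", sep = "")
  cat(sprintf("Minimized discrepancy %.6g; df = %d; %s\n", x$discrepancy,
              x$df, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.igdc_cfa <- function(object, ...) {
  fi <- if (object$converged && object$df > 0L &&
            object$spec$model != "independence") fit_indices(object) else NULL
  structure(list(fit = object, indices = fi), class = "summary.igdc_cfa")
}

#' @export
print.summary.igdc_cfa <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$indices)) print(x$indices)
  if (!is.null(x$fit$gamma)) {
    cat("\nSecond-order loadings (R-squared in parentheses):\n")
    g <- x$fit$gamma
    for (f in names(g)) cat(sprintf("  %s: %.2f (%.2f)\n", f, g[f], g[f]^2))
  }
  if (!is.null(x$fit$lambda)) {
    cat("\nItem loadings:\n")
    print(round(x$fit$lambda, 3))
  }
  invisible(x)
}

#' @export
coef.igdc_cfa <- function(object, ...) {
  c(object$lambda, if (!is.null(object$gamma)) {
    stats::setNames(object$gamma, paste0("gamma_", names(object$gamma)))
  })
}

#' @export
fitted.igdc_cfa <- function(object, ...) {
  if (object$spec$model == "independence") return(diag(1, nrow(object$s)))
  implied_correlation(object$lambda, object$gamma, object$spec)
}

#' @export
residuals.igdc_cfa <- function(object, ...) {
  object$s - fitted(object)
}

#' Plot loadings of a fitted ordinal CFA
#'
#' Dot chart of standardized item loadings grouped by subconstruct, with
#' second-order loadings marked.
#'
#' @param x an \code{"igdc_cfa"}.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.igdc_cfa <- function(x, ...) {
  if (is.null(x$lambda)) stop("independence model has no loadings to plot")
  fac <- rep(names(x$spec$factor_map), lengths(x$spec$factor_map))
  graphics::dotchart(unname(x$lambda), labels = names(x$lambda),
                     groups = factor(fac, levels = names(x$spec$factor_map)),
                     xlab = "standardized loading", xlim = c(0, 1), ...)
  if (!is.null(x$gamma)) {
    graphics::mtext(sprintf("second-order loadings: %s",
                            paste(sprintf("%s %.2f", names(x$gamma), x$gamma),
                                  collapse = ", ")), side = 3, cex = 0.7)
  }
  invisible(x)
}

#' Simulate datasets from a fitted second-order model
#'
#' Uses the fitted loadings as the generating truth, with the default
#' response thresholds, to draw complete synthetic datasets.
#'
#' @param object a converged second-order \code{"igdc_cfa"}.
#' @param nsim number of datasets.
#' @param seed root seed for the first replicate; replicate r uses
#'   \code{seed + r - 1}.
#' @param n_persons rows per dataset (default: the fitting sample size).
#' @param ... unused.
#' @return list of \code{"igdc_data"} objects (a single object when
#'   \code{nsim = 1}).
#' @export
simulate.igdc_cfa <- function(object, nsim = 1, seed = 1L, n_persons = NULL, ...) {
  if (object$spec$model != "second_order") {
    stop("simulation requires the second-order model")
  }
  lam <- pmin(pmax(object$lambda, 0.01), 0.99)
  gam <- pmin(pmax(object$gamma, 0.01), 0.99)
  out <- lapply(seq_len(nsim), function(r) {
    generate_dataset(igdc_config(
      n_persons = if (is.null(n_persons)) object$n else n_persons,
      seed = as.integer(seed) + r - 1L,
      factor_map = object$spec$factor_map, lambda = lam, gamma = gam))
  })
  if (nsim == 1) out[[1]] else out
}
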