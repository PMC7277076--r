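# Polychoric correlation estimation: two-stage maximum likelihood.
# Stage 1 fixes thresholds from the univariate margins; stage 2 maximizes
# the bivariate-normal cell-probability likelihood over rho alone.

#' Estimate normal-theory thresholds for one ordinal item
#'
#' Cutpoints are the normal quantiles of the cumulative category
#' proportions: \eqn{\tau_c = \Phi^{-1}(P(X \le c))}. Categories that are
#' unobserved are collapsed into their nearest observed neighbour (the
#' preceding category when one exists, otherwise the following one), with
#' a warning, because an empty category contributes no threshold
#' information.
#'
#' @param x integer codes for one item (levels \code{0:(n_categories-1)}).
#' @param n_categories total number of response categories the item admits.
#' @param item label used in error messages.
#' @return numeric vector of strictly increasing cutpoints, with attribute
#'   \code{"collapsed"} (logical) and \code{"codes"} giving the collapsed
#'   recoding applied to \code{0:(n_categories-1)}.
#' @export
estimate_thresholds <- function(x, n_categories = 3L, item = "item") {
  x <- as.integer(x)
  if (anyNA(x)) stop("missing responses in ", item)
  if (any(x < 0L | x >= n_categories)) {
    stop("codes outside 0..", n_categories - 1L, " in ", item)
  }
  counts <- tabulate(x + 1L, nbins = n_categories)
  observed <- counts > 0L
  if (sum(observed) < 2L) {
    stop("item ", item, " is constant and cannot enter the model")
  }
  # collapse empty categories toward the nearest non-empty neighbour
  codes <- integer(n_categories)
  cur <- -1L
  for (c in seq_len(n_categories)) {
    if (observed[c]) cur <- cur + 1L
    codes[c] <- max(cur, 0L)
  }
  collapsed <- any(!observed)
  if (collapsed) {
    warning("empty categories collapsed for ", item, call. = FALSE)
  }
  kept <- counts[observed]
  cum <- cumsum(kept) / sum(kept)
  tau <- stats::qnorm(cum[-length(cum)])
  structure(tau, collapsed = collapsed, codes = codes)
}

# Rectangle probabilities for a bivariate normal over the grid defined by
# two augmented threshold vectors (-Inf, tau, Inf). Returns an r x c matrix.
.cell_probs <- function(tau_a, tau_b, rho) {
  a <- c(-Inf, tau_a, Inf)
  b <- c(-Inf, tau_b, Inf)
  r <- length(a) - 1L
  s <- length(b) - 1L
  grid <- matrix(pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho),
                 nrow = length(a))
  p <- grid[-1L, -1L, drop = FALSE] - grid[-nrow(grid), -1L, drop = FALSE] -
    grid[-1L, -ncol(grid), drop = FALSE] +
    grid[-nrow(grid), -ncol(grid), drop = FALSE]
  pmax(p, 0)
}

# Log-likelihood of a contingency table at rho, cells floored at 1e-12.
.polychor_loglik <- function(rho, tab, tau_a, tau_b) {
  p <- .cell_probs(tau_a, tau_b, rho)
  sum(tab * log(pmax(p, 1e-12)))
}

#' Polychoric correlation of one contingency table
#'
#' Maximizes the bivariate-normal cell log-likelihood over
#' \eqn{\rho \in [-0.999, 0.999]} with the thresholds held fixed
#' (two-stage estimation). The bound keeps near-deterministic tables away
#' from the singular \eqn{|\rho| = 1} boundary.
#'
#' @param tab contingency table of counts (rows: item a, cols: item b).
#' @param tau_a,tau_b threshold vectors from [estimate_thresholds()],
#'   lengths \code{nrow(tab) - 1} and \code{ncol(tab) - 1}.
#' @param se logical; also return the (fixed-threshold) asymptotic
#'   standard error from the Fisher information.
#' @return the estimate, with attribute \code{"se"} when requested.
#' @export
polychoric_pair <- function(tab, tau_a, tau_b, se = FALSE) {
  tab <- as.matrix(tab)
  if (sum(tab) <= 0) stop("contingency table has no observations")
  stopifnot(length(tau_a) == nrow(tab) - 1L, length(tau_b) == ncol(tab) - 1L)
  if (!all(is.finite(tau_a)) || !all(is.finite(tau_b))) {
    stop("non-finite thresholds")
  }
  opt <- stats::optimize(.polychor_loglik, interval = c(-0.999, 0.999),
                         tab = tab, tau_a = tau_a, tau_b = tau_b,
                         maximum = TRUE, tol = 1e-8)
  rho <- opt$maximum
  # optimize() never quite reaches the interval ends; snap when the
  # likelihood keeps increasing at the bound.
  for (bound in c(-0.999, 0.999)) {
    if (abs(rho - bound) < 1e-4 &&
        .polychor_loglik(bound, tab, tau_a, tau_b) >= opt$objective) {
      rho <- bound
    }
  }
  if (se) {
    attr(rho, "se") <- sqrt(1 / .polychor_info(rho, tau_a, tau_b, sum(tab)))
  }
  rho
}

# Fisher information for rho (thresholds fixed): n * sum (dpi/drho)^2 / pi.
# dPhi2/drho is the bivariate density (Plackett's identity), so the cell
# derivative is the four-corner density difference.
.polychor_info <- function(rho, tau_a, tau_b, n) {
  a <- c(-Inf, tau_a, Inf)
  b <- c(-Inf, tau_b, Inf)
  rho <- min(max(rho, -0.998), 0.998)
  dg <- matrix(dbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho),
               nrow = length(a))
  d <- dg[-1L, -1L, drop = FALSE] - dg[-nrow(dg), -1L, drop = FALSE] -
    dg[-1L, -ncol(dg), drop = FALSE] + dg[-nrow(dg), -ncol(dg), drop = FALSE]
  p <- pmax(.cell_probs(tau_a, tau_b, rho), 1e-12)
  n * sum(d^2 / p)
}

#' Polychoric correlation matrix of an ordinal item set
#'
#' Runs [estimate_thresholds()] per item and [polychoric_pair()] per item
#' pair. Also records, for each pair, the inverse asymptotic variance of
#' the estimate (unit-information scale), which the CFA module uses as
#' diagonal weights.
#'
#' @param responses person x item matrix or data frame of integer codes.
#' @param n_categories number of admissible categories per item.
#' @return an object of class \code{"polycor"}: list with \code{rho}
#'   (item x item correlation matrix), \code{thresholds} (named list),
#'   \code{weights} (item x item matrix of unit-information DWLS weights),
#'   \code{n} (persons) and \code{collapsed} (labels of items with merged
#'   categories).
#' @export
polychoric_matrix <- function(responses, n_categories = 3L) {
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 items")
  items <- colnames(X)
  if (is.null(items)) items <- paste0("V", seq_len(p))
  const <- vapply(seq_len(p), function(j) length(unique(X[, j])) < 2L, logical(1))
  if (any(const)) {
    stop("constant items cannot enter the model: ",
         paste(items[const], collapse = ", "))
  }
  thr <- vector("list", p)
  names(thr) <- items
  Xc <- X
  for (j in seq_len(p)) {
    thr[[j]] <- estimate_thresholds(X[, j], n_categories, item = items[j])
    codes <- attr(thr[[j]], "codes")
    Xc[, j] <- codes[X[, j] + 1L]
  }
  rho <- diag(1, p)
  wts <- matrix(NA_real_, p, p)
  n <- nrow(X)
  for (i in seq_len(p - 1L)) {
    for (k in (i + 1L):p) {
      tab <- table(factor(Xc[, i], levels = 0:length(thr[[i]])),
                   factor(Xc[, k], levels = 0:length(thr[[k]])))
      r <- polychoric_pair(tab, thr[[i]], thr[[k]])
      rho[i, k] <- rho[k, i] <- as.numeric(r)
      # unit-information weight: inverse of n * Var(rho_hat)
      wts[i, k] <- wts[k, i] <- .polychor_info(as.numeric(r), thr[[i]], thr[[k]], n) / n
    }
  }
  dimnames(rho) <- dimnames(wts) <- list(items, items)
  structure(list(rho = rho, thresholds = thr, weights = wts, n = n,
                 collapsed = items[vapply(thr, attr, logical(1), "collapsed")]),
            class = "polycor")
}

#' @export
print.polycor <- function(x, ...) {
  p <- ncol(x$rho)
  cat("Polychoric correlation matrix: ", p, " items, n = ", x$n, "\n", sep = "")
  cat("Latent correlations range ",
      sprintf("[%.3f, %.3f]", min(x$rho[lower.tri(x$rho)]),
              max(x$rho[lower.tri(x$rho)])), "\n", sep = "")
  if (length(x$collapsed)) {
    cat("Items with collapsed categories:",
        paste(x$collapsed, collapse = ", "), "\n")
  }
  invisible(x)
}
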