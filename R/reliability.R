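# Reliability and criterion-validity statistics.

#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum \sigma^2_{item} / \sigma^2_{total})}
#' with sample (n-1) variances.
#'
#' @param items person x item numeric matrix with >= 2 columns.
#' @return scalar alpha (can be negative for incoherent item sets).
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  k <- ncol(X)
  if (k < 2L || nrow(X) < 2L) stop("need >= 2 items and >= 2 persons")
  vt <- stats::var(rowSums(X))
  if (vt <= 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / vt)
}

#' Kuder-Richardson 20
#'
#' Cronbach's alpha for dichotomous items with item variances
#' \eqn{p(1-p)} taken from the item means.
#'
#' @param items person x item binary (0/1) matrix.
#' @return scalar KR-20.
#' @export
kr20 <- function(items) {
  X <- as.matrix(items)
  k <- ncol(X)
  if (k < 2L || nrow(X) < 2L) stop("need >= 2 items and >= 2 persons")
  if (!all(X %in% c(0, 1))) stop("KR-20 requires binary items")
  p <- colMeans(X)
  vt <- stats::var(rowSums(X))
  if (vt <= 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(p * (1 - p)) / vt)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return scalar correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3L) stop("need >= 3 persons")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Two-sample t statistic
#'
#' Pooled-variance Student form by default (df = n1 + n2 - 2), matching
#' the convention of reporting df = n - 2 for a whole-sample split;
#' Welch's unequal-variance form behind \code{pooled = FALSE}.
#'
#' @param x_pos,x_neg numeric vectors (each >= 2 values).
#' @param pooled use the pooled-variance form (default TRUE).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{means}.
#' @export
two_sample_t <- function(x_pos, x_neg, pooled = TRUE) {
  n1 <- length(x_pos); n2 <- length(x_neg)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 observations")
  m1 <- mean(x_pos); m2 <- mean(x_neg)
  v1 <- stats::var(x_pos); v2 <- stats::var(x_neg)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) stop("zero variance")
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       means = c(pos = m1, neg = m2))
}

#' Mann-Whitney U statistic
#'
#' \eqn{U_a} counts pairs where group a outranks group b, with half
#' credit for ties; \eqn{U_b = n_a n_b - U_a}. Both orientations are
#' returned because reporting conventions differ. The normal
#' approximation p-value uses the tie-corrected variance.
#'
#' @param x_a,x_b numeric vectors (each >= 1 value).
#' @return list with \code{u_a}, \code{u_b}, \code{p_value}.
#' @export
mann_whitney_u <- function(x_a, x_b) {
  na <- length(x_a); nb <- length(x_b)
  if (na < 1L || nb < 1L) stop("each group needs >= 1 observation")
  r <- rank(c(x_a, x_b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  n <- na + nb
  ties <- table(c(x_a, x_b))
  tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- na * nb / 12 * (n + 1 - tie_adj)
  p <- if (s2 > 0) 2 * stats::pnorm(-abs(u_a - na * nb / 2) / sqrt(s2)) else 1
  list(u_a = u_a, u_b = u_b, p_value = min(p, 1))
}

#' Chi-square test of independence
#'
#' \eqn{\sum (O-E)^2/E} with \eqn{df = (r-1)(c-1)}; rows or columns with
#' zero margins are dropped with a warning.
#'
#' @param table r x c matrix of counts.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square_independence <- function(table) {
  O <- as.matrix(table)
  keep_r <- rowSums(O) > 0
  keep_c <- colSums(O) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero-margin rows/columns dropped")
    O <- O[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(O) < 2L || ncol(O) < 2L) stop("table degenerate after dropping zero margins")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
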