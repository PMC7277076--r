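# Independent oracles used across test files. Each re-derives a quantity
# by brute force or a different algorithm than the implementation.

# Polychoric by exhaustive likelihood grid search (step 0.001).
grid_polychoric <- function(tab, tau_a, tau_b, step = 0.001) {
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r) {
    a <- c(-Inf, tau_a, Inf); b <- c(-Inf, tau_b, Inf)
    g <- matrix(pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), r),
                nrow = length(a))
    p <- g[-1, -1, drop = FALSE] - g[-nrow(g), -1, drop = FALSE] -
      g[-1, -ncol(g), drop = FALSE] + g[-nrow(g), -ncol(g), drop = FALSE]
    sum(tab * log(pmax(p, 1e-12)))
  }, 0)
  grid[which.max(ll)]
}

# AUC as the normalized rank-pair count (ties get half credit).
pair_auc <- function(scores, reference) {
  pos <- scores[reference == 1]
  neg <- scores[reference == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Mann-Whitney U by exhaustive pair enumeration.
pair_u <- function(x_a, x_b) {
  sum(outer(x_a, x_b, function(a, b) (a > b) + 0.5 * (a == b)))
}

# The seven reconstructed 2x2 tables behind the published cutoff scan.
reference_tables <- function() {
  ref <- cigdc_cutoff_reference()
  lapply(seq_len(nrow(ref)), function(i) {
    reconstruct_counts(ref$sensitivity[i], ref$specificity[i],
                       ref$ppr[i], ref$npr[i], n_pos = 60, n_neg = 404)
  })
}

# Items the top-3 rule should drop from the 34-item pool.
dropped_items <- c("F1_4", "F2_3", "F4_3", "F5_3", "F6_2", "F9_1", "F9_5")
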