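test_that("confusion tables count exactly and conserve margins", {
  scores <- c(10, 25, 19, 30, 5, 22, 18, 21, 7, 20)
  ref <- c(0, 1, 0, 1, 0, 0, 1, 1, 0, 0)
  t <- confusion_table(scores, ref, 20)
  # hand count: screen-positive {25,30,22,21,20}; positives {25,30,18,21}
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 3L, fp = 2L, fn = 1L, tn = 4L))
  expect_equal(t$tp + t$fn, sum(ref))
  expect_equal(t$fp + t$tn, sum(ref == 0))
  none <- confusion_table(scores, ref, 99)
  expect_equal(none$tp + none$fp, 0L)
  all_pos <- confusion_table(scores, ref, min(scores))
  expect_equal(all_pos$fn + all_pos$tn, 0L)
  expect_error(confusion_table(numeric(0), numeric(0), 5), "empty")
})

test_that("efficacy indices follow their formulas including Haldane's correction", {
  perfect <- efficacy_indices(confusion_table(c(rep(1, 10), rep(0, 10)),
                                              c(rep(1, 10), rep(0, 10)), 1))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$youden, 1)
  e <- efficacy_indices(structure(list(tp = 2L, fp = 3L, fn = 1L, tn = 4L),
                                  class = "confusion_table"))
  expect_equal(e$sensitivity, 200 / 3, tolerance = 1e-12)
  expect_equal(e$specificity, 400 / 7, tolerance = 1e-12)
  expect_equal(round(e$kappa, 2), 0.20)
  expect_equal(round(e$youden, 3), 0.238)
  expect_equal(e$dor, (2 * 4) / (3 * 1), tolerance = 1e-12)
  # a zero cell switches DOR to the +0.5-all-cells form
  z <- efficacy_indices(structure(list(tp = 5L, fp = 0L, fn = 2L, tn = 8L),
                                  class = "confusion_table"))
  expect_equal(z$dor, (5.5 * 8.5) / (0.5 * 2.5), tolerance = 1e-12)
  # empty screen-positive margin flags PPR rather than silently zeroing
  u <- efficacy_indices(structure(list(tp = 0L, fp = 0L, fn = 3L, tn = 7L),
                                  class = "confusion_table"))
  expect_true("ppr" %in% u$undefined)
  expect_true(is.nan(u$ppr))
})

test_that("kappa is 1 only for perfect agreement and near 0 under independence", {
  set.seed(99)
  scores <- rbinom(10000, 1, 0.3)
  ref <- rbinom(10000, 1, 0.25)
  k <- efficacy_indices(confusion_table(scores, ref, 1))$kappa
  expect_lt(abs(k), 0.02)
  imperfect <- efficacy_indices(confusion_table(
    c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1), 1))
  expect_lt(imperfect$kappa, 1)
})

test_that("trapezoid AUC equals the rank-pair statistic and known cases", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(4, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc, 0.875)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    scores <- sample(0:12, n, replace = TRUE)
    ref <- rbinom(n, 1, 0.4)
    if (length(unique(ref)) < 2) ref[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, ref)$auc, pair_auc(scores, ref),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both")
})

test_that("cutoff scans compose per-cutoff tables and keep the monotone shape", {
  d <- generate_dataset(igdc_config(n_persons = 464, seed = 7))
  keep <- setdiff(colnames(d$responses), dropped_items)
  scores <- sum_score(d$responses, keep)
  ref <- as.integer(rowSums(d$dsm_items) >= 5)
  scan <- scan_cutoffs(scores, ref, c(10, 45))
  expect_equal(nrow(scan$rows), 36L)
  i <- sample(nrow(scan$rows), 1)
  t_i <- confusion_table(scores, ref, scan$rows$cutoff[i])
  expect_equal(scan$rows$tp[i], t_i$tp)
  expect_equal(scan$rows$tn[i], t_i$tn)
  expect_true(all(diff(scan$rows$sensitivity) <= 1e-12))
  expect_true(all(diff(scan$rows$specificity) >= -1e-12))
  expect_true(all(scan$rows$tp + scan$rows$fn == sum(ref)))
  one <- scan_cutoffs(scores, ref, c(20, 20))
  expect_equal(nrow(one$rows), 1L)
})

test_that("reconstructed published tables are unique and drive the selection rule", {
  tabs <- reference_tables()
  counts <- t(vapply(tabs, function(t) unlist(t[c("tp", "fp", "fn", "tn")]),
                     integer(4)))
  expect_equal(counts[, "tp"], c(55L, 54L, 54L, 52L, 49L, 46L, 41L))
  expect_equal(counts[, "tn"], c(295L, 317L, 325L, 334L, 345L, 352L, 365L))
  scan <- scan_from_tables(16:22, tabs)
  sel <- select_optimal_cutoff(scan)
  expect_equal(sel$candidates, 17:21)
  expect_equal(sort(sel$kappa_max_set), c(20L, 21L))
  expect_equal(sel$selected, 20L)
  # no admissible cutoff is an explicit result, not an error
  none <- select_optimal_cutoff(scan, min_sens = 99.9, min_spec = 99.9)
  expect_true(is.na(none$selected))
  expect_match(paste(none$audit, collapse = " "), "no admissible")
  # single admissible row selects itself
  single <- select_optimal_cutoff(scan_from_tables(20L, tabs[5]))
  expect_equal(single$selected, 20L)
})

test_that("the rounded-kappa tie rule overrides the unrounded ordering", {
  # cutoff 1 has lower unrounded kappa but higher sensitivity; both round
  # to the same 2-dp kappa, so the tie-break must pick cutoff 1
  tabs <- list(
    structure(list(tp = 42L, fp = 26L, fn = 8L, tn = 124L), class = "confusion_table"),
    structure(list(tp = 40L, fp = 22L, fn = 10L, tn = 128L), class = "confusion_table"))
  scan <- scan_from_tables(1:2, tabs)
  expect_lt(scan$rows$kappa[1], scan$rows$kappa[2])
  expect_equal(round_half_up(scan$rows$kappa[1], 2),
               round_half_up(scan$rows$kappa[2], 2))
  sel <- select_optimal_cutoff(scan)
  expect_equal(sel$selected, 1L)
  expect_match(paste(sel$audit, collapse = " "), "unrounded")
})

test_that("classification splits the sample with conserved complements", {
  tabs <- reference_tables()
  t20 <- tabs[[5]]
  scores <- rep(c(20L, 19L), c(t20$tp + t20$fp, t20$fn + t20$tn))
  g <- classify(scores, 20)
  expect_equal(round_half_up(100 * mean(g), 1), 23.3)
  expect_equal(sum(attr(g, "group_sizes")), 464L)
  expect_true(all(classify(c(1, 2, 3), 10) == 0L))
})
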