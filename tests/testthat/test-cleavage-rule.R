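test_that("order_variants sorts by cleaved count, then mean activity, then id", {
  # counts A=5, B=2, C=5 over 6 targets; mean activity C > A
  M <- rbind(A = c(1, 1, 1, 1, 1, 0),
             B = c(1, 1, 0, 0, 0, 0),
             C = c(1, 1, 1, 1, 1, 0))
  colnames(M) <- paste0("T", 1:6)
  vals <- M * 0.9
  vals["C", ] <- M["C", ] * 1.1
  calls <- call_cleavage(norm_activity(vals))
  expect_identical(order_variants(calls), c("C", "A", "B"))

  # degenerate ties: all equal -> lexicographic
  M2 <- rbind(Zv = c(1, 0), Av = c(1, 0), Mv = c(1, 0))
  colnames(M2) <- c("T1", "T2")
  expect_identical(order_variants(make_calls(M2)), c("Av", "Mv", "Zv"))

  # single variant -> identity
  expect_identical(order_variants(make_calls(M2[1, , drop = FALSE])), "Zv")
})

test_that("order_targets sorts by cleaved-by count and resolves ties to minimize outliers", {
  # staircase-consistent: any tie order gives 0 outliers -> lexicographic
  M <- staircase_matrix(c(4, 2, 1), 4)
  calls <- make_calls(M)
  ord <- order_targets(calls)
  expect_identical(ord, c("T01", "T02", "T03", "T04"))
  # T02..T04 counts: 2,1,1 -> tie block (T03,T04) stays lexicographic

  # distinct counts -> sorted strictly by count
  M2 <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  dimnames(M2) <- list(paste0("V", 1:3), c("Tb", "Tc", "Ta"))
  M2 <- M2[, c(3, 1, 2)]  # shuffle columns: counts Ta=1, Tb=3, Tc=2
  expect_identical(order_targets(make_calls(M2)), c("Tb", "Tc", "Ta"))
})

test_that("order_targets matches the brute-force oracle on noised staircases", {
  set.seed(21)
  for (i in 1:40) {
    nv <- sample(2:4, 1); nt <- sample(3:6, 1)
    M <- staircase_matrix(sort(sample(0:nt, nv, replace = TRUE),
                               decreasing = TRUE), nt)
    # flip one random cell
    f <- sample(length(M), 1)
    M[f] <- 1 - M[f]
    calls <- make_calls(M)
    ord <- order_targets(calls)
    map <- suppressWarnings(
      fit_boundary(calls, variant_order = order_variants(calls),
                   target_order = ord))
    bf <- brute_force_best_order(calls)
    expect_identical(nrow(map$outliers), as.integer(bf$min_outliers))
  }
})

test_that("fit_boundary picks the minimal-misclassification cutoff with small-b ties", {
  # ordered row [1,1,0,1,0]: b=2 and b=4 both cost 1; smaller b wins,
  # leaving one outlier (the cleaved cell at position 4)
  M <- matrix(c(1, 1, 0, 1, 0), 1, 5,
              dimnames = list("V1", paste0("T", 1:5)))
  calls <- make_calls(M)
  map <- suppressWarnings(
    fit_boundary(calls, variant_order = "V1",
                 target_order = paste0("T", 1:5)))
  expect_identical(unname(map$boundary["V1"]), 2L)
  expect_identical(nrow(map$outliers), 1L)
  expect_identical(map$outliers$target_id, "T4")
  expect_identical(map$outliers$observed, "cleaved")

  # all-cleaved variant: b = n_targets, no outliers
  M2 <- matrix(1, 1, 4, dimnames = list("V1", paste0("T", 1:4)))
  map2 <- fit_boundary(make_calls(M2), variant_order = "V1",
                       target_order = paste0("T", 1:4))
  expect_identical(unname(map2$boundary["V1"]), 4L)
  expect_identical(nrow(map2$outliers), 0L)

  # perfect staircase: boundaries equal observed counts, zero outliers
  M3 <- staircase_matrix(c(5, 3, 1), 5)
  map3 <- rank_cleavage_map(make_calls(M3))
  expect_identical(unname(map3$boundary), c(5L, 3L, 1L))
  expect_identical(nrow(map3$outliers), 0L)

  # count_matched mode pins b at the observed cleaved count
  map4 <- suppressWarnings(
    fit_boundary(calls, variant_order = "V1",
                 target_order = paste0("T", 1:5), mode = "count_matched"))
  expect_identical(unname(map4$boundary["V1"]), 3L)
})

test_that("score_rule_fit pools the confusion matrix and computes the G-mean", {
  M <- staircase_matrix(c(5, 3, 1), 5)
  fit0 <- score_rule_fit(rank_cleavage_map(make_calls(M)))
  expect_equal(fit0$gmean, 1.00)
  expect_identical(fit0$n_outliers, 0L)

  # 10 cleaved / 10 not-cleaved with exactly one FN
  M1 <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 1), c(1, 1, 0, 0),
              c(1, 0, 0, 0), c(0, 0, 0, 0))
  dimnames(M1) <- list(paste0("V", 1:5), paste0("T", 1:4))
  calls1 <- make_calls(M1)
  map1 <- suppressWarnings(
    fit_boundary(calls1, variant_order = paste0("V", 1:5),
                 target_order = paste0("T", 1:4)))
  fit1 <- score_rule_fit(map1)
  expect_identical(c(fit1$TP, fit1$FN, fit1$TN, fit1$FP), c(9L, 1L, 10L, 0L))
  expect_equal(fit1$sensitivity, 0.9)
  expect_equal(fit1$specificity, 1.0)
  expect_equal(fit1$gmean, sqrt(0.9))
  expect_identical(fit1$n_outliers, 1L)
  # invariant: gmean = sqrt(sens * spec)
  expect_equal(fit1$gmean, sqrt(fit1$sensitivity * fit1$specificity))

  # single-class matrix: gmean undefined and flagged
  Mall <- matrix(1, 3, 3, dimnames = list(paste0("V", 1:3), paste0("T", 1:3)))
  fit_all <- score_rule_fit(rank_cleavage_map(make_calls(Mall)))
  expect_true(is.na(fit_all$gmean))
  expect_identical(fit_all$flag, "single_class")
})

test_that("gmean equals 1 exactly when there are no outliers", {
  set.seed(22)
  for (i in 1:20) {
    nv <- sample(2:5, 1); nt <- sample(3:7, 1)
    M <- staircase_matrix(sort(sample(0:nt, nv, replace = TRUE),
                               decreasing = TRUE), nt)
    if (all(M == M[1, 1])) next                    # skip single-class
    if (sum(M) == 0 || sum(M) == length(M)) next
    fit <- score_rule_fit(rank_cleavage_map(make_calls(M)))
    expect_identical(fit$n_outliers == 0L, isTRUE(all.equal(fit$gmean, 1)))
  }
})

test_that("flipping a concordant cell (map fixed) never increases the G-mean", {
  set.seed(23)
  for (i in 1:20) {
    M <- staircase_matrix(sort(sample(0:6, 4, replace = TRUE),
                               decreasing = TRUE), 6)
    if (sum(M) == 0 || sum(M) == length(M)) next
    calls <- make_calls(M)
    map <- suppressWarnings(rank_cleavage_map(calls))
    before <- score_rule_fit(map)$gmean
    # flip one concordant (correctly classified) cell, keep the map fixed
    pred <- map$calls & FALSE
    for (r in seq_len(nrow(pred))) {
      if (map$boundary[r] > 0) pred[r, seq_len(map$boundary[r])] <- TRUE
    }
    conc <- which(map$calls == pred)
    if (!length(conc)) next
    cell <- sample(conc, 1)
    map$calls[cell] <- !map$calls[cell]
    after <- score_rule_fit(map)$gmean
    expect_true(is.na(after) || after <= before + 1e-12)
  }
})

test_that("variant_roc computes tie-aware AUC and matches the trapezoid area", {
  ord <- paste0("T", 1:6)
  perfect <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), ord)
  r1 <- variant_roc(ord, perfect, "v")
  expect_equal(r1$auc, 1.00)
  expect_equal(r1$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r1$points[nrow(r1$points), ]), c(fpr = 1, tpr = 1))

  # alternating balanced calls: closed-form rank AUC
  alt <- stats::setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), ord)
  # positives at ranks 6,4,2; AUC = P(pos outranks neg) = (3+2+1)/9... via
  # the rank statistic: (sum ranks pos - n1(n1+1)/2)/(n1 n0)
  expect_equal(variant_roc(ord, alt, "v")$auc,
               (sum(c(6, 4, 2)) - 3 * 4 / 2) / 9)

  # tie groups: everything tied -> AUC exactly 0.5
  r_tied <- variant_roc(ord, alt, "v", tie_groups = rep(1, 6))
  expect_equal(r_tied$auc, 0.5)

  # all-one-class column: undefined, flagged
  r_flag <- variant_roc(ord, stats::setNames(rep(TRUE, 6), ord), "v")
  expect_true(is.na(r_flag$auc))
  expect_identical(r_flag$flag, "single_class")

  # property: rank AUC equals trapezoid AUC, curve monotone
  set.seed(24)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    calls <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                             paste0("T", seq_len(n)))
    if (all(calls) || !any(calls)) next
    r <- variant_roc(paste0("T", seq_len(n)), calls, "v")
    expect_equal(r$auc, cleavr:::trapezoid_auc(r$points), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("relabeling targets without changing the order leaves the ROC unchanged", {
  set.seed(25)
  n <- 8
  calls <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                           paste0("T", 1:n))
  r1 <- variant_roc(paste0("T", 1:n), calls, "v")
  relabeled <- stats::setNames(calls, paste0("X", 1:n))
  r2 <- variant_roc(paste0("X", 1:n), relabeled, "v")
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$points, r2$points)
})

test_that("brute_force_best_order enumerates correctly and guards size", {
  M <- staircase_matrix(c(4, 2, 1), 4)
  expect_identical(brute_force_best_order(make_calls(M))$min_outliers, 0L)

  # a flipped staircase cell can sometimes be reordered away; check that
  # the oracle indeed finds the absorbing order
  Mf <- M; Mf[2, 4] <- 1
  expect_identical(brute_force_best_order(make_calls(Mf))$min_outliers, 0L)

  # crossing pattern that no order can absorb: one outlier minimum
  Mx <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("V1", "V2"), c("T1", "T2")))
  expect_identical(brute_force_best_order(make_calls(Mx))$min_outliers, 1L)

  M0 <- matrix(0, 3, 4, dimnames = list(paste0("V", 1:3), paste0("T", 1:4)))
  expect_identical(brute_force_best_order(make_calls(M0))$min_outliers, 0L)

  big <- matrix(0, 5, 6, dimnames = list(paste0("V", 1:5), paste0("T", 1:6)))
  expect_error(brute_force_best_order(make_calls(big)), "too large")
})
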