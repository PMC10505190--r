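test_that("sample_model is reproducible and validates degenerate inputs", {
  p1 <- sample_model(n_targets = 10, n_variants = 5, seed = 7)
  p2 <- sample_model(n_targets = 10, n_variants = 5, seed = 7)
  expect_identical(p1, p2)
  p3 <- sample_model(n_targets = 10, n_variants = 5, seed = 8)
  expect_false(identical(p1$c, p3$c))

  # single WT-like variant with zero span
  p4 <- sample_model(n_targets = 5, n_variants = 1, f_span = c(0, 0), seed = 1)
  expect_identical(names(p4$f), "WT")
  expect_identical(unname(p4$f), 0)

  expect_error(sample_model(c_dist = c(5, 5)), "degenerate")
  expect_error(sample_model(n_variants = 3, f_span = c(0, 0)), "degenerate")
  expect_error(sample_model(m = c(`25` = 1)), "1..20")
})

test_that("evenly spaced inhibitions give distinct expected cleavable fractions", {
  p <- sample_model(n_targets = 2000, n_variants = 19, c_dist = c(0, 10),
                    f_span = c(0, 9.5), seed = 5)
  # analytic: P(c > f_v) = (10 - f_v)/10 under Uniform(0, 10)
  frac_expected <- (10 - p$f) / 10
  frac_observed <- vapply(p$f, function(fv) mean(p$c > fv), 0)
  expect_true(all(abs(frac_observed - frac_expected) < 0.05))
  expect_true(all(diff(frac_expected) < 0))        # strictly distinct
})

test_that("noiseless simulation survives the full normalize/call path losslessly", {
  p <- sample_model(n_targets = 12, n_variants = 6, cleaved_band = c(1, 1),
                    residual_scale = 0, seed = 3)
  raw <- simulate_disruption_matrix(p, replicate_sd = 0)
  m <- normalize_to_wt(raw)
  calls <- call_cleavage(m)
  truth <- outer(seq_along(p$f), seq_along(p$c),
                 Vectorize(function(i, j) {
                   names(p$f)[i] == "WT" || p$c[j] > p$f[i]
                 }))
  dimnames(truth) <- list(names(p$f), names(p$c))
  expect_identical(calls$calls, truth)
  fit <- score_rule_fit(suppressWarnings(rank_cleavage_map(calls, m)))
  expect_equal(fit$gmean, 1.00)
})

test_that("only WT cleaves when every contribution is below the variant floor", {
  p <- sample_model(n_targets = 6, n_variants = 4, c_dist = c(0, 1),
                    f_span = c(0, 10), seed = 2)
  p$f[-1] <- p$f[-1] + 2                    # all IFNs above max contribution
  raw <- simulate_disruption_matrix(p, replicate_sd = 0)
  calls <- call_cleavage(normalize_to_wt(raw))
  expect_true(all(calls$calls["WT", ]))
  expect_false(any(calls$calls[-1, ]))
})

test_that("simulated matrices admit a zero-outlier ordering when noiseless (Guttman property)", {
  for (s in 1:5) {
    p <- sample_model(n_targets = 10, n_variants = 5, residual_scale = 0,
                      softness = 0, seed = 100 + s)
    raw <- simulate_disruption_matrix(p, replicate_sd = 0)
    calls <- call_cleavage(normalize_to_wt(raw))
    map <- suppressWarnings(rank_cleavage_map(calls))
    expect_identical(nrow(map$outliers), 0L)
  }
})

test_that("hard-threshold monotonicity: raising f shrinks, raising c grows cleaved sets", {
  p <- sample_model(n_targets = 10, n_variants = 5, residual_scale = 0,
                    seed = 9)
  base <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p, replicate_sd = 0)))$calls

  p_f <- p; p_f$f["IFN02"] <- p_f$f["IFN02"] + 3
  after_f <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p_f, replicate_sd = 0)))$calls
  expect_true(all(!after_f["IFN02", ] | base["IFN02", ]))  # subset
  expect_identical(after_f[setdiff(rownames(base), "IFN02"), ],
                   base[setdiff(rownames(base), "IFN02"), ])

  p_c <- p; p_c$c["T03"] <- p_c$c["T03"] + 3
  after_c <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p_c, replicate_sd = 0)))$calls
  expect_true(all(!base[, "T03"] | after_c[, "T03"]))      # superset
  expect_identical(after_c[, setdiff(colnames(base), "T03")],
                   base[, setdiff(colnames(base), "T03")])
})

test_that("mismatch screen: zero penalty reproduces on-target calls, huge penalty kills all", {
  p <- sample_model(n_targets = 8, n_variants = 4, cleaved_band = c(1, 1),
                    residual_scale = 0, m = c(`18` = 0, `19` = 1000), seed = 6)
  off <- simulate_mismatch_screen(p)
  on_calls <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p, replicate_sd = 0)))$calls
  off18 <- off[off$position == 18, ]
  for (r in seq_len(nrow(off18))) {
    expect_identical(off18$value[r] >= 0.20,
                     unname(on_calls[off18$variant_id[r], off18$target_id[r]]))
  }
  expect_true(all(off$value[off$position == 19] < 0.20))

  # off-target calls are a subset of on-target calls whenever m >= 0
  p2 <- sample_model(n_targets = 8, n_variants = 4, cleaved_band = c(1, 1),
                     residual_scale = 0, m = c(`20` = 1.5), seed = 16)
  off2 <- simulate_mismatch_screen(p2)
  on2 <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p2, replicate_sd = 0)))$calls
  hit <- off2$value >= 0.20
  for (r in which(hit)) {
    expect_true(on2[off2$variant_id[r], off2$target_id[r]])
  }
  expect_error(simulate_mismatch_screen(p2, positions = 25), "1..20")
})

test_that("a target-matched variant cleaves on-target but not off-target", {
  # contribution between f of the matched variant and the mismatch-shifted
  # threshold: c - f < m
  p <- sample_model(n_targets = 1, n_variants = 3, f_span = c(0, 4),
                    cleaved_band = c(1, 1), residual_scale = 0,
                    m = c(`18` = 3), seed = 4)
  p$c[] <- 3                                  # f = 0, 2, 4
  on <- call_cleavage(normalize_to_wt(
    simulate_disruption_matrix(p, replicate_sd = 0)))$calls
  expect_true(on["IFN01", 1])                 # 3 > 2: cleaves on-target
  off <- simulate_mismatch_screen(p)
  v <- off[off$variant_id == "IFN01", "value"]
  expect_true(all(v < 0.20))                  # 3 < 2 + 3: no off-target
})

test_that("recovery: noiseless concordances are 1, shuffled labels give null concordance", {
  p <- sample_model(seed = 31)                # default 50 x 20 panel
  raw <- simulate_disruption_matrix(p, replicate_sd = 0)
  map <- suppressWarnings(rank_cleavage_map(call_cleavage(normalize_to_wt(raw))))
  rec <- recover_and_compare(p, map)
  expect_equal(rec$target_concordance, 1.00)
  expect_equal(rec$variant_concordance, 1.00)
  expect_equal(rec$gmean, 1.00)

  # permutation null: shuffling the true contributions kills concordance
  set.seed(32)
  rhos <- replicate(100, {
    ps <- p
    ps$c[] <- sample(ps$c)
    recover_and_compare(ps, map)$target_concordance_all
  })
  expect_lt(abs(mean(rhos)), 0.05)
  expect_lt(mean(abs(rhos)), 0.2)
})

test_that("moderate-noise recovery keeps target concordance high", {
  p <- sample_model(seed = 33)                # stated world defaults
  raw <- simulate_disruption_matrix(p)        # replicate jitter sd 1
  map <- suppressWarnings(rank_cleavage_map(call_cleavage(normalize_to_wt(raw))))
  rec <- recover_and_compare(p, map)
  expect_gte(rec$target_concordance_all, 0.9)
  expect_gte(rec$variant_concordance_all, 0.9)
})

test_that("design enumerations count mixture guides and saturating off-targets", {
  d <- mismatch_design(paste0("T", 1:4), positions = c(18, 19, 20))
  expect_identical(nrow(d), 4L * 3L * 3L)
  expect_identical(unique(d$position), c(18, 19, 20))
  s <- single_mismatch_design(paste0("g", 1:2))
  expect_identical(nrow(s), 2L * 20L * 3L)
  expect_error(mismatch_design("T1", positions = 0), "1..20")
})
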