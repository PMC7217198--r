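test_that("interim rule eliminates, continues and declares joint winners", {
  design <- design_preset("four_arm_sepsis")
  ## statistics strong enough to knock out arm 2 (Z = 14.38, V = 16.28
  ## exceeds the elimination line 10.90266 + 0.12380 V)
  h <- fixture_table5()
  res <- apply_interim(matrix(h$n[, , 4], 4, 4), matrix(h$S[, , 4], 4, 4),
                       active = 1:4, design_preset("four_arm_sepsis",
                                                   n_strata = 4))
  expect_true(2 %in% res$eliminated)
  expect_false(res$stop)
  ## all-zero scores at high information: every pair no different
  cn <- matrix(360, 4, 1); cs <- matrix(180, 4, 1)  # V = 45 per pair
  res <- apply_interim(cn, cs, 1:4, design)
  expect_true(res$stop)
  expect_equal(res$kind, "joint_winners")
  expect_setequal(res$winners, 1:4)
  ## same balance at low information: continue
  cn <- matrix(36, 4, 1); cs <- matrix(18, 4, 1)
  res <- apply_interim(cn, cs, 1:4, design)
  expect_false(res$stop)
  expect_equal(nrow(res$decisions), 6)
})

test_that("a degenerate scenario resolves at the first interim analysis", {
  h <- simulate_multiarm_trial(design_preset("four_arm_sepsis"),
                               p = c(1, 0, 0, 0), seed = 1)
  expect_equal(h$K, 1L)
  expect_equal(h$outcome$kind, "sole_winner")
  expect_equal(h$outcome$winners, 1L)
  expect_equal(h$outcome$total_n, 144L)
  expect_equal(h$eliminated_by, c(NA_integer_, 1L, 1L, 1L))
})

test_that("accrual is conserved and histories freeze at elimination", {
  design <- design_preset("four_arm_sepsis", n_strata = 4)
  p <- matrix(c(0.7, 0.5, 0.45, 0.4), 4, 4)
  for (s in 1:5) {
    h <- simulate_multiarm_trial(design, p, seed = s)
    for (i in 1:4) {
      ks <- seq_len(h$last_interim[i])
      tot <- colSums(matrix(h$n[i, , ks], nrow = 4))
      expect_equal(diff(c(0, tot)), rep(36, length(ks)))
      expect_true(all(h$S[i, , ks] <= h$n[i, , ks]))
      expect_true(all(t(apply(cbind(0, matrix(h$S[i, , ks], 4)), 1, diff)) >= 0))
      ## nothing recorded beyond the arm's final analysis
      if (h$last_interim[i] < h$K)
        expect_true(all(is.na(h$n[i, , (h$last_interim[i] + 1):h$K])))
    }
    expect_lte(h$outcome$total_n, design$max_total_n)
    expect_lte(h$K, design$max_interims)
  }
})

test_that("simulation is reproducible under a fixed seed", {
  d <- design_preset("four_arm_simple")
  h1 <- simulate_multiarm_trial(d, c(0.6, 0.5, 0.4, 0.4), seed = 99)
  h2 <- simulate_multiarm_trial(d, c(0.6, 0.5, 0.4, 0.4), seed = 99)
  expect_identical(h1$S, h2$S)
  expect_identical(h1$outcome, h2$outcome)
  t1 <- simulate_two_arm_trial(design_preset("two_arm_tri"), 0.6, 0.5,
                               seed = 7)
  t2 <- simulate_two_arm_trial(design_preset("two_arm_tri"), 0.6, 0.5,
                               seed = 7)
  expect_identical(t1$S, t2$S)
})

test_that("arm labels are exchangeable", {
  d <- design_preset("four_arm_simple")
  set.seed(5)
  win1 <- mean(replicate(300, {
    h <- simulate_multiarm_trial(d, c(0.6, 0.4, 0.4, 0.4))
    identical(h$outcome$winners, 1L)
  }))
  win2 <- mean(replicate(300, {
    h <- simulate_multiarm_trial(d, c(0.4, 0.6, 0.4, 0.4))
    identical(h$outcome$winners, 2L)
  }))
  expect_lt(abs(win1 - win2), 0.1)  # ~3 MC SEs at 300 replicates
})

test_that("two-arm trial stops on the printed boundary convention", {
  d2 <- design_preset("two_arm_tri")
  h <- simulate_two_arm_trial(d2, 1, 0, seed = 1)
  expect_equal(h$K, 1L)
  expect_equal(h$outcome$boundary, "upper")   # Z = 18 over u_1 ~ 11.49
  expect_equal(h$outcome$z_star, 18)
  h <- simulate_two_arm_trial(d2, 0, 1, seed = 1)
  expect_equal(h$outcome$boundary, "lower")
  expect_equal(h$outcome$kind, "no_better")
  ## boundary record maps to the 0/1 convention of the published runs
  set.seed(21)
  for (r in 1:10) {
    h <- simulate_two_arm_trial(d2, 0.65, 0.55)
    if (!is.na(h$outcome$boundary)) {
      b <- as.integer(h$outcome$boundary == "upper")
      if (b == 1L) expect_gte(h$outcome$z_star,
                              10.93898 + 0.123134 * h$outcome$v_star)
      else expect_lte(h$outcome$z_star,
                      -10.93898 + 0.369402 * h$outcome$v_star)
    }
    expect_lte(h$K, d2$max_interims + d2$extension_interims)
  }
})

test_that("the patient cap stops the trial before it is exceeded", {
  b <- pairwise_boundary(50, 0.1, 0.5)  # unreachable boundaries
  d <- design_spec(n_arms = 4, boundary = b, per_arm_increment = 36,
                   max_total_n = 500, max_interims = 40)
  h <- simulate_multiarm_trial(d, c(0.5, 0.5, 0.5, 0.5), seed = 3)
  expect_equal(h$outcome$kind, "unresolved")
  expect_equal(h$outcome$stop_reason, "cap_reached")
  expect_equal(h$outcome$total_n, 432L)  # 3 interims of 144; a 4th would top 500
})
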