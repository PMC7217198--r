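test_that("back-sampling anchored at the first interim returns the data", {
  h <- two_arm_case_history(35, 59, 2)
  spec <- reverse_start_spec(h, start_interim = 1)
  b <- reverse_fill(spec, 50)
  expect_true(all(b$S[, 1, 1, 1] == h$S[1, 1, 1]))
  expect_true(all(b$S[, 2, 1, 1] == h$S[2, 1, 1]))
  expect_true(all(consistency_mask(b)))
})

test_that("an all-success arm back-fills deterministically", {
  tab <- rbind(
    data.frame(arm = 1, stratum = 1, interim = 1:3, cum_n = c(36, 72, 108),
               cum_S = c(36, 72, 108)),
    data.frame(arm = 2, stratum = 1, interim = 1:3, cum_n = c(36, 72, 108),
               cum_S = c(10, 20, 30)))
  h <- trial_history(design_preset("two_arm_tri"), tab)
  b <- reverse_fill(reverse_start_spec(h), 200)
  expect_true(all(b$S[, 1, 1, 1] == 36))
  expect_true(all(b$S[, 1, 1, 2] == 72))
})

test_that("back-filled counts follow the exact hypergeometric law", {
  set.seed(31)
  h <- toy_history(2, 3)
  spec <- reverse_start_spec(h)
  b <- reverse_fill(spec, 5e4)
  ## arm 1: draws of 2 from 4 responses of which 2 are successes
  emp <- tabulate(b$S[, 1, 1, 1] + 1L, 3) / 5e4
  expect_lt(max(abs(emp - stats::dhyper(0:2, 2, 2, 2))), 0.01)
  ## arm 2: 3 successes among 4
  emp <- tabulate(b$S[, 2, 1, 1] + 1L, 3) / 5e4
  expect_lt(max(abs(emp - stats::dhyper(0:2, 3, 1, 2))), 0.01)
})

test_that("filtered back-sampling matches exhaustive path enumeration", {
  ## Enumerable toy trial: conditional law of the first-interim counts
  ## given the terminal counts and continuation, by direct enumeration of
  ## the hypergeometric masses with stopping states removed.
  set.seed(32)
  d <- toy_design()
  for (term in list(c(2, 2), c(3, 2), c(2, 3))) {
    h <- toy_history(term[1], term[2])
    exact <- matrix(0, 3, 3)
    for (s1 in 0:2) for (s2 in 0:2) {
      w <- stats::dhyper(s1, term[1], 4 - term[1], 2) *
           stats::dhyper(s2, term[2], 4 - term[2], 2)
      st <- pair_statistics(2, s1, 2, s2)
      if (classify_pair(st$z, st$v, d$boundary) == "continue")
        exact[s1 + 1, s2 + 1] <- w
    }
    exact <- exact / sum(exact)
    b <- reverse_fill(reverse_start_spec(h), 1e5)
    keep <- consistency_mask(b)
    emp <- table(factor(b$S[keep, 1, 1, 1], 0:2),
                 factor(b$S[keep, 2, 1, 1], 0:2)) / sum(keep)
    tv <- sum(abs(emp - exact)) / 2
    expect_lt(tv, 0.01)
  }
})

test_that("paths that would have stopped early are deleted", {
  h <- two_arm_case_history(35, 59, 2)
  spec <- reverse_start_spec(h)
  b <- reverse_fill(spec, 1000)
  ## force one replicate over the first-interim efficacy boundary
  b$S[1, 1, 1, 1] <- 36; b$S[1, 2, 1, 1] <- 0   # Z1 = 18 > u1
  keep <- consistency_mask(b)
  expect_false(keep[1])
  ## a path equal to a mid-region value is retained
  b$S[2, 1, 1, 1] <- 17; b$S[2, 2, 1, 1] <- 29
  expect_true(consistency_mask(b)[2])
})

test_that("completeness is stable across chunk sizes and reproducible", {
  h <- two_arm_case_history(82, 55, 3)   # strong upper crossing
  r1 <- rb2_estimate(h, option = 2, n_sims = 4e4, seed = 5,
                     chunk_size = 4e4)
  r2 <- rb2_estimate(h, option = 2, n_sims = 4e4, seed = 5,
                     chunk_size = 7000)
  expect_lt(abs(r1$prop_complete - r2$prop_complete), 0.01)
  r3 <- rb2_estimate(h, option = 2, n_sims = 4e4, seed = 5,
                     chunk_size = 4e4)
  expect_identical(r1$theta_tilde, r3$theta_tilde)
  expect_identical(r1$n_complete, r3$n_complete)
  ## published values for this run: 95.8% complete, estimate 1.069
  expect_lt(abs(r1$prop_complete - 0.958), 0.01)
  expect_lt(abs(r1$theta_tilde - 1.069), 0.03)
})

test_that("a trial stopped at the first analysis needs no conditioning", {
  tab <- rbind(data.frame(arm = 1, stratum = 1, interim = 1, cum_n = 36,
                          cum_S = 30),
               data.frame(arm = 2, stratum = 1, interim = 1, cum_n = 36,
                          cum_S = 8))
  h <- trial_history(design_preset("two_arm_tri"), tab)
  r <- rb2_estimate(h, option = 2, n_sims = 500, seed = 1)
  st <- pair_statistics(36, 30, 36, 8)
  expect_equal(r$theta_tilde, st$z / st$v)
  expect_equal(r$se, 1 / sqrt(st$v))
  expect_equal(r$prop_complete, 1)
})

test_that("the stratified analysis uses the small-sample information", {
  h <- fixture_table5()
  set.seed(9)
  spec <- reverse_start_spec(h, 4)
  b <- reverse_fill(spec, 200)
  keep <- consistency_mask(b)
  ## replicate the estimator arithmetic for the first consistent path
  r <- rb2_estimate(h, pairs = rbind(c(1, 2)), option = 2, n_sims = 200,
                    seed = 9, min_complete = 10)
  i1 <- which(keep)
  th <- vapply(i1, function(r_) {
    z <- 0; vp <- 0
    for (c in 1:4) {
      z <- z + pair_statistics(h$n[1, c, 1], b$S[r_, 1, c, 1],
                               h$n[2, c, 1], b$S[r_, 2, c, 1])$z
      vp <- vp + adjusted_information(h$n[1, c, 1], b$S[r_, 1, c, 1],
                                      h$n[2, c, 1], b$S[r_, 2, c, 1])$v_prime
    }
    z / vp
  }, 0)
  expect_equal(r$theta_tilde, mean(th), tolerance = 1e-10)
})

test_that("standard errors are reported or flagged, never silent NaN", {
  h <- fixture_table5()
  r <- rb2_estimate(h, option = 2, n_sims = 3000, seed = 2,
                    min_complete = 1000)
  expect_true(all(is.na(r$se) | r$se > 0))
  expect_false(any(is.nan(r$se)))
  ## the deep start has few consistent replicates at this scale
  expect_true(is.logical(r$reliable))
})
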