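test_that("score and information reproduce printed pairwise statistics", {
  ## two arms of 72 with 35 and 59 successes
  st <- pair_statistics(72, 35, 72, 59)
  expect_equal(st$z, -12)
  expect_equal(st$v, 8.160, tolerance = 1e-4)
  ## single centre of the four-arm example
  st <- pair_statistics(41, 35, 39, 25)
  expect_equal(st$z, 4.25)
  expect_equal(st$v, 3.75, tolerance = 2e-3)
  ## four-centre stratified totals at the elimination analysis
  h <- fixture_table5()
  d <- select_comparison_data(h, c(1, 2), option = 2)
  st <- pair_statistics(d$n_i, d$s_i, d$n_j, d$s_j)
  expect_equal(round(st$z, 2), 14.38)
  expect_equal(round(st$v, 2), 16.28)
  ## equal arms, equal successes
  expect_equal(pair_statistics(20, 7, 20, 7)$z, 0)
})

test_that("pair statistics are antisymmetric with common information", {
  set.seed(41)
  for (r in 1:25) {
    nc <- sample(1:4, 1)
    ni <- sample(0:40, nc, replace = TRUE)
    nj <- sample(0:40, nc, replace = TRUE)
    if (sum(ni + nj) == 0) ni[1] <- 5
    si <- vapply(ni, function(n) if (n > 0) sample(0:n, 1) else 0L, 0L)
    sj <- vapply(nj, function(n) if (n > 0) sample(0:n, 1) else 0L, 0L)
    a <- pair_statistics(ni, si, nj, sj)
    b <- pair_statistics(nj, sj, ni, si)
    expect_equal(a$z, -b$z)
    expect_equal(a$v, b$v)
  }
})

test_that("information is nondecreasing along nested cumulative data", {
  set.seed(42)
  for (r in 1:10) {
    K <- 8
    n1 <- cumsum(sample(5:20, K, TRUE)); n2 <- cumsum(sample(5:20, K, TRUE))
    s1 <- cumsum(c(sample(0:diff(c(0, n1))[1], 1),
                   vapply(diff(n1), function(d) sample(0:d, 1), 0L)))
    s2 <- cumsum(c(sample(0:diff(c(0, n2))[1], 1),
                   vapply(diff(n2), function(d) sample(0:d, 1), 0L)))
    v <- vapply(seq_len(K), function(k)
      pair_statistics(n1[k], s1[k], n2[k], s2[k])$v, 0)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("small-sample information satisfies the n/(n-1) identity", {
  av <- adjusted_information(9, 8, 9, 4)
  expect_equal(av$v_prime, 18 / 17, tolerance = 1e-12)
  expect_equal(pair_statistics(9, 8, 9, 4)$v, 1)
  set.seed(43)
  for (r in 1:20) {
    ni <- sample(1:30, 1); nj <- sample(1:30, 1)
    si <- sample(0:ni, 1); sj <- sample(0:nj, 1)
    n <- ni + nj
    expect_equal(adjusted_information(ni, si, nj, sj)$v_prime,
                 pair_statistics(ni, si, nj, sj)$v * n / (n - 1),
                 tolerance = 1e-12)
  }
  ## all-success stratum carries no information
  expect_equal(adjusted_information(10, 10, 8, 8)$v_prime, 0)
  ## degenerate single-patient stratum contributes zero
  expect_equal(adjusted_information(1, 1, 0, 0)$v_prime, 0)
})

test_that("count validation rejects impossible inputs", {
  expect_error(pair_statistics(10, 11, 10, 2), "0 <= successes")
  expect_error(pair_statistics(10, -1, 10, 2), "0 <= successes")
  expect_error(pair_statistics(0, 0, 0, 0), "at least one stratum")
})

test_that("pairwise classification matches the four-arm decision rule", {
  b4 <- design_preset("four_arm_sepsis")$boundary
  ## minimal first-interim elimination: 23 of 36 versus 0 of 36
  st <- pair_statistics(36, 23, 36, 0)
  expect_equal(classify_pair(st$z, st$v, b4), "i_better")
  st <- pair_statistics(36, 22, 36, 0)
  expect_equal(classify_pair(st$z, st$v, b4), "continue")
  ## no-difference interval opens only beyond a/b_inner
  expect_equal(classify_pair(0, 30, b4), "no_difference")
  expect_equal(classify_pair(0, 4.44, b4), "continue")
  ## mirror property under arm exchange
  set.seed(44)
  for (r in 1:50) {
    z <- stats::runif(1, -25, 25); v <- stats::runif(1, 0.1, 60)
    d1 <- classify_pair(z, v, b4); d2 <- classify_pair(-z, v, b4)
    mirror <- c(i_better = "j_better", j_better = "i_better",
                no_difference = "no_difference", continue = "continue")
    expect_equal(d2, unname(mirror[d1]))
  }
  ## no information, no decision
  expect_equal(classify_pair(0, 0, b4), "continue")
})

test_that("boundary geometry reproduces the design constants", {
  g2 <- boundary_geometry(design_preset("two_arm_tri")$boundary)
  expect_equal(g2$v_meet, 88.8380, tolerance = 1e-5)
  g4 <- boundary_geometry(design_preset("four_arm_sepsis")$boundary)
  expect_equal(g4$v_nodiff_min, 29.356, tolerance = 1e-4)
  ## no-difference cannot be declared during the first six interim analyses
  expect_gt(g4$v_nodiff_min, 6 * 4.40337)
  ## v_meet is linear in the intercept
  b <- pairwise_boundary(2, 0.1, 0.5, type = "one_sided")
  b2 <- pairwise_boundary(4, 0.1, 0.5, type = "one_sided")
  expect_equal(boundary_geometry(b2)$v_meet, 2 * boundary_geometry(b)$v_meet)
  expect_error(pairwise_boundary(2, 0.3, 0.3), "b_inner")
})

test_that("information increments translate to the published sample sizes", {
  expect_equal(implied_sample_increment(4.40337, 0.40, 0.50), 35.58,
               tolerance = 1e-3)
  expect_equal(implied_sample_increment(4.40337, 0.50, 0.60), 35.58,
               tolerance = 1e-3)
  expect_equal(implied_sample_increment(2 * 4.40337, 0.40, 0.50),
               2 * implied_sample_increment(4.40337, 0.40, 0.50))
  expect_error(implied_sample_increment(4.4, 0, 0))
})
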