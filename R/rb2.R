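## ---- reverse-simulation Rao-Blackwell estimation (RB2) ----------------
##
## The unbiased estimate theta_hat_1 = Z_1/V_1 from the first interim
## analysis is replaced by its conditional expectation given the terminal
## sufficient statistics. The conditional distribution is sampled by
## "reverse simulation": working backwards from each arm's final counts,
## the successes at interim k are drawn as hypergeometric observations
## (n_k responses drawn from the n_{k+1} responses of which S_{k+1} are
## successes), independently per arm and stratum; sample paths on which the
## trial would not have continued to the observed stopping pattern are
## deleted.

#' Anchor points and consistency requirements for reverse simulation
#'
#' Builds everything a reverse simulation needs from an observed trial
#' history: each arm's anchor interim (the analysis whose observed counts
#' seed the back-sampling: `min(last_interim, start_interim)`), the fixed
#' patient schedule at all earlier interims, and the per-interim
#' requirements that a back-filled path must satisfy to be consistent with
#' the real trial:
#'
#' * an interim that was the last for both arms of a pair uses the real
#'   data and never fails;
#' * at the interim an arm was eliminated, a replicate must reproduce every
#'   "better than" conclusion the real data reached against that arm, and
#'   must not find it better or worse than arms that did not defeat it;
#' * at earlier interims no pair may cross an elimination boundary, and the
#'   set of arms that in fact continued must not be declared jointly no
#'   different (which would have stopped the trial);
#' * for the one-sided two-arm design, the path must stay strictly inside
#'   the continuation region before the final analysis.
#'
#' The real trial's conclusions are recomputed from the observed counts by
#' replaying the interim decision rule, so loaded histories need no stored
#' decision log.
#'
#' @param history A `trial_history`.
#' @param start_interim The interim analysis from which back-sampling
#'   starts; defaults to the trial's final analysis `K`. Pairwise analyses
#'   restricted to data collected while both arms were in contention
#'   (Option 2) use `min(last_interim[i], last_interim[j])`.
#' @return An object of class `reverse_start_spec`.
#' @export
reverse_start_spec <- function(history, start_interim = NULL) {
  stopifnot(inherits(history, "trial_history"))
  m <- if (is.null(start_interim)) history$K else as.integer(start_interim)
  if (m < 1L || m > history$K) stop("'start_interim' outside 1..K")
  design <- history$design
  last <- history$last_interim
  anchors <- pmin(last, m)
  reqs <- vector("list", max(m - 1L, 0L))
  if (m > 1L) for (k in seq_len(m - 1L)) {
    active <- which(last >= k)
    res <- .interim_decide(
      matrix(history$n[, , k], history$n_arms, history$n_strata),
      matrix(history$S[, , k], history$n_arms, history$n_strata),
      active, design$boundary)
    ## real "w found better than l" conclusions at interim k
    winners <- c(res$pairs[1L, res$code == 1L], res$pairs[2L, res$code == 2L])
    losers  <- c(res$pairs[2L, res$code == 1L], res$pairs[1L, res$code == 2L])
    pairs <- res$pairs
    type <- character(ncol(pairs)); winner <- integer(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      li <- last[i] == k; lj <- last[j] == k
      if (li && lj) {
        type[q] <- "skip"
      } else if (li || lj) {
        e <- if (li) i else j; o <- if (li) j else i
        beat <- any(winners == o & losers == e)
        if (beat) { type[q] <- "reproduce"; winner[q] <- o }
        else type[q] <- "no_bw"
      } else type[q] <- "no_bw"
    }
    reqs[[k]] <- list(pairs = pairs, type = type, winner = winner,
                      continuing = which(last > k))
  }
  structure(list(design = design, n_arms = history$n_arms,
                 n_strata = history$n_strata, start = m,
                 anchors = anchors, last = last,
                 n_sched = history$n, S_obs = history$S, reqs = reqs),
            class = "reverse_start_spec")
}

#' Back-fill earlier interim analyses by hypergeometric sampling
#'
#' For each arm and stratum independently, starting from the observed
#' counts at the arm's anchor interim, draws the cumulative successes at
#' interim `k` given those at `k + 1` as a hypergeometric observation: the
#' number of successes among `n_k` responses drawn without replacement from
#' the `n_{k+1}` responses of which `S_{k+1}` are successes. No consistency
#' filtering is applied here; see [consistency_mask()].
#'
#' @param spec A [reverse_start_spec()].
#' @param n_sims Number of replicate paths.
#' @return A `replicate_batch`: list with `S`, a
#'   `[n_sims, arm, stratum, interim]` array of cumulative successes
#'   (columns at and above an arm's anchor hold the observed values), and
#'   the generating `spec`.
#' @export
reverse_fill <- function(spec, n_sims) {
  stopifnot(inherits(spec, "reverse_start_spec"), n_sims >= 1)
  m <- spec$start
  S <- array(NA_real_, c(n_sims, spec$n_arms, spec$n_strata, m))
  for (i in seq_len(spec$n_arms)) {
    a <- spec$anchors[i]
    for (c in seq_len(spec$n_strata)) {
      S[, i, c, a] <- spec$S_obs[i, c, a]
      if (a > 1L) for (k in seq(a - 1L, 1L)) {
        up_n <- spec$n_sched[i, c, k + 1L]
        dn_n <- spec$n_sched[i, c, k]
        if (dn_n > up_n) stop("patient schedule decreases between interims")
        s_up <- S[, i, c, k + 1L]
        S[, i, c, k] <- stats::rhyper(n_sims, m = s_up, n = up_n - s_up,
                                      k = dn_n)
      }
    }
  }
  structure(list(S = S, spec = spec, n_sims = n_sims),
            class = "replicate_batch")
}

## stratified pairwise totals for one interim, vectorised over replicates
.batch_zv <- function(batch, i, j, k) {
  spec <- batch$spec
  zt <- 0; vt <- 0
  for (c in seq_len(spec$n_strata)) {
    zv <- .zv(spec$n_sched[i, c, k], batch$S[, i, c, k],
              spec$n_sched[j, c, k], batch$S[, j, c, k])
    zt <- zt + zv$z; vt <- vt + zv$v
  }
  list(z = zt, v = vt)
}

#' Which reverse-simulated paths are consistent with the observed trial?
#'
#' Applies the deletion rules encoded in the [reverse_start_spec()] at every
#' interim analysis before the start interim, using the plain information
#' `V` throughout (the small-sample variant enters estimation only).
#'
#' @param batch A `replicate_batch` from [reverse_fill()].
#' @return Logical vector of length `n_sims`; `TRUE` marks complete
#'   (consistent) replicates.
#' @export
consistency_mask <- function(batch) {
  stopifnot(inherits(batch, "replicate_batch"))
  spec <- batch$spec
  rule <- spec$design$boundary
  ok <- rep(TRUE, batch$n_sims)
  m <- spec$start
  if (m == 1L) return(ok)
  one_sided <- rule$type == "one_sided"
  for (k in seq_len(m - 1L)) {
    rq <- spec$reqs[[k]]
    np <- ncol(rq$pairs)
    nd_mask <- vector("list", np)
    for (q in seq_len(np)) {
      if (rq$type[q] == "skip") next
      i <- rq$pairs[1L, q]; j <- rq$pairs[2L, q]
      zv <- .batch_zv(batch, i, j, k)
      up <- rule$a + rule$b_outer * zv$v
      if (one_sided) {
        lo <- -rule$a + rule$b_inner * zv$v
        ok <- ok & zv$z > lo & zv$z < up
        next
      }
      i_bet <- zv$z >= up
      j_bet <- zv$z <= -up
      if (rq$type[q] == "reproduce") {
        ok <- ok & (if (rq$winner[q] == i) i_bet else j_bet)
      } else {
        ok <- ok & !i_bet & !j_bet
      }
      if (i %in% rq$continuing && j %in% rq$continuing) {
        half <- rule$b_inner * zv$v - rule$a
        nd_mask[[q]] <- half > 0 & zv$z > -half & zv$z < half
      }
    }
    ## a path on which all arms that in fact continued would have been
    ## declared jointly no different would have stopped the trial here
    if (!one_sided && length(rq$continuing) >= 2L) {
      nds <- Filter(Negate(is.null), nd_mask)
      if (length(nds)) {
        all_nd <- Reduce(`&`, nds)
        ok <- ok & !all_nd
      }
    }
  }
  ok
}

## per-replicate first-interim estimate components for a pair:
## numerator sum_c Z_c1, denominator sum_c V_c1 (plain) or sum_c V'_c1
.batch_theta1 <- function(batch, i, j, stratified) {
  spec <- batch$spec
  zt <- 0; dt <- 0
  for (c in seq_len(spec$n_strata)) {
    ni <- spec$n_sched[i, c, 1L]; nj <- spec$n_sched[j, c, 1L]
    si <- batch$S[, i, c, 1L]; sj <- batch$S[, j, c, 1L]
    zv <- .zv(ni, si, nj, sj)
    zt <- zt + zv$z
    dt <- dt + if (stratified) .vprime(ni, si, nj, sj) else zv$v
  }
  list(z1 = zt, d1 = dt)
}

#' Reverse-simulation Rao-Blackwell estimates after an elimination trial
#'
#' For each requested pairwise comparison, reconstructs replicate first
#' interim analyses from the terminal sufficient statistics
#' ([reverse_fill()]), deletes paths inconsistent with the observed
#' stopping pattern ([consistency_mask()]), and over the remaining paths
#' averages the first-interim estimate to obtain the Rao-Blackwellised
#' point estimate, with standard error
#' `sqrt(mean(1/V_1) - var(theta_hat_1 | data))` and a normal-theory
#' confidence interval. In the stratified case the estimate and SE use the
#' small-sample information [adjusted_information()] in the denominator;
#' consistency checking always uses the plain information.
#'
#' Under Option 2 each pair's reverse simulation starts from the last
#' interim at which both arms were present, so pairs sharing a start
#' interim share one replicate set; under Option 1 a single reverse
#' simulation from the final analysis serves all pairs. A trial (or pair)
#' whose start is the first interim analysis needs no conditioning: the
#' estimate is exactly `Z_1/V_1` with SE `1/sqrt(V_1)`.
#'
#' @param history A `trial_history`.
#' @param pairs Two-column matrix of arm index pairs; default all pairs.
#' @param option 1 (all data on each arm) or 2 (restrict to joint
#'   contention); see [select_comparison_data()].
#' @param n_sims Reverse simulations per start interim.
#' @param seed Optional integer seed (one stream; chunks consume it
#'   sequentially).
#' @param stratified Use the small-sample information in estimation;
#'   defaults to `TRUE` when the history has more than one stratum.
#' @param min_complete Reliability threshold: estimates based on fewer
#'   consistent replicates are flagged (`reliable = FALSE`).
#' @param chunk_size Replicates are generated and filtered in chunks of
#'   this size to bound memory.
#' @param z_crit Normal quantile for confidence intervals.
#' @return Data frame of class `rb2_result`, one row per pair: point
#'   estimate `theta_tilde`, `se`, `ci_lo`, `ci_hi`, replicate accounting
#'   (`n_sims`, `n_complete`, `prop_complete`, `reliable`), the moment
#'   components `mean_inv_v1` and `var_theta1`, unbiased success-probability
#'   estimates `p_i_hat`, `p_j_hat`, and the `start_interim` used. A
#'   negative SE radicand yields `se = NA` (reported, never silent).
#' @examples
#' \donttest{
#' h <- fixture_table5()
#' rb2_estimate(h, pairs = rbind(c(1, 2)), option = 2, n_sims = 20000,
#'              seed = 1)
#' }
#' @export
rb2_estimate <- function(history, pairs = NULL, option = 2L, n_sims = 1e5,
                         seed = NULL, stratified = NULL,
                         min_complete = 1000L, chunk_size = 1e5,
                         z_crit = 1.96) {
  stopifnot(inherits(history, "trial_history"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stratified)) stratified <- history$n_strata > 1L
  if (is.null(pairs))
    pairs <- t(utils::combn(history$n_arms, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  option <- as.integer(option)
  starts <- if (option == 2L)
    pmin(history$last_interim[pairs[, 1L]], history$last_interim[pairs[, 2L]])
  else rep(history$K, nrow(pairs))
  out <- vector("list", nrow(pairs))
  for (m in sort(unique(starts))) {
    idx <- which(starts == m)
    spec <- reverse_start_spec(history, m)
    npair <- length(idx)
    if (m == 1L) {
      ## conditioning on the first interim analysis is vacuous: the
      ## estimate is taken directly from the observed data
      for (qq in seq_len(npair)) {
        i <- pairs[idx[qq], 1L]; j <- pairs[idx[qq], 2L]
        b1 <- structure(list(S = array(history$S[, , 1L],
                                       c(1L, history$n_arms,
                                         history$n_strata, 1L)),
                             spec = spec, n_sims = 1L),
                        class = "replicate_batch")
        comp <- .batch_theta1(b1, i, j, stratified)
        if (comp$d1 <= 0)
          stop("no information at the first interim analysis for pair ",
               i, "-", j)
        th <- comp$z1 / comp$d1
        se <- sqrt(1 / comp$d1)
        out[[idx[qq]]] <- data.frame(
          i = i, j = j, theta_tilde = th, se = se,
          ci_lo = th - z_crit * se, ci_hi = th + z_crit * se,
          n_sims = n_sims, n_complete = n_sims, prop_complete = 1,
          reliable = TRUE, mean_inv_v1 = 1 / comp$d1, var_theta1 = 0,
          n_degenerate = 0L,
          p_i_hat = sum(history$S[i, , 1L]) / sum(history$n[i, , 1L]),
          p_j_hat = sum(history$S[j, , 1L]) / sum(history$n[j, , 1L]),
          start_interim = 1L)
      }
      next
    }
    n_done <- 0; n_complete <- 0
    s_th <- s_th2 <- s_inv <- rep(0, npair)
    n_degen <- rep(0L, npair)
    s_p <- matrix(0, npair, 2L)
    while (n_done < n_sims) {
      nb <- min(chunk_size, n_sims - n_done)
      batch <- reverse_fill(spec, nb)
      keep <- consistency_mask(batch)
      n_done <- n_done + nb
      n_complete <- n_complete + sum(keep)
      if (!any(keep)) next
      for (qq in seq_len(npair)) {
        i <- pairs[idx[qq], 1L]; j <- pairs[idx[qq], 2L]
        comp <- .batch_theta1(batch, i, j, stratified)
        z1 <- comp$z1[keep]; d1 <- comp$d1[keep]
        pos <- d1 > 0
        n_degen[qq] <- n_degen[qq] + sum(!pos)
        th <- z1[pos] / d1[pos]
        s_th[qq] <- s_th[qq] + sum(th)
        s_th2[qq] <- s_th2[qq] + sum(th^2)
        s_inv[qq] <- s_inv[qq] + sum(1 / d1[pos])
        n1i <- sum(spec$n_sched[i, , 1L]); n1j <- sum(spec$n_sched[j, , 1L])
        si1 <- sum(matrix(batch$S[keep, i, , 1L], nrow = sum(keep)))
        sj1 <- sum(matrix(batch$S[keep, j, , 1L], nrow = sum(keep)))
        s_p[qq, ] <- s_p[qq, ] + c(si1 / n1i, sj1 / n1j)
      }
    }
    if (n_complete == 0L)
      stop(sprintf(
        "no consistent reverse simulations for start interim %d (of %d)",
        m, n_sims))
    for (qq in seq_len(npair)) {
      nc_eff <- n_complete - n_degen[qq]
      mean_th <- s_th[qq] / nc_eff
      var_th <- if (nc_eff > 1L)
        (s_th2[qq] - nc_eff * mean_th^2) / (nc_eff - 1L) else 0
      var_th <- max(var_th, 0)
      mean_inv <- s_inv[qq] / nc_eff
      rad <- mean_inv - var_th
      se <- if (rad > 0) sqrt(rad) else NA_real_
      out[[idx[qq]]] <- data.frame(
        i = pairs[idx[qq], 1L], j = pairs[idx[qq], 2L],
        theta_tilde = mean_th, se = se,
        ci_lo = mean_th - z_crit * se, ci_hi = mean_th + z_crit * se,
        n_sims = n_sims, n_complete = n_complete,
        prop_complete = n_complete / n_sims,
        reliable = n_complete >= min_complete,
        mean_inv_v1 = mean_inv, var_theta1 = var_th,
        n_degenerate = n_degen[qq],
        p_i_hat = s_p[qq, 1L] / n_complete,
        p_j_hat = s_p[qq, 2L] / n_complete,
        start_interim = m)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("rb2_result", "data.frame")
  res
}
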