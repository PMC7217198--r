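#' Monte Carlo operating characteristics of a design
#'
#' Simulates the design repeatedly under a scenario of success
#' probabilities and tallies, per arm, the proportion of runs in which it
#' is declared sole winner and in which it is eliminated; the expected
#' total sample size; the proportion of runs ending with a named set of
#' arms declared jointly no different (`nod_set`); and the proportion of
#' runs left unresolved at the patient cap or interim limit. Monte Carlo
#' standard errors `sqrt(p(1-p)/nreps)` accompany all proportions.
#'
#' For a one-sided two-arm design, `win` for arm 1 is the upper-boundary
#' crossing proportion and `win` for arm 2 the lower ("no better")
#' proportion.
#'
#' @param design A [design_spec()].
#' @param p Success probabilities (vector per arm, or matrix arm x stratum
#'   for centre-specific rates in multi-arm designs).
#' @param nreps Number of simulated trials.
#' @param seed Optional integer seed.
#' @param nod_set Arm indices whose joint no-difference declaration defines
#'   the `nod` event; default: the arms sharing the maximum success
#'   probability, when at least two do (otherwise `nod` is `NA`).
#' @return An object of class `opchar`: list with `E_n`, `win`, `elim`,
#'   `nod`, `still`, their MC standard errors, `nreps` and the scenario.
#' @examples
#' \donttest{
#' operating_characteristics(design_preset("four_arm_simple"),
#'                           p = c(0.6, 0.4, 0.4, 0.4), nreps = 2000,
#'                           seed = 1)
#' }
#' @export
operating_characteristics <- function(design, p, nreps, seed = NULL,
                                      nod_set = NULL) {
  stopifnot(inherits(design, "design_spec"), nreps >= 1)
  if (!is.null(seed)) set.seed(seed)
  na <- design$n_arms
  pvec <- if (is.matrix(p)) rowMeans(p) else p
  if (is.null(nod_set)) {
    best <- which(abs(pvec - max(pvec)) < 1e-12)
    nod_set <- if (length(best) >= 2L) best else NULL
  }
  two_arm <- design$boundary$type == "one_sided"
  win <- numeric(na); elim <- numeric(na)
  nod <- 0L; still <- 0L; tot_n <- 0
  for (r in seq_len(nreps)) {
    h <- if (two_arm) simulate_two_arm_trial(design, p[1L], p[2L])
         else simulate_multiarm_trial(design, p)
    oc <- h$outcome
    tot_n <- tot_n + oc$total_n
    if (two_arm) {
      if (identical(oc$boundary, "upper")) win[1L] <- win[1L] + 1
      if (identical(oc$boundary, "lower")) win[2L] <- win[2L] + 1
      if (is.na(oc$boundary)) still <- still + 1L
    } else {
      if (oc$kind == "sole_winner") win[oc$winners] <- win[oc$winners] + 1
      elim[!is.na(h$eliminated_by)] <- elim[!is.na(h$eliminated_by)] + 1
      if (!is.null(nod_set) && oc$kind == "joint_winners" &&
          setequal(oc$winners, nod_set)) nod <- nod + 1L
      if (oc$kind == "unresolved") still <- still + 1L
    }
  }
  prop <- function(x) x / nreps
  mcse <- function(pr) sqrt(pr * (1 - pr) / nreps)
  win <- prop(win); elim <- prop(elim)
  nodp <- if (is.null(nod_set) && !two_arm) NA_real_ else prop(nod)
  stillp <- prop(still)
  structure(list(E_n = tot_n / nreps, win = win, elim = elim, nod = nodp,
                 still = stillp,
                 se_win = mcse(win), se_elim = mcse(elim),
                 se_nod = if (is.na(nodp)) NA_real_ else mcse(nodp),
                 se_still = mcse(stillp),
                 nreps = nreps, p = p, nod_set = nod_set,
                 design = design$name),
            class = "opchar")
}

#' @export
print.opchar <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d runs%s):\n", x$nreps,
              if (is.null(x$design)) "" else paste0(", ", x$design)))
  cat(sprintf("  E(n) = %.0f\n", x$E_n))
  cat("  win :", paste(sprintf("%.4f", x$win), collapse = " "), "\n")
  cat("  elim:", paste(sprintf("%.4f", x$elim), collapse = " "), "\n")
  cat(sprintf("  nod = %s, still = %.4f\n",
              ifelse(is.na(x$nod), "NA", sprintf("%.4f", x$nod)), x$still))
  invisible(x)
}

#' @export
as.data.frame.opchar <- function(x, ...) {
  data.frame(arm = seq_along(x$win), win = x$win, se_win = x$se_win,
             elim = x$elim, se_elim = x$se_elim, E_n = x$E_n, nod = x$nod,
             still = x$still, nreps = x$nreps)
}

#' Sampling properties of post-trial estimators
#'
#' Simulates trials under a known scenario, applies the chosen estimator to
#' every pairwise comparison of every run, and aggregates bias, spread,
#' reported standard errors and confidence-interval coverage against the
#' true log-odds ratios. Reverse-simulation analyses whose number of
#' consistent replicates falls below `min_complete` are considered
#' unreliable, dropped from the aggregates, and counted in `n_excluded`.
#'
#' @param design A [design_spec()]; the analytic method (`"rb1"`) requires
#'   a one-sided two-arm design.
#' @param p Vector of success probabilities per arm.
#' @param method `"naive"`, `"rb1"` or `"rb2"`.
#' @param nreps Number of simulated trials.
#' @param n_reverse Reverse simulations per analysis (`"rb2"`).
#' @param seed Optional integer seed.
#' @param option Comparison-data policy for multi-arm analyses; Option 1
#'   lets one reverse-simulation set serve every pairwise comparison.
#' @param min_complete Reliability threshold on consistent replicates.
#' @return Data frame, one row per pair: true `theta`, mean and SD of the
#'   estimates, mean reported SE, mean CI endpoints, empirical `coverage`,
#'   `nreps_used` and `n_excluded`.
#' @export
evaluate_estimators <- function(design, p, method = c("naive", "rb1", "rb2"),
                                nreps, n_reverse = 5e4, seed = NULL,
                                option = 1L, min_complete = 1000L) {
  method <- match.arg(method)
  stopifnot(inherits(design, "design_spec"), length(p) == design$n_arms)
  if (!is.null(seed)) set.seed(seed)
  two_arm <- design$boundary$type == "one_sided"
  if (method == "rb1" && !two_arm)
    stop("the analytic Rao-Blackwell method is two-arm only")
  pairs <- t(utils::combn(design$n_arms, 2L))
  np <- nrow(pairs)
  theta_true <- log(p[pairs[, 1L]] * (1 - p[pairs[, 2L]])) -
    log(p[pairs[, 2L]] * (1 - p[pairs[, 1L]]))
  est <- se <- lo <- hi <- matrix(NA_real_, nreps, np)
  excluded <- matrix(FALSE, nreps, np)
  for (r in seq_len(nreps)) {
    h <- if (two_arm) simulate_two_arm_trial(design, p[1L], p[2L])
         else simulate_multiarm_trial(design, p)
    if (method == "rb2") {
      rb <- rb2_estimate(h, pairs = pairs, option = option,
                         n_sims = n_reverse, min_complete = min_complete)
      est[r, ] <- rb$theta_tilde; se[r, ] <- rb$se
      lo[r, ] <- rb$ci_lo; hi[r, ] <- rb$ci_hi
      excluded[r, ] <- !rb$reliable
    } else for (q in seq_len(np)) {
      if (method == "naive") {
        ne <- naive_analysis(h, pairs[q, ], option = option)
        est[r, q] <- ne$theta_hat; se[r, q] <- ne$se
        lo[r, q] <- ne$ci_lo; hi[r, q] <- ne$ci_hi
      } else {
        r1 <- rb1_estimate(h$outcome$z_star, h$K, design,
                           v_star = h$outcome$v_star)
        est[r, q] <- r1$theta_tilde; se[r, q] <- r1$se
        lo[r, q] <- r1$ci_lo; hi[r, q] <- r1$ci_hi
      }
    }
  }
  out <- lapply(seq_len(np), function(q) {
    use <- !excluded[, q] & !is.na(est[, q])
    cov_use <- use & !is.na(se[, q])
    data.frame(i = pairs[q, 1L], j = pairs[q, 2L], theta = theta_true[q],
               mean_estimate = mean(est[use, q]),
               sd_estimate = stats::sd(est[use, q]),
               mean_se = mean(se[cov_use, q]),
               mean_ci_lo = mean(lo[cov_use, q]),
               mean_ci_hi = mean(hi[cov_use, q]),
               coverage = mean(lo[cov_use, q] <= theta_true[q] &
                                 hi[cov_use, q] >= theta_true[q]),
               nreps_used = sum(use), n_excluded = sum(excluded[, q]))
  })
  res <- do.call(rbind, out)
  attr(res, "method") <- method
  res
}
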