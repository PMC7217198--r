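#' Naive (unadjusted) log-odds-ratio estimate
#'
#' The estimate that ignores the sequential design: `theta_hat = Z*/V*` with
#' `SE = 1/sqrt(V*)` and 95% confidence interval `theta_hat +/- 1.96 SE`,
#' where `Z*` and `V*` are the score and information in the final dataset.
#' Following a trial with data-dependent stopping this estimate is biased
#' away from zero and its intervals undercover; it is the reference point
#' for the Rao-Blackwell corrections.
#'
#' @param z_star,v_star Terminal score and information; `v_star > 0`.
#' @param z_crit Normal quantile for the confidence interval. The
#'   conventional 1.96 is the default and is kept fixed for worked-example
#'   fidelity; pass e.g. `qnorm(0.995)` for other levels.
#' @return An object of class `naive_estimate`: list with `theta_hat`, `se`,
#'   `ci_lo`, `ci_hi`, `z_star`, `v_star`.
#' @examples
#' naive_estimate(-12.0, 8.160)   # theta -1.471, CI (-2.157, -0.784)
#' @export
naive_estimate <- function(z_star, v_star, z_crit = 1.96) {
  stopifnot(length(z_star) == 1L, length(v_star) == 1L)
  if (!is.finite(v_star) || v_star <= 0)
    stop("'v_star' must be positive")
  theta <- z_star / v_star
  se <- 1 / sqrt(v_star)
  structure(list(theta_hat = theta, se = se,
                 ci_lo = theta - z_crit * se, ci_hi = theta + z_crit * se,
                 z_star = z_star, v_star = v_star),
            class = "naive_estimate")
}

#' @export
print.naive_estimate <- function(x, ...) {
  cat(sprintf("Naive estimate: theta = %.3f, SE = %.3f, 95%% CI (%.3f, %.3f)\n",
              x$theta_hat, x$se, x$ci_lo, x$ci_hi))
  cat(sprintf("  from Z* = %.4f, V* = %.4f\n", x$z_star, x$v_star))
  invisible(x)
}

#' Select the terminal data for one pairwise comparison
#'
#' Two policies for which data enter a pairwise analysis after a multi-arm
#' elimination trial:
#'
#' * Option 1 uses all data available on each arm, i.e. each arm's counts at
#'   its own last interim analysis (arms eliminated earlier contribute less).
#' * Option 2 restricts to patients randomised while both arms were still in
#'   contention: both arms' counts at interim `min(last_i, last_j)`. This
#'   protects the comparison against temporal drift in the recruited
#'   population or in trial conduct.
#'
#' @param history A `trial_history`.
#' @param pair Length-2 vector of arm indices `(i, j)`.
#' @param option 1 or 2.
#' @return List with per-stratum counts `n_i`, `s_i`, `n_j`, `s_j`, and the
#'   interim indices used (`interim_i`, `interim_j`; equal under Option 2).
#' @export
select_comparison_data <- function(history, pair, option = 2L) {
  stopifnot(inherits(history, "trial_history"), length(pair) == 2L)
  i <- pair[1L]; j <- pair[2L]
  if (any(pair < 1L) || any(pair > history$n_arms) || i == j)
    stop("invalid arm pair")
  option <- as.integer(option)
  if (!option %in% c(1L, 2L)) stop("'option' must be 1 or 2")
  if (option == 2L) {
    k <- min(history$last_interim[i], history$last_interim[j])
    ki <- kj <- k
  } else {
    ki <- history$last_interim[i]; kj <- history$last_interim[j]
  }
  list(n_i = history$n[i, , ki], s_i = history$S[i, , ki],
       n_j = history$n[j, , kj], s_j = history$S[j, , kj],
       interim_i = ki, interim_j = kj)
}

#' Naive analysis of one pairwise comparison from a trial history
#'
#' Convenience wrapper: selects the comparison data by the chosen option,
#' computes the stratified score and information, and forms the naive
#' estimate.
#'
#' @inheritParams select_comparison_data
#' @param z_crit Normal quantile for the confidence interval.
#' @return A `naive_estimate`.
#' @export
naive_analysis <- function(history, pair, option = 2L, z_crit = 1.96) {
  d <- select_comparison_data(history, pair, option)
  st <- pair_statistics(d$n_i, d$s_i, d$n_j, d$s_j)
  naive_estimate(st$z, st$v, z_crit = z_crit)
}
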