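## ---- analytic two-arm Rao-Blackwell estimation (RB1) ------------------
##
## For the one-sided triangular test the conditional mean and variance of
## the first-interim score Z_1, given the stopping analysis K and terminal
## score, are available analytically from group-sequential stopping
## sub-distributions. Under the canonical model the score increments are
## independent normal with variance equal to the information increment (and
## mean theta * dV; the likelihood factor exp(theta z - theta^2 V / 2)
## cancels in the conditional ratio, so everything is evaluated at
## theta = 0). Writing l_k, u_k for the continuation limits, the survivor
## function
##   S(t) = P(Z_1 > l_1 + t | K = n, Z_n in (z_n - dz, z_n + dz))
## is a ratio of continuation probabilities for the design with first
## continuation region (l_1 + t, u_1), and
##   E(Z_1 - l_1 | .)   = integral of S(t) dt over (0, u_1 - l_1),
##   E((Z_1 - l_1)^2|.) = 2 * integral of t S(t) dt.
## The continuation probabilities are evaluated by backward recursion of
## the conditional crossing probability on a z-grid (Armitage-type
## numerical integration).

#' Numerical configuration for the analytic Rao-Blackwell method
#'
#' @param delta_z Half-width of the pinched final continuation region
#'   around the terminal score (dimensionless score units).
#' @param t_grid_points Number of intervals of the t-grid on
#'   `(0, u_1 - l_1)` used for the survivor-function integrals.
#' @param z_grid_points Grid points per continuation interval in the
#'   backward recursion.
#' @param v_schedule `"realized"`: equal information spacing scaled to the
#'   observed terminal information, `V_i = i V*/K` (the default, which
#'   reproduces the published two-arm worked analyses); `"nominal"`: the
#'   design's anticipated schedule `V_i = i * nominal_v_increment`.
#' @return List of class `rb1_config`.
#' @export
rb1_config <- function(delta_z = 0.01, t_grid_points = 100L,
                       z_grid_points = 400L,
                       v_schedule = c("realized", "nominal")) {
  stopifnot(delta_z > 0, t_grid_points >= 2, z_grid_points >= 10)
  list(delta_z = delta_z, t_grid_points = as.integer(t_grid_points),
       z_grid_points = as.integer(z_grid_points),
       v_schedule = match.arg(v_schedule))
}

## trapezoid quadrature weights for an arbitrary grid
.trapw <- function(x) {
  h <- diff(x)
  w <- numeric(length(x))
  w[1L] <- h[1L] / 2
  w[length(x)] <- h[length(h)] / 2
  if (length(x) > 2L)
    w[2L:(length(x) - 1L)] <- (h[-1L] + h[-length(h)]) / 2
  w
}

## Backward pass: g(z) on a grid over the first continuation interval,
## where g(z) = P(stay in (l_k, u_k) for k = 2..n-1 and Z_n in the pinched
## region | Z_1 = z), theta = 0. Returns list(z1_grid, g).
.rb1_backward <- function(lower, upper, v, z_n, delta_z, ngrid) {
  n <- length(v)
  stopifnot(n >= 2L)
  dv <- diff(c(0, v))
  zk <- seq(lower[n - 1L], upper[n - 1L], length.out = ngrid)
  g <- stats::pnorm((z_n + delta_z - zk) / sqrt(dv[n])) -
       stats::pnorm((z_n - delta_z - zk) / sqrt(dv[n]))
  if (n >= 3L) for (k in seq(n - 2L, 1L)) {
    zprev <- seq(lower[k], upper[k], length.out = ngrid)
    w <- .trapw(zk)
    kern <- outer(zprev, zk, function(x, y)
      stats::dnorm(y - x, 0, sqrt(dv[k + 1L])))
    g <- as.vector(kern %*% (w * g))
    zk <- zprev
  }
  list(z1 = zk, g = g)
}

#' Probability of continuing to a pinched final analysis
#'
#' Evaluates, at `theta = 0` under the canonical group-sequential model,
#' the probability that the score path stays strictly inside the
#' continuation regions `(l_k, u_k)` for `k < n` -- with the first region
#' shrunk to `(l_1 + t, u_1)` -- and lands in the pinched final region
#' `(z_n - delta_z, z_n + delta_z)` at information `v[n]`.
#'
#' @param lower,upper Continuation limits at each of the `n` analyses.
#' @param v Strictly increasing information values `V_1, ..., V_n`.
#' @param z_n Terminal score.
#' @param t Shift of the first lower limit, in `[0, u_1 - l_1]`.
#' @param config An [rb1_config()].
#' @return A probability.
#' @export
continuation_mass <- function(lower, upper, v, z_n, t = 0,
                              config = rb1_config()) {
  n <- length(v)
  stopifnot(length(lower) == n, length(upper) == n, all(diff(v) > 0))
  if (t < 0 || t > upper[1L] - lower[1L])
    stop("'t' must lie in [0, u_1 - l_1]")
  if (n == 1L)
    return(max(0, stats::pnorm((min(z_n + config$delta_z, upper[1L])) /
                                 sqrt(v[1L])) -
                  stats::pnorm((max(z_n - config$delta_z, lower[1L] + t)) /
                                 sqrt(v[1L]))))
  bk <- .rb1_backward(lower, upper, v, z_n, config$delta_z,
                      config$z_grid_points)
  f1 <- stats::dnorm(bk$z1, 0, sqrt(v[1L])) * bk$g
  keep <- bk$z1 >= lower[1L] + t
  if (sum(keep) < 2L) return(0)
  sum(.trapw(bk$z1[keep]) * f1[keep])
}

## boundary limits for the first n analyses of a one-sided design,
## given the information schedule
.rb1_limits <- function(boundary, v) {
  stopifnot(boundary$type == "one_sided")
  list(lower = -boundary$a + boundary$b_inner * v,
       upper = boundary$a + boundary$b_outer * v)
}

.rb1_vschedule <- function(n, design, v_star, config) {
  if (config$v_schedule == "realized") {
    if (is.null(v_star) || !is.finite(v_star))
      stop("realized information schedule requires 'v_star'")
    seq_len(n) * v_star / n
  } else seq_len(n) * design$nominal_v_increment
}

#' Conditional survivor function of the first-interim score
#'
#' `S(t) = P(Z_1 > l_1 + t | K = n, Z_n near z_n)`, the ratio of pinched
#' continuation probabilities with and without the first lower limit
#' shifted by `t`. Evaluated on a uniform t-grid over `(0, u_1 - l_1)`;
#' `S(0) = 1` and `S` is nonincreasing. One backward pass provides the
#' whole curve.
#'
#' @param z_n Terminal score at the stopping analysis.
#' @param n Stopping interim index, `>= 2`.
#' @param design A one-sided [design_spec()].
#' @param config An [rb1_config()].
#' @param v_star Realised terminal information (used when
#'   `config$v_schedule = "realized"`).
#' @return Data frame with columns `t` and `s`.
#' @export
survivor_curve <- function(z_n, n, design, config = rb1_config(),
                           v_star = NULL) {
  stopifnot(n >= 2L)
  v <- .rb1_vschedule(n, design, v_star, config)
  lim <- .rb1_limits(design$boundary, v)
  bk <- .rb1_backward(lim$lower, lim$upper, v, z_n, config$delta_z,
                      config$z_grid_points)
  f1 <- stats::dnorm(bk$z1, 0, sqrt(v[1L])) * bk$g
  ## dense cumulative integral from above for arbitrary lower limits
  zz <- seq(lim$lower[1L], lim$upper[1L], length.out = 4000L)
  ff <- stats::approx(bk$z1, f1, zz, rule = 2L)$y
  seg <- diff(zz) * (ff[-1L] + ff[-length(ff)]) / 2
  upint <- rev(cumsum(rev(c(seg, 0))))      # integral from zz[i] to u_1
  if (upint[1L] <= 0)
    stop("degenerate terminal point: zero continuation mass")
  tg <- seq(0, lim$upper[1L] - lim$lower[1L],
            length.out = config$t_grid_points + 1L)
  s <- stats::approx(zz, upint, lim$lower[1L] + tg, rule = 2L)$y / upint[1L]
  data.frame(t = tg, s = pmin(pmax(s, 0), 1))
}

#' Analytic Rao-Blackwell estimate for a two-arm triangular trial
#'
#' Computes the conditional mean and variance of the first-interim score
#' given the stopping analysis and terminal score via the survivor-function
#' integrals, and returns the Rao-Blackwellised log-odds-ratio estimate
#' `theta_tilde = E(Z_1 | .) / V_1` with standard error
#' `sqrt(1/V_1 - var(Z_1 | .) / V_1^2)` and normal-theory confidence
#' interval. A trial stopped at the first analysis needs no adjustment:
#' `theta_tilde = z_1 / V_1` with SE `1/sqrt(V_1)`.
#'
#' @param z_n Terminal score.
#' @param n Stopping interim index.
#' @param design A one-sided [design_spec()], e.g.
#'   `design_preset("two_arm_tri")`.
#' @param config An [rb1_config()].
#' @param v_star Realised terminal information; required for the default
#'   realised information schedule.
#' @param z_crit Normal quantile for the confidence interval.
#' @return List of class `rb1_estimate`: `theta_tilde`, `se`, `ci_lo`,
#'   `ci_hi`, and the conditional moments `e_z1`, `var_z1`, plus the
#'   information schedule used.
#' @examples
#' d <- design_preset("two_arm_tri")
#' rb1_estimate(-12.0, 2, d, v_star = 8.160)   # theta ~ -1.463
#' @export
rb1_estimate <- function(z_n, n, design, config = rb1_config(),
                         v_star = NULL, z_crit = 1.96) {
  stopifnot(inherits(design, "design_spec"),
            design$boundary$type == "one_sided", n >= 1L)
  v <- .rb1_vschedule(n, design, v_star, config)
  if (n == 1L) {
    th <- z_n / v[1L]; se <- 1 / sqrt(v[1L])
    return(structure(list(theta_tilde = th, se = se,
                          ci_lo = th - z_crit * se, ci_hi = th + z_crit * se,
                          e_z1 = z_n, var_z1 = 0, v = v),
                     class = "rb1_estimate"))
  }
  sc <- survivor_curve(z_n, n, design, config, v_star = v_star)
  lim <- .rb1_limits(design$boundary, v)
  w <- .trapw(sc$t)
  e_shift <- sum(w * sc$s)                 # E(Z_1 - l_1 | .)
  e_shift2 <- 2 * sum(w * sc$t * sc$s)     # E((Z_1 - l_1)^2 | .)
  var_z1 <- e_shift2 - e_shift^2
  e_z1 <- lim$lower[1L] + e_shift
  th <- e_z1 / v[1L]
  rad <- 1 / v[1L] - var_z1 / v[1L]^2
  se <- if (rad > 0) sqrt(rad) else NA_real_
  structure(list(theta_tilde = th, se = se,
                 ci_lo = th - z_crit * se, ci_hi = th + z_crit * se,
                 e_z1 = e_z1, var_z1 = var_z1, v = v),
            class = "rb1_estimate")
}

#' @export
print.rb1_estimate <- function(x, ...) {
  cat(sprintf("Analytic RB estimate: theta = %.3f, SE = %.3f, 95%% CI (%.3f, %.3f)\n",
              x$theta_tilde, x$se, x$ci_lo, x$ci_hi))
  invisible(x)
}
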