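## ---- interim decision logic -------------------------------------------

## Minimal fast path: decide eliminations / stopping at one interim.
## cum_n, cum_S: [n_arms, n_strata] cumulative counts; active: arm indices.
## Returns integer decision codes per active pair plus the consequences.
.interim_decide <- function(cum_n, cum_S, active, rule) {
  m <- length(active)
  pairs <- utils::combn(active, 2L)
  np <- ncol(pairs)
  code <- integer(np)
  for (q in seq_len(np)) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    zv <- .zv(cum_n[i, ], cum_S[i, ], cum_n[j, ], cum_S[j, ])
    code[q] <- .classify_code(sum(zv$z), sum(zv$v), rule)
  }
  ## every arm found worse than any other is eliminated (simultaneous
  ## evaluation on the same interim data)
  losers <- unique(c(pairs[2L, code == 1L], pairs[1L, code == 2L]))
  remaining <- setdiff(active, losers)
  stop <- FALSE; kind <- NA_character_; winners <- integer(0)
  if (length(remaining) <= 1L) {
    stop <- TRUE
    if (length(remaining) == 1L) {
      kind <- "sole_winner"; winners <- remaining
    } else kind <- "unresolved"   # pathological elimination cycle
  } else {
    ## joint winners: every pair among the remaining arms concludes
    ## no difference (re-evaluated on this interim's data)
    keep <- pairs[1L, ] %in% remaining & pairs[2L, ] %in% remaining
    if (all(code[keep] == 3L)) {
      stop <- TRUE; kind <- "joint_winners"; winners <- remaining
    }
  }
  list(pairs = pairs, code = code, eliminated = losers,
       remaining = remaining, stop = stop, kind = kind, winners = winners)
}

#' Apply the interim decision rule to cumulative data
#'
#' Computes the (stratified) score and information for every pair of active
#' arms, classifies each against the design's boundaries, eliminates every
#' arm found worse than at least one other active arm, and determines whether
#' the trial stops: with a sole winner when one arm remains, or with joint
#' winners when every remaining pair is declared no different. A pure,
#' deterministic function; the reverse-simulation consistency filter replays
#' it on observed data.
#'
#' @param cum_n,cum_s Matrices `[arm, stratum]` of cumulative patients and
#'   successes at this interim.
#' @param active Indices of arms still in the trial.
#' @param design A [design_spec()].
#' @return List with a `decisions` data frame (`i`, `j`, `decision`),
#'   `eliminated`, `remaining`, `stop`, `kind` and `winners`.
#' @export
apply_interim <- function(cum_n, cum_s, active, design) {
  stopifnot(inherits(design, "design_spec"))
  cum_n <- as.matrix(cum_n); cum_s <- as.matrix(cum_s)
  if (length(active) < 1L) stop("no active arms")
  res <- .interim_decide(cum_n, cum_s, active, design$boundary)
  labels <- if (design$boundary$type == "one_sided")
    .DECISION_LABELS_1S else .DECISION_LABELS
  list(decisions = data.frame(i = res$pairs[1L, ], j = res$pairs[2L, ],
                              decision = labels[res$code + 1L]),
       eliminated = res$eliminated, remaining = res$remaining,
       stop = res$stop, kind = res$kind, winners = res$winners)
}

## ---- trial history container ------------------------------------------

.new_trial_history <- function(design, n_arr, s_arr, last_interim,
                               eliminated_by, K, outcome, decisions) {
  structure(list(design = design, n_arms = design$n_arms,
                 n_strata = design$n_strata, K = K,
                 n = n_arr, S = s_arr,
                 last_interim = last_interim, eliminated_by = eliminated_by,
                 outcome = outcome, decisions = decisions),
            class = "trial_history")
}

#' @export
print.trial_history <- function(x, ...) {
  cat(sprintf("Trial history: %d arms, %d stratum/strata, %d interim analyses\n",
              x$n_arms, x$n_strata, x$K))
  cat(sprintf("  outcome: %s%s (%s), total n = %d\n", x$outcome$kind,
              if (length(x$outcome$winners))
                paste0(" [", paste(x$outcome$winners, collapse = ","), "]")
              else "",
              x$outcome$stop_reason, x$outcome$total_n))
  for (i in seq_len(x$n_arms)) {
    el <- if (is.na(x$eliminated_by[i])) ""
          else sprintf(", eliminated by arm %d", x$eliminated_by[i])
    cat(sprintf("  arm %d: n = %d, S = %d, last interim %d%s\n", i,
                sum(x$n[i, , x$last_interim[i]]),
                sum(x$S[i, , x$last_interim[i]]), x$last_interim[i], el))
  }
  invisible(x)
}

## cumulative counts of one arm at one interim (matrix row over strata)
.arm_counts <- function(history, arm, interim) {
  list(n = history$n[arm, , interim], s = history$S[arm, , interim])
}

#' Score/information path for one pairwise comparison
#'
#' @param history A `trial_history`.
#' @param i,j Arm indices.
#' @return Data frame with one row per interim analysis at which both arms
#'   were present: `interim`, `z`, `v` (stratified totals).
#' @export
pair_path <- function(history, i, j) {
  kmax <- min(history$last_interim[i], history$last_interim[j])
  out <- data.frame(interim = seq_len(kmax), z = NA_real_, v = NA_real_)
  for (k in seq_len(kmax)) {
    zv <- .zv(history$n[i, , k], history$S[i, , k],
              history$n[j, , k], history$S[j, , k])
    out$z[k] <- sum(zv$z); out$v[k] <- sum(zv$v)
  }
  out
}

## ---- forward simulation: multi-arm ------------------------------------

#' Simulate one multi-arm elimination trial
#'
#' Runs the design forward: at each interim analysis every remaining arm
#' accrues `per_arm_increment` new binomial responses (split at random
#' across strata with equal probabilities when the design is stratified),
#' all pairwise comparisons are evaluated, arms found worse than any other
#' are eliminated, and the trial stops with a sole winner, with joint
#' winners, or when a further interim analysis would exceed the patient cap
#' or the interim limit (outcome `unresolved`).
#'
#' @param design A [design_spec()] with a symmetric pairwise rule.
#' @param p Success probabilities: a vector of length `n_arms` (used in all
#'   strata) or a matrix `[n_arms, n_strata]` for centre-specific rates.
#' @param seed Optional integer seed.
#' @return A `trial_history`.
#' @examples
#' h <- simulate_multiarm_trial(design_preset("four_arm_simple"),
#'                              p = c(0.6, 0.4, 0.4, 0.4), seed = 1)
#' h$outcome$kind
#' @export
simulate_multiarm_trial <- function(design, p, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(seed)) set.seed(seed)
  nc <- design$n_strata
  na <- design$n_arms
  if (is.matrix(p)) {
    stopifnot(nrow(p) == na, ncol(p) == nc)
  } else {
    stopifnot(length(p) == na)
    p <- matrix(p, nrow = na, ncol = nc)
  }
  if (any(p < 0) || any(p > 1)) stop("success probabilities must lie in [0, 1]")
  inc <- design$per_arm_increment
  kmax <- design$max_interims
  rule <- design$boundary
  n_arr <- array(NA_real_, c(na, nc, kmax))
  s_arr <- array(NA_real_, c(na, nc, kmax))
  cum_n <- matrix(0, na, nc); cum_s <- matrix(0, na, nc)
  active <- seq_len(na)
  last_interim <- integer(na); eliminated_by <- rep(NA_integer_, na)
  dec_k <- list(); total <- 0L; K <- 0L
  outcome <- NULL
  for (k in seq_len(kmax)) {
    if (total + length(active) * inc > design$max_total_n) {
      outcome <- list(kind = "unresolved", winners = active,
                      total_n = total, stop_reason = "cap_reached")
      break
    }
    for (i in active) {
      if (nc == 1L) {
        alloc <- inc
        sinc <- stats::rbinom(1L, inc, p[i, 1L])
      } else {
        alloc <- as.vector(stats::rmultinom(1L, inc, rep(1, nc)))
        sinc <- stats::rbinom(nc, alloc, p[i, ])
      }
      cum_n[i, ] <- cum_n[i, ] + alloc
      cum_s[i, ] <- cum_s[i, ] + sinc
      n_arr[i, , k] <- cum_n[i, ]; s_arr[i, , k] <- cum_s[i, ]
    }
    total <- total + length(active) * inc
    K <- k
    last_interim[active] <- k
    res <- .interim_decide(cum_n, cum_s, active, rule)
    if (length(res$eliminated)) {
      for (el in res$eliminated) {
        winner_over <- c(res$pairs[1L, res$code == 1L & res$pairs[2L, ] == el],
                         res$pairs[2L, res$code == 2L & res$pairs[1L, ] == el])
        eliminated_by[el] <- winner_over[1L]
      }
    }
    dec_k[[k]] <- cbind(interim = k, i = res$pairs[1L, ],
                        j = res$pairs[2L, ], code = res$code)
    active <- res$remaining
    if (res$stop) {
      outcome <- list(kind = res$kind, winners = res$winners,
                      total_n = total, stop_reason = "boundary")
      break
    }
  }
  if (is.null(outcome))
    outcome <- list(kind = "unresolved", winners = active, total_n = total,
                    stop_reason = "max_interims")
  decisions <- as.data.frame(do.call(rbind, dec_k))
  decisions$decision <- .DECISION_LABELS[decisions$code + 1L]
  decisions$code <- NULL
  .new_trial_history(design, n_arr[, , seq_len(max(K, 1L)), drop = FALSE],
                     s_arr[, , seq_len(max(K, 1L)), drop = FALSE],
                     last_interim, eliminated_by, K, outcome, decisions)
}

## ---- forward simulation: two-arm triangular test -----------------------

#' Simulate one two-arm triangular trial
#'
#' The one-sided triangular test: at each interim both arms accrue
#' `per_arm_increment` responses and the trial stops when
#' `Z >= a + b_outer V` (arm 1 better; upper boundary) or
#' `Z <= -a + b_inner V` (arm 1 no better; lower boundary), both inclusive.
#' Interim analyses continue past the planned `max_interims` up to
#' `max_interims + extension_interims` while no boundary has been reached
#' (covering realised information increments that fall short of the
#' anticipated value); a trial with no crossing at the final permitted
#' analysis ends `unresolved`.
#'
#' @param design A [design_spec()] with a one-sided boundary, e.g.
#'   `design_preset("two_arm_tri")`.
#' @param p1,p2 Success probabilities on the experimental and control arm.
#' @param seed Optional integer seed.
#' @return A `trial_history`; `outcome$boundary` is `"upper"`, `"lower"` or
#'   `NA`, and `outcome$z_star`, `outcome$v_star` hold the terminal
#'   statistics.
#' @export
simulate_two_arm_trial <- function(design, p1, p2, seed = NULL) {
  stopifnot(inherits(design, "design_spec"), design$n_arms == 2L,
            design$boundary$type == "one_sided",
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (!is.null(seed)) set.seed(seed)
  inc <- design$per_arm_increment
  kmax <- design$max_interims + design$extension_interims
  n_arr <- array(NA_real_, c(2L, 1L, kmax))
  s_arr <- array(NA_real_, c(2L, 1L, kmax))
  s1 <- 0L; s2 <- 0L
  boundary <- NA_character_; K <- kmax
  z <- v <- numeric(kmax)
  for (k in seq_len(kmax)) {
    s1 <- s1 + stats::rbinom(1L, inc, p1)
    s2 <- s2 + stats::rbinom(1L, inc, p2)
    n_arr[, 1L, k] <- k * inc
    s_arr[, 1L, k] <- c(s1, s2)
    zv <- .zv(k * inc, s1, k * inc, s2)
    z[k] <- zv$z; v[k] <- zv$v
    code <- .classify_code(zv$z, zv$v, design$boundary)
    if (code != 0L) {
      ## if past the boundary meeting point both conditions can hold;
      ## the upper (efficacy) boundary takes precedence (code 1 checked first)
      boundary <- if (code == 1L) "upper" else "lower"
      K <- k
      break
    }
  }
  kind <- switch(boundary, upper = "sole_winner", lower = "no_better",
                 "unresolved")
  outcome <- list(kind = kind,
                  winners = if (identical(kind, "sole_winner")) 1L else integer(0),
                  total_n = 2L * inc * K,
                  stop_reason = if (is.na(boundary)) "max_interims" else "boundary",
                  boundary = boundary, z_star = z[K], v_star = v[K],
                  z_path = z[seq_len(K)], v_path = v[seq_len(K)])
  .new_trial_history(design, n_arr[, , seq_len(K), drop = FALSE],
                     s_arr[, , seq_len(K), drop = FALSE],
                     last_interim = c(K, K),
                     eliminated_by = rep(NA_integer_, 2L),
                     K = K, outcome = outcome,
                     decisions = data.frame(interim = seq_len(K), i = 1L,
                                            j = 2L,
                                            decision = .DECISION_LABELS_1S[
                                              c(rep(1L, K - 1L),
                                                if (is.na(boundary)) 1L
                                                else if (boundary == "upper") 2L
                                                else 3L)]))
}
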