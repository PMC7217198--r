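#' Straight-line stopping boundaries for one pairwise comparison
#'
#' A pairwise decision rule in the (V, Z) plane of the efficient score `Z`
#' and Fisher information `V` for a log-odds ratio. Two rule types are
#' supported:
#'
#' * `"symmetric"` (double triangular): at information `v`, treatment i is
#'   declared better than j if `z >= a + b_outer * v`, worse if
#'   `z <= -(a + b_outer * v)`, and the two are declared no different if `z`
#'   falls strictly inside the open interval
#'   `(a - b_inner * v, -a + b_inner * v)`, which is nonempty only once
#'   `v > a / b_inner`.
#' * `"one_sided"` (triangular): only an upper efficacy line
#'   `z >= a + b_outer * v` and a rising lower "no better" line
#'   `z <= -a + b_inner * v` exist; there is no middle stopping region.
#'
#' Elimination/stopping comparisons are inclusive (`>=`, `<=`); the
#' no-difference interval is open. The continuation region is the set of
#' `(v, z)` for which no conclusion is reached.
#'
#' @param a Boundary intercept, positive.
#' @param b_outer Slope of the elimination (efficacy) boundaries, `>= 0`.
#' @param b_inner Slope of the inner (no-difference / no-better) boundaries;
#'   must exceed `b_outer` so the boundaries eventually meet.
#' @param type `"symmetric"` or `"one_sided"`.
#' @return An object of class `pairwise_boundary`.
#' @examples
#' b <- pairwise_boundary(10.90266, 0.12380, 0.37140)
#' classify_pair(11.5, 3.913, b)
#' boundary_geometry(pairwise_boundary(10.93898, 0.123134, 0.369402,
#'                                     type = "one_sided"))
#' @export
pairwise_boundary <- function(a, b_outer, b_inner,
                              type = c("symmetric", "one_sided")) {
  type <- match.arg(type)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b_outer), length(b_outer) == 1L, b_outer >= 0,
            is.numeric(b_inner), length(b_inner) == 1L)
  if (b_inner <= b_outer)
    stop("'b_inner' must exceed 'b_outer' (boundaries must meet)")
  structure(list(a = a, b_outer = b_outer, b_inner = b_inner, type = type),
            class = "pairwise_boundary")
}

#' @export
print.pairwise_boundary <- function(x, ...) {
  cat(sprintf("Pairwise boundary (%s):\n", x$type))
  cat(sprintf("  upper: Z >= %g + %g V\n", x$a, x$b_outer))
  if (x$type == "symmetric") {
    cat(sprintf("  lower: Z <= -%g - %g V\n", x$a, x$b_outer))
    cat(sprintf("  no difference: Z in (%g - %g V, -%g + %g V), open\n",
                x$a, x$b_inner, x$a, x$b_inner))
  } else {
    cat(sprintf("  lower: Z <= -%g + %g V\n", x$a, x$b_inner))
  }
  invisible(x)
}

## integer decision codes used by the hot loops:
##   0 continue, 1 i_better, 2 j_better / j_no_better, 3 no_difference
.DECISION_LABELS <- c("continue", "i_better", "j_better", "no_difference")
.DECISION_LABELS_1S <- c("continue", "i_better", "j_no_better")

## vectorised over z and v
.classify_code <- function(z, v, rule) {
  up <- rule$a + rule$b_outer * v
  if (rule$type == "one_sided") {
    lo <- -rule$a + rule$b_inner * v
    code <- integer(length(z))
    code[z >= up] <- 1L
    code[code == 0L & z <= lo] <- 2L
    return(code)
  }
  code <- integer(length(z))
  code[z >= up] <- 1L
  code[code == 0L & z <= -up] <- 2L
  half <- rule$b_inner * v - rule$a      # no-difference interval is (-half, half)
  nd <- code == 0L & half > 0 & z > -half & z < half
  code[nd] <- 3L
  code
}

#' Classify one pairwise comparison against its stopping boundaries
#'
#' @param z Efficient score(s) for the comparison of i versus j.
#' @param v Fisher information value(s), `>= 0`.
#' @param rule A [pairwise_boundary()].
#' @return Character vector: for symmetric rules one of `"i_better"`,
#'   `"j_better"`, `"no_difference"`, `"continue"`; for one-sided rules one
#'   of `"i_better"`, `"j_no_better"`, `"continue"`.
#' @seealso [pair_statistics()] to compute `z` and `v` from counts.
#' @export
classify_pair <- function(z, v, rule) {
  stopifnot(inherits(rule, "pairwise_boundary"), all(v >= 0))
  code <- .classify_code(z, v, rule)
  labels <- if (rule$type == "one_sided") .DECISION_LABELS_1S else .DECISION_LABELS
  labels[code + 1L]
}

#' Geometry of a pairwise boundary
#'
#' `v_meet` is the information at which the upper elimination line and the
#' inner (no-better / no-difference) line meet, closing the continuation
#' triangle: `2a / (b_inner - b_outer)`. For symmetric rules,
#' `v_nodiff_min = a / b_inner` is the smallest information at which the
#' no-difference interval is nonempty.
#'
#' @param rule A [pairwise_boundary()].
#' @return List with `v_meet` and, for symmetric rules, `v_nodiff_min`.
#' @export
boundary_geometry <- function(rule) {
  stopifnot(inherits(rule, "pairwise_boundary"))
  v_meet <- 2 * rule$a / (rule$b_inner - rule$b_outer)
  if (rule$type == "symmetric")
    list(v_meet = v_meet, v_nodiff_min = rule$a / rule$b_inner)
  else
    list(v_meet = v_meet)
}

#' Per-arm sample size implied by a target information increment
#'
#' For two equal arms of `n` patients each with success probabilities
#' `p_i`, `p_j`, the information for the log-odds ratio is approximately
#' `V = (n / 2) * pbar * (1 - pbar)` with `pbar = (p_i + p_j) / 2`. This
#' solves for `n` given the desired per-interim increment in `V`.
#'
#' @param v_increment Target information increment per interim analysis.
#' @param p_i,p_j Anticipated success probabilities, strictly in (0, 1).
#' @return Patients per arm per interim (not rounded).
#' @examples
#' implied_sample_increment(4.40337, 0.40, 0.50)  # 35.58, rounded up to 36
#' @export
implied_sample_increment <- function(v_increment, p_i, p_j) {
  stopifnot(v_increment > 0, p_i > 0, p_i < 1, p_j > 0, p_j < 1)
  pbar <- (p_i + p_j) / 2
  2 * v_increment / (pbar * (1 - pbar))
}
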