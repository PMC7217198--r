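## Elementwise score and information for grouped binary data.
## All arguments may be vectors (strata, replicates, interims); recycled.
## Z = (n_j S_i - n_i S_j) / (n_i + n_j)
## V = n_i n_j (S_i + S_j) (n_i + n_j - S_i - S_j) / (n_i + n_j)^3
## Strata with n_i + n_j = 0 contribute (0, 0).
.zv <- function(n_i, s_i, n_j, s_j) {
  ## double arithmetic: integer counts overflow in n_i n_j S (n - S)
  n_i <- as.numeric(n_i); s_i <- as.numeric(s_i)
  n_j <- as.numeric(n_j); s_j <- as.numeric(s_j)
  n <- n_i + n_j
  s <- s_i + s_j
  z <- (n_j * s_i - n_i * s_j) / n
  v <- n_i * n_j * s * (n - s) / n^3
  ## empty strata (n = 0) contribute (0, 0); keep full recycled length
  bad <- !is.finite(z)
  if (any(bad)) z[bad] <- 0
  bad <- !is.finite(v)
  if (any(bad)) v[bad] <- 0
  list(z = z, v = v)
}

## small-sample information variant used in stratified Rao-Blackwell
## estimation: V' = V * n / (n - 1); strata with n <= 1 contribute 0.
.vprime <- function(n_i, s_i, n_j, s_j) {
  n_i <- as.numeric(n_i); s_i <- as.numeric(s_i)
  n_j <- as.numeric(n_j); s_j <- as.numeric(s_j)
  n <- n_i + n_j
  s <- s_i + s_j
  vp <- n_i * n_j * s * (n - s) / (n^2 * (n - 1))
  bad <- !is.finite(vp)          # degenerate strata with n <= 1
  if (any(bad)) vp[bad] <- 0
  vp
}

.check_counts <- function(n, s, what) {
  if (any(n < 0) || any(s < 0) || any(s > n))
    stop("invalid counts for ", what, ": need 0 <= successes <= n")
}

#' Efficient score and Fisher information for one pairwise comparison
#'
#' Computes, per stratum and in total, the efficient score `Z` and Fisher
#' information `V` for the log-odds ratio comparing treatment i with
#' treatment j from cumulative counts of patients and successes. With several
#' strata the statistics are computed separately within each stratum and then
#' summed. Strata with no patients on either arm contribute zero to both.
#'
#' `Z` is antisymmetric in the two arms and equals the difference in success
#' proportions scaled by `n_i n_j / (n_i + n_j)`; `V` is the pooled success
#' rate times the pooled failure rate times the same factor.
#'
#' @param n_i,s_i Patients and successes on treatment i, one value per
#'   stratum.
#' @param n_j,s_j Patients and successes on treatment j.
#' @return An object of class `pair_stats`: list with totals `z`, `v` and
#'   per-stratum components `z_c`, `v_c`.
#' @examples
#' pair_statistics(72, 35, 72, 59)   # z = -12, v = 8.160
#' @export
pair_statistics <- function(n_i, s_i, n_j, s_j) {
  stopifnot(length(n_i) == length(s_i), length(n_j) == length(s_j),
            length(n_i) == length(n_j))
  .check_counts(n_i, s_i, "arm i")
  .check_counts(n_j, s_j, "arm j")
  if (sum(n_i + n_j) == 0)
    stop("at least one stratum must contain patients")
  zv <- .zv(n_i, s_i, n_j, s_j)
  structure(list(z = sum(zv$z), v = sum(zv$v), z_c = zv$z, v_c = zv$v,
                 n_strata = length(n_i)),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("Pair statistics: Z = %.4f, V = %.4f (%d stratum/strata)\n",
              x$z, x$v, x$n_strata))
  invisible(x)
}

#' Small-sample adjusted information
#'
#' The information variant `V' = n_i n_j S (n - S) / (n^2 (n - 1))` with
#' `n = n_i + n_j`, `S = s_i + s_j`, equal to `V * n / (n - 1)`. It is used in
#' place of `V` in the denominator of stratified Rao-Blackwell estimates,
#' where within-stratum first-interim samples are small: `E(Z)` is closer to
#' `theta * V'` than to `theta * V`, and `var(Z)` closer to `V'`. Strata with
#' `n_i + n_j <= 1` are degenerate and contribute zero.
#'
#' @inheritParams pair_statistics
#' @return List with total `v_prime` and per-stratum `v_prime_c`.
#' @examples
#' adjusted_information(9, 8, 9, 4)   # v = 1, v' = 18/17
#' @export
adjusted_information <- function(n_i, s_i, n_j, s_j) {
  .check_counts(n_i, s_i, "arm i")
  .check_counts(n_j, s_j, "arm j")
  vp <- .vprime(n_i, s_i, n_j, s_j)
  list(v_prime = sum(vp), v_prime_c = vp)
}
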