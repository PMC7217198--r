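#' Worked-example dataset: one realisation of the four-arm stratified design
#'
#' The complete interim history of a single simulated run of the four-arm
#' elimination design conducted at four centres: cumulative patients and
#' successes per arm, centre and interim analysis. Arm 2 was eliminated by
#' arm 1 at the fourth interim analysis, arm 4 by arm 1 at the fifth, and
#' arm 1 defeated arm 3 at the twelfth, ending the trial with arm 1 the sole
#' winner after 1188 patients. This dataset drives the worked examples for
#' comparison-data selection, naive analysis and reverse-simulation
#' Rao-Blackwell estimation.
#'
#' @return A `trial_history` with 4 arms, 4 strata and `K = 12`.
#' @examples
#' h <- fixture_table5()
#' d <- select_comparison_data(h, c(1, 2), option = 2)
#' pair_statistics(d$n_i, d$s_i, d$n_j, d$s_j)  # Z = 14.38, V = 16.28
#' @export
fixture_table5 <- function() {
  n <- list(
    ## arm 1, centres 1-4, interims 1-12
    list(c(11, 18, 30, 41, 50, 57, 65, 76, 86, 92, 98, 103),
         c(10, 16, 25, 33, 41, 49, 60, 71, 82, 88, 96, 100),
         c(7, 17, 25, 35, 44, 55, 63, 68, 72, 83, 90, 104),
         c(8, 21, 28, 35, 45, 55, 64, 73, 84, 97, 112, 125)),
    ## arm 2, interims 1-4
    list(c(12, 24, 31, 39), c(6, 13, 25, 30),
         c(7, 16, 22, 35), c(11, 19, 30, 40)),
    ## arm 3, interims 1-12
    list(c(9, 19, 29, 39, 48, 57, 67, 74, 85, 91, 102, 111),
         c(7, 15, 24, 32, 40, 49, 57, 64, 72, 79, 88, 94),
         c(9, 17, 25, 32, 42, 50, 58, 68, 76, 90, 101, 111),
         c(11, 21, 30, 41, 50, 60, 70, 82, 91, 100, 105, 116)),
    ## arm 4, interims 1-5
    list(c(9, 15, 23, 36, 50), c(9, 20, 32, 42, 47),
         c(11, 19, 28, 32, 40), c(7, 18, 25, 34, 43)))
  s <- list(
    list(c(10, 17, 27, 35, 41, 46, 53, 63, 69, 74, 78, 83),
         c(10, 14, 20, 25, 30, 34, 40, 47, 58, 61, 65, 67),
         c(6, 11, 16, 20, 26, 32, 36, 41, 43, 49, 55, 64),
         c(4, 13, 15, 20, 27, 34, 38, 45, 48, 53, 62, 68)),
    list(c(9, 17, 19, 25), c(4, 8, 12, 13),
         c(5, 11, 15, 21), c(1, 5, 8, 11)),
    list(c(8, 15, 21, 27, 33, 41, 49, 56, 65, 70, 79, 85),
         c(5, 9, 15, 22, 28, 31, 33, 38, 44, 47, 52, 56),
         c(3, 5, 8, 13, 21, 27, 31, 37, 41, 48, 55, 60),
         c(4, 7, 12, 15, 18, 23, 26, 34, 37, 42, 44, 45)),
    list(c(5, 11, 17, 24, 32), c(6, 11, 16, 24, 27),
         c(5, 8, 12, 14, 18), c(3, 9, 10, 13, 16)))
  last <- c(12L, 4L, 12L, 5L)
  K <- 12L
  n_arr <- array(NA_real_, c(4L, 4L, K))
  s_arr <- array(NA_real_, c(4L, 4L, K))
  for (a in 1:4)
    for (c in 1:4) {
      ks <- seq_len(last[a])
      n_arr[a, c, ks] <- n[[a]][[c]]
      s_arr[a, c, ks] <- s[[a]][[c]]
    }
  design <- design_preset("four_arm_sepsis", n_strata = 4L)
  .new_trial_history(design, n_arr, s_arr, last_interim = last,
                     eliminated_by = c(NA_integer_, 1L, 1L, 1L),
                     K = K,
                     outcome = list(kind = "sole_winner", winners = 1L,
                                    total_n = 1188L,
                                    stop_reason = "boundary"),
                     decisions = NULL)
}
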