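#' Full specification of a sequential elimination design
#'
#' Bundles the pairwise decision rule with the trial-level schedule: how many
#' arms start, how many new responses per remaining arm trigger an interim
#' analysis, the total patient cap, and the maximum number of interim
#' analyses.
#'
#' @param n_arms Number of treatment arms at the start of the trial.
#' @param boundary A [pairwise_boundary()] applied to every pairwise
#'   comparison.
#' @param per_arm_increment New patient responses per remaining arm between
#'   interim analyses.
#' @param max_total_n Cap on the total number of patients; the trial stops
#'   before any interim analysis that would exceed it.
#' @param max_interims Maximum number of interim analyses.
#' @param n_strata Number of strata (centres); when greater than 1 the score
#'   and information are computed within stratum and summed.
#' @param nominal_v_increment Anticipated information increment per interim
#'   for one pairwise comparison (used by the two-arm extension rule and as
#'   the nominal schedule for analytic estimation).
#' @param extension_interims Two-arm designs only: additional interim
#'   analyses permitted beyond `max_interims` when realised information
#'   increments fall short of `nominal_v_increment` and no boundary has been
#'   reached.
#' @param name Optional preset name carried for display and serialisation.
#' @return An object of class `design_spec`.
#' @seealso [design_preset()] for the shipped configurations.
#' @export
design_spec <- function(n_arms, boundary, per_arm_increment, max_total_n,
                        max_interims, n_strata = 1L,
                        nominal_v_increment = NA_real_,
                        extension_interims = 0L, name = NULL) {
  stopifnot(inherits(boundary, "pairwise_boundary"),
            n_arms >= 2, per_arm_increment >= 1,
            max_total_n >= n_arms * per_arm_increment,
            max_interims >= 1, n_strata >= 1)
  structure(list(name = name, n_arms = as.integer(n_arms),
                 boundary = boundary,
                 per_arm_increment = as.integer(per_arm_increment),
                 max_total_n = as.integer(max_total_n),
                 max_interims = as.integer(max_interims),
                 extension_interims = as.integer(extension_interims),
                 n_strata = as.integer(n_strata),
                 nominal_v_increment = nominal_v_increment),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Sequential elimination design%s:\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'")))
  cat(sprintf("  %d arms, %d per arm per interim, cap %d patients, max %d interims",
              x$n_arms, x$per_arm_increment, x$max_total_n, x$max_interims))
  if (x$extension_interims > 0)
    cat(sprintf(" (+%d if information lags)", x$extension_interims))
  cat(sprintf("\n  %d stratum/strata, nominal V increment %s\n",
              x$n_strata, format(x$nominal_v_increment)))
  print(x$boundary)
  invisible(x)
}

#' Shipped design configurations
#'
#' Three ready-made designs, stored as JSON under
#' `system.file("extdata", "design_presets.json", package = "seqelim")`:
#'
#' * `"four_arm_sepsis"`: four arms, double-triangular pairwise rule with
#'   `Z >= 10.90266 + 0.12380 V` etc., 36 responses per remaining arm per
#'   interim, at most 2772 patients. Calibrated so that the probability of
#'   wrongly declaring a sole winner among truly equal arms is at most 0.025
#'   and an arm inferior by an odds ratio of 1.5 is eliminated with
#'   probability at least 0.90.
#' * `"two_arm_tri"`: the one-sided triangular test extracted from the above
#'   for one experimental-versus-control comparison
#'   (`Z >= 10.93898 + 0.123134 V` / `Z <= -10.93898 + 0.369402 V`), 36 per
#'   arm per interim, 20 planned interim analyses extendable to 25; the
#'   boundaries meet at `V = 88.8380`.
#' * `"four_arm_simple"`: a smaller four-arm design (odds ratio 2.25 at 90%
#'   power), 32 per remaining arm per interim, at most 8 interim analyses and
#'   640 patients, boundaries `Z = 4.9261 + 0.2470 V` and
#'   `Z = -4.9261 + 0.7411 V`.
#'
#' @param name Preset name.
#' @param n_strata Number of strata to run the design with (the decision
#'   rules are unchanged; statistics are summed over strata).
#' @return A [design_spec()].
#' @export
design_preset <- function(name = c("four_arm_sepsis", "two_arm_tri",
                                   "four_arm_simple"),
                          n_strata = 1L) {
  name <- match.arg(name)
  path <- system.file("extdata", "design_presets.json", package = "seqelim")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)[[name]]
  design_spec(n_arms = cfg$arms,
              boundary = pairwise_boundary(cfg$a, cfg$b_outer, cfg$b_inner,
                                           type = cfg$rule_type),
              per_arm_increment = cfg$per_arm_increment,
              max_total_n = cfg$max_total_n,
              max_interims = cfg$max_interims,
              extension_interims = cfg$extension_interims,
              n_strata = n_strata,
              nominal_v_increment = cfg$nominal_v_increment,
              name = name)
}
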