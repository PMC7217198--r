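## Twelve terminal datasets from simulated runs of the two-arm triangular
## test, with the published naive-analysis columns (estimate and 95% CI)
## and the boundary crossed (1 = upper). n per arm is half the printed
## total; patients are evenly divided.
table2_cases <- function() {
  data.frame(
    case = 1:12,
    K  = c(2, 3, 4, 10, 8, 13, 9, 6, 6, 5, 5, 3),
    n  = c(144, 216, 288, 720, 576, 936, 648, 432, 432, 360, 360, 216) / 2,
    s1 = c(35, 68, 102, 284, 201, 275, 252, 120, 161, 135, 124, 82),
    s2 = c(59, 87, 118, 285, 201, 259, 222, 88, 130, 108, 92, 55),
    z_star = c(-12, -9.5, -8, -0.5, 0, 8, 15, 16, 15.5, 13.5, 16, 13.5),
    v_star = c(8.160, 10.943, 12.986, 29.833, 30.359, 57.337, 31.819,
               26.963, 23.745, 19.744, 21.600, 12.527),
    b = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
    theta_hat = c(-1.471, -0.868, -0.616, -0.017, 0.000, 0.140, 0.471,
                  0.593, 0.653, 0.684, 0.741, 1.078),
    ci_lo = c(-2.157, -1.461, -1.160, -0.376, -0.356, -0.119, 0.124,
              0.216, 0.251, 0.243, 0.319, 0.524),
    ci_hi = c(-0.784, -0.276, -0.072, 0.342, 0.356, 0.398, 0.819, 0.971,
              1.055, 1.125, 1.162, 1.631),
    rb1_theta = c(-1.463, -0.823, -0.560, 0.046, 0.051, 0.224, 0.420,
                  0.519, 0.580, 0.653, 0.655, 1.059),
    rb1_se = c(0.360, 0.325, 0.298, 0.204, 0.201, 0.166, 0.197, 0.214,
               0.226, 0.239, 0.238, 0.291),
    rb2_pct_complete = c(99.3, 89.3, 79.9, 55.7, 67.0, 17.0, 63.7, 56.0,
                         54.9, 85.7, 58.5, 95.8),
    rb2_theta = c(-1.473, -0.834, -0.567, 0.046, 0.052, 0.227, 0.424,
                  0.529, 0.584, 0.658, 0.671, 1.069),
    rb2_se = c(0.383, 0.334, 0.295, 0.158, 0.183, 0.158, 0.185, 0.213,
               0.229, 0.245, 0.243, 0.312))
}

## Trial history for a two-arm realisation given only terminal counts:
## earlier interims are filled with any monotone values (they are never
## used: reverse simulation is seeded from the terminal analysis only).
two_arm_case_history <- function(s1_star, s2_star, K,
                                 design = design_preset("two_arm_tri")) {
  inc <- design$per_arm_increment
  k <- seq_len(K)
  tab <- rbind(
    data.frame(arm = 1, stratum = 1, interim = k, cum_n = inc * k,
               cum_S = floor(s1_star * k / K)),
    data.frame(arm = 2, stratum = 1, interim = k, cum_n = inc * k,
               cum_S = floor(s2_star * k / K)))
  trial_history(design, tab)
}

## Enumerable toy design for conditional-distribution oracles: two arms,
## two patients per arm per interim, two interim analyses, loose one-sided
## boundary so that some (but not all) first-interim outcomes stop.
toy_design <- function() {
  design_spec(n_arms = 2, per_arm_increment = 2, max_total_n = 100,
              max_interims = 2,
              boundary = pairwise_boundary(0.5, 0.1, 0.6,
                                           type = "one_sided"),
              nominal_v_increment = 0.25)
}

toy_history <- function(s1_star, s2_star) {
  tab <- rbind(
    data.frame(arm = 1, stratum = 1, interim = 1:2, cum_n = c(2, 4),
               cum_S = c(min(s1_star, 2), s1_star)),
    data.frame(arm = 2, stratum = 1, interim = 1:2, cum_n = c(2, 4),
               cum_S = c(min(s2_star, 2), s2_star)))
  trial_history(toy_design(), tab)
}
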