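{
  "four_arm_sepsis": {
    "arms": 4,
    "a": 10.90266,
    "b_outer": 0.1238,
    "b_inner": 0.3714,
    "rule_type": "symmetric",
    "per_arm_increment": 36,
    "max_total_n": 2772,
    "max_interims": 40,
    "extension_interims": 0,
    "n_strata": 1,
    "nominal_v_increment": 4.40337
  },
  "two_arm_tri": {
    "arms": 2,
    "a": 10.93898,
    "b_outer": 0.123134,
    "b_inner": 0.369402,
    "rule_type": "one_sided",
    "per_arm_increment": 36,
    "max_total_n": 1800,
    "max_interims": 20,
    "extension_interims": 5,
    "n_strata": 1,
    "nominal_v_increment": 4.4419
  },
  "four_arm_simple": {
    "arms": 4,
    "a": 4.9261,
    "b_outer": 0.247,
    "b_inner": 0.7411,
    "rule_type": "symmetric",
    "per_arm_increment": 32,
    "max_total_n": 640,
    "max_interims": 8,
    "extension_interims": 0,
    "n_strata": 1,
    "nominal_v_increment": 4.0
  }
}
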