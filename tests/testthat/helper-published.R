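# Published effect-table rows (standardized effect, s.e., interval
# endpoints) used for interval-arithmetic checks.
published_rows <- data.frame(
  target = rep(c("numeracy", "numeracy", "numeracy",
                 "reading", "reading", "reading"), 2),
  treatment = rep(c("wellbeing", "depression"), each = 6),
  model = rep(c("bayesian_ridge", "two_stage", "dml"), 4),
  beta_std = c(0.0294, 0.0332, 0.0270, 0.0139, 0.0201, 0.0189,
               -0.0438, -0.0446, -0.0475, -0.0385, -0.0328, -0.0425),
  se_std = c(0.0103, 0.0143, 0.0101, 0.0115, 0.0157, 0.0124,
             0.0101, 0.0138, 0.0102, 0.0112, 0.0150, 0.0128),
  lo = c(0.0092, 0.0052, 0.0072, -0.0086, -0.0107, -0.0054,
         -0.0636, -0.0716, -0.0675, -0.0605, -0.0622, -0.0676),
  hi = c(0.0495, 0.0612, 0.0468, 0.0364, 0.0509, 0.0432,
         -0.0240, -0.0176, -0.0275, -0.0165, -0.0034, -0.0174))
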