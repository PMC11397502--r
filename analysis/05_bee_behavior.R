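#!/usr/bin/env Rscript
# Pollinator-choice analyses on the artificial bullseye discs: disc
# geometry, differential-conditioning learning curves on synthetic choice
# sequences, and binary preference tests.
# Writes results/learning_curve.csv and results/preference_tests.csv.

library(bullseye)

dir.create("results", showWarnings = FALSE)

cat(sprintf("disc designs: small %.0f%%, medium %.0f%%, large %.0f%% pigmented area\n",
            disc_area_fraction(1.2, 6), disc_area_fraction(2.4, 6),
            disc_area_fraction(3.6, 6)))

# synthetic conditioning experiment: 20 bees, 80 visits, success rising
# from near-chance to a strong preference for the rewarded disc
choices <- gen_choices(p0 = 0.55, p_final = 0.82, n_bees = 20L,
                       n_visits = 80L, seed = 1)
lc <- learning_curve(choices)
print(lc)
write.csv(lc$curve, "results/learning_curve.csv", row.names = FALSE)

# binary preference: first landings of 30 naive bees on two disc types
pref <- rbind(
  data.frame(comparison = "small vs medium", a = 7, b = 23),
  data.frame(comparison = "medium vs large", a = 14, b = 16)
)
pref$proportion <- NA_real_
pref$p_value <- NA_real_
for (i in seq_len(nrow(pref))) {
  t <- preference_test(pref$a[i], pref$b[i])
  pref$proportion[i] <- t$proportion
  pref$p_value[i] <- t$p_value
}
print(pref, row.names = FALSE)
write.csv(pref, "results/preference_tests.csv", row.names = FALSE)
cat("wrote results/learning_curve.csv and results/preference_tests.csv\n")
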