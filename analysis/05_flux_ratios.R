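#!/usr/bin/env Rscript
# Relative flux ratios: parameter-recovery curve for the PC/PDH estimator and
# the glutamine synthetase activity read-out.

library(hrmasflux)
dir.create("results", showWarnings = FALSE)

cat("== PC/PDH estimator recovery (propagation model, no back-exchange) ==\n")
grid <- seq(0.05, 0.5, by = 0.05)
est <- vapply(grid, function(r) {
  p <- propagate("glc_1_13C", flux_params(pc = r, me = 0, dilution_unlabeled = 0,
                                          scrambling = 0, glu_turnover = 1))
  flux_ratios(profile_fractions(p)[c("Glu C2", "Glu C3", "Glu C4",
                                     "Lac C2")])$pc_over_pdh
}, numeric(1))
rec <- data.frame(true_pc_over_pdh = grid, estimated = round(est, 4))
print(rec, row.names = FALSE)
cat("The estimator reads pc/(pc + pdh), slightly compressing large ratios.\n\n")

cat("== Default glucose-brain calibration ==\n")
pdef <- propagate("glc_1_13C", default_flux_params("glc_1_13C", "brain_cortex"))
fdef <- flux_ratios(profile_fractions(pdef)[c("Glu C2", "Glu C3", "Glu C4",
                                              "Lac C2")])
cat(sprintf("pc_over_pdh = %.3f  (%s)\n", fdef$pc_over_pdh,
            fdef$formulas[["pc_over_pdh"]]))
cat(sprintf("pc_over_me  = %.3f  (%s)\n\n", fdef$pc_over_me,
            fdef$formulas[["pc_over_me"]]))

cat("== GS relative activity (Gln C4 / Glu C4) ==\n")
ref <- incorporation_reference()
g <- function(r) ref$ace_brain_mean[ref$row == r]
gs <- gs_relative_activity(g("Gln C4"), g("Glu C4"))
cat(sprintf("reference acetate-brain means: ratio %.3f (compositional %.3f)\n",
            gs$ratio, gs$ratio_compositional))
cat(sprintf("a 23%% drop in Gln C4 alone lowers the ratio to %.3f (-23%%)\n",
            gs_relative_activity(0.77 * g("Gln C4"), g("Glu C4"))$ratio))
write.csv(rec, "results/pc_pdh_recovery.csv", row.names = FALSE)
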