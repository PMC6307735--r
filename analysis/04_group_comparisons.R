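#!/usr/bin/env Rscript
# FGR-vs-AGA contrasts and the HRMAS time-drift control for the seed-1 run,
# plus a multi-seed stability check of the four headline effects.

library(hrmasflux)
run_dir <- "results/run_seed1"
if (!file.exists(file.path(run_dir, "comparisons.csv"))) {
  res <- run_pipeline(run_config(seed = 1, out_dir = run_dir))
}
cmp <- read.csv(file.path(run_dir, "comparisons.csv"), check.names = FALSE)

cat("== Significant FGR-vs-AGA contrasts (two-tailed unpaired t, p < 0.05) ==\n")
sig <- cmp[cmp$significant, c("group", "tissue", "variable",
                              "percent_difference", "p_value")]
sig$percent_difference <- round(sig$percent_difference, 1)
sig$p_value <- signif(sig$p_value, 3)
print(sig, row.names = FALSE)
cat(sprintf("\n(%d contrasts tested in total; no multiple-testing correction,\n",
            nrow(cmp)))
cat("matching the source analysis -- post-correct if desired.)\n\n")

inifin <- read.csv(file.path(run_dir, "initial_final.csv"), check.names = FALSE)
cat("== Initial vs final CPMG (paired one-tailed, accumulation) ==\n")
cat(sprintf("glutamine area: %+.1f%% over the session (p = %.2g)\n\n",
            inifin$percent_difference, inifin$p_value))

cat("== Headline effects across 8 seeds (percent difference; * p < 0.05) ==\n")
heads <- data.frame(group = "ACE",
                    tissue = c("brain_cortex", "brain_cortex", "heart_apex",
                               "heart_apex"),
                    variable = c("Lac C2", "Lac C3", "Gln C4", "gpc_gpe"))
rows <- list()
for (s in 1:8) {
  r <- run_pipeline(run_config(seed = s))
  cc <- r$comparisons
  rows[[s]] <- vapply(seq_len(nrow(heads)), function(i) {
    x <- cc[cc$group == heads$group[i] & cc$tissue == heads$tissue[i] &
              cc$variable == heads$variable[i], ]
    sprintf("%+.0f%%%s", x$percent_difference, if (x$significant) "*" else "")
  }, character(1))
}
tab <- do.call(rbind, rows)
colnames(tab) <- paste(heads$tissue, heads$variable)
print(data.frame(seed = 1:8, tab, check.names = FALSE), row.names = FALSE)
cat("\nEffect directions are stable across seeds; significance at n = 6/6 is\n")
cat("marginal for the lactate contrasts, as the source p-values imply.\n")
write.csv(data.frame(seed = 1:8, tab, check.names = FALSE),
          "results/headline_stability.csv", row.names = FALSE)
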