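#!/usr/bin/env Rscript
# Step 4: rank-correlation suite for age pleiotropy.
#
# Kendall's tau-b between per-mutation median relative fecundities across
# age pairs, between the change in relative fecundity and its level at the
# earlier age (deleteriousness vs induced aging; conservatively biased
# negative under pure noise), and between day-5 fecundity and day-33
# survival effects. Run on the deleterious and aging subsets from step 3.

suppressPackageStartupMessages(library(fecage))

ds <- load_fecundity_table("results/data.csv",
                           survival_path = "results/survival.csv")
report_tab <- read.csv("results/aging_report.csv", stringsAsFactors = FALSE)

subsets <- list(all = ds$mutation_ids,
                deleterious = report_tab$mutation[report_tab$deleterious],
                aging = report_tab$mutation[report_tab$aging])
pairs <- list(c(5, 19), c(5, 33), c(19, 33))

rows <- list()
for (sn in names(subsets)) {
  sub <- subsets[[sn]]
  if (length(sub) < 3) next
  for (pr in pairs) {
    r1 <- age_pleiotropy(ds, sub, pr)
    r2 <- aging_vs_deleteriousness(ds, sub, pr)
    rows[[length(rows) + 1]] <- data.frame(
      subset = sn, comparison = sprintf("fec%d_vs_fec%d", pr[1], pr[2]),
      tau = r1$tau, p = r1$p_two_tailed, n = r1$n, method = r1$method)
    rows[[length(rows) + 1]] <- data.frame(
      subset = sn, comparison = sprintf("change%d_%d_vs_level%d",
                                        pr[1], pr[2], pr[1]),
      tau = r2$tau, p = r2$p_two_tailed, n = r2$n, method = r2$method)
  }
  rs <- survival_pleiotropy(ds, sub)
  rows[[length(rows) + 1]] <- data.frame(
    subset = sn, comparison = "fec5_vs_surv33",
    tau = rs$tau, p = rs$p_two_tailed, n = rs$n, method = rs$method)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/pleiotropy.csv", row.names = FALSE)

cat("Pleiotropy correlations (Kendall tau-b):\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nWrote results/pleiotropy.csv\n")
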