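#!/usr/bin/env Rscript
# Group statistics over the per-cell dwell parameters: Shapiro-Wilk and
# Levene checks feeding the ANOVA/Tukey vs Kruskal-Wallis/Dunn decision
# rule, with z-score outlier screening. Run 04_dwell_analysis.R first.

library(gabakin)
cells <- read.csv("results/cell_summary.csv")

params <- setdiff(names(cells), c("genotype", "cell"))
rows <- list()
for (p in params) {
  cmp <- compare_groups(cells[[p]], cells$genotype, parameter = p)
  cat(sprintf("%-20s %s omnibus p = %.4g\n", p, cmp$test, cmp$omnibus_p))
  if (!is.null(cmp$posthoc)) {
    ph <- cmp$posthoc
    for (i in seq_len(nrow(ph)))
      cat(sprintf("    %s vs %s: p_adj = %.4g%s\n", ph$group1[i],
                  ph$group2[i], ph$p_adj[i],
                  ifelse(ph$p_adj[i] < 0.05, " *", "")))
    rows[[p]] <- data.frame(parameter = p, test = cmp$test,
                            group1 = ph$group1, group2 = ph$group2,
                            p_adj = ph$p_adj)
  }
}
if (length(rows))
  write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
            "results/group_comparisons.csv", row.names = FALSE)
cat("Post-hoc table written to results/group_comparisons.csv\n")
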