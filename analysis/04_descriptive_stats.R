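#!/usr/bin/env Rscript
# Stage 4 — the statistical reporting surface on the reclassified fixture:
# per-type descriptive tables with Tukey compact letters, one-way ANOVA and
# Kruskal-Wallis per parameter, and the Pearson correlation matrix with
# significance stars.

suppressPackageStartupMessages(library(honeyaudit))
tab <- read_samples("results/fixture_final.csv")

letters_by_param <- list()
tests <- NULL
for (pm in c("glu", "fru", "suc", "hmf", "mc", "acid", "dia", "ins",
             "econd")) {
  groups <- split(tab[[pm]], tab$final_type)
  av <- oneway_anova(groups)
  kw <- kruskal_wallis(groups)
  letters_by_param[[pm]] <- tukey_hsd(groups)$letters
  tests <- rbind(tests, data.frame(
    parameter = pm, F = av$statistic, df1 = av$df[1], df2 = av$df[2],
    p_anova = av$p_value, H = kw$statistic, p_kw = kw$p_value))
}
write.csv(tests, "results/group_tests.csv", row.names = FALSE)
cat("parameters with type effect at p < 0.05 (ANOVA):",
    paste(tests$parameter[tests$p_anova < 0.05], collapse = ", "), "\n")

sm <- describe_by(tab, "final_type")
render_tables(sm, letters = letters_by_param,
              path = "results/descriptives_by_type.csv")
render_tables(sm, letters = letters_by_param, format = "markdown",
              path = "results/descriptives_by_type.md")

corr <- pearson_matrix(tab)
write.csv(data.frame(parameter = rownames(corr$r), round(corr$r, 3),
                     check.names = FALSE),
          "results/correlations.csv", row.names = FALSE)
write.csv(data.frame(parameter = rownames(corr$stars), corr$stars,
                     check.names = FALSE),
          "results/correlation_stars.csv", row.names = FALSE)
cat(sprintf("strongest off-diagonal correlation: acid-econd r = %.3f %s\n",
            corr$r["acid", "econd"], corr$stars["acid", "econd"]))
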