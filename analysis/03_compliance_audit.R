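#!/usr/bin/env Rscript
# Stage 3 — threshold screening and two-tier grading of the reclassified
# fixture under the default regulatory policy. Writes per-sample verdicts
# and the audit summary.

suppressPackageStartupMessages(library(honeyaudit))
tab <- read_samples("results/fixture_final.csv")
cs <- summarize_compliance(tab)
print(cs)

audit <- cs$audit
audit$codes <- vapply(audit$codes, paste, character(1), collapse = ";")
write.csv(audit, "results/audit_per_sample.csv", row.names = FALSE)
jsonlite::write_json(
  list(grades = as.list(cs$grade_counts),
       violations = as.list(cs$code_counts),
       violations_suspect_grade = as.list(cs$code_counts_suspect_grade),
       blend_flags = cs$blend_flags,
       nonconforming_pct = cs$nonconforming_pct),
  "results/audit_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat(sprintf("non-conforming: %d of %d (%.1f%%); %d possible nectar/honeydew blends flagged\n",
            cs$nonconforming, cs$n, cs$nonconforming_pct, cs$blend_flags))
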