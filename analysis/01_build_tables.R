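#!/usr/bin/env Rscript
# Stage 1 — construct the two study tables:
#   (a) the deterministic 609-sample deviation fixture (the audit benchmark),
#   (b) a realistic table from the calibrated Gaussian-copula generator.
# Writes both CSVs and the fixture manifest under results/.

suppressPackageStartupMessages(library(honeyaudit))
dir.create("results", showWarnings = FALSE)
seed <- 7L

fx <- build_fixture(seed)
write_samples(fx$table, "results/fixture.csv")
jsonlite::write_json(fx$manifest, "results/fixture_manifest.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("fixture: %d samples, %d declared types, %d expected non-conforming (%.1f%%)\n",
            fx$manifest$total, length(fx$manifest$declared_type_counts),
            fx$manifest$adulterated + fx$manifest$suspect,
            fx$manifest$nonconforming_pct))

real <- generate_realistic(generator_config(seed = seed))
write_samples(real, "results/realistic.csv")
cat(sprintf("realistic table: %d samples; honeydew econd %.2f-%.2f, all others <= %.2f\n",
            nrow(real),
            min(real$econd[real$declared_type == "honeydew"]),
            max(real$econd[real$declared_type == "honeydew"]),
            max(real$econd[real$declared_type != "honeydew"])))
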