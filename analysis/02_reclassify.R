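#!/usr/bin/env Rscript
# Stage 2 — conductivity-based botanical reclassification of the fixture:
# flower samples above 0.8 mS/cm become honeydew, declared honeydew below
# it becomes polyfloral. Writes the finalized table and the move report.

suppressPackageStartupMessages(library(honeyaudit))
tab <- read_samples("results/fixture.csv")
rc <- reclassify_table(tab)
write_samples(rc$table, "results/fixture_final.csv")
jsonlite::write_json(rc$report[c("moved", "moved_in", "moved_out",
                                 "final_honeydew")],
                     "results/reclassification.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("reclassified %d samples (%d into honeydew, %d out to polyfloral); %d final honeydew\n",
            rc$report$moved, rc$report$moved_in, rc$report$moved_out,
            rc$report$final_honeydew))
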