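#!/usr/bin/env Rscript
# Stage 5 — train the 8-12-6 honey-type classifier (logistic hidden layer,
# softmax output, cross-entropy loss, BFGS, 10 random restarts selected on
# held-out loss) on the realistic synthetic table and report per-class
# test recognition.

suppressPackageStartupMessages(library(honeyaudit))
tab <- read_samples("results/realistic.csv")
tab$final_type <- reclassify_table(tab)$table$final_type

fit <- train_classifier(tab, split_seed = 71L, init_seed = 72L)
ev <- fit$evaluation

cat(sprintf("train accuracy %.2f%%, test accuracy %.2f%% (restart %d, validation loss %.3f)\n",
            ev$train$accuracy, ev$test$accuracy, fit$model$chosen_restart,
            fit$model$validation_loss))
cat("per-class test recognition (%):\n")
print(round(ev$test$per_class_rate, 2))

jsonlite::write_json(
  list(confusion_test = ev$test$confusion,
       per_class_test = as.list(ev$test$per_class_rate),
       accuracy = list(train = ev$train$accuracy, test = ev$test$accuracy),
       config = fit$model$config),
  "results/classifier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
write.csv(as.data.frame(ev$test$confusion), "results/confusion_test.csv",
          row.names = FALSE)
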