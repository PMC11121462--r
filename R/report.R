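#' Run the full audit pipeline
#'
#' Orchestrates generate (or load) → reclassify → compliance audit →
#' descriptive statistics → classifier training as one reproducible run,
#' writing per-stage artifacts under `out_dir` and returning (and writing) a
#' machine-readable summary. Fully deterministic given the seeds; the
#' summary records every policy constant used.
#'
#' @param input `"fixture"`, `"realistic"`, or a path to a sample CSV.
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param policy a [default_policy()].
#' @param seed integer seed driving the generator and classifier.
#' @param stages character subset of `c("reclassify", "audit", "stats",
#'   "train")`; generation/loading always runs first.
#' @return The run summary (list), invisibly written as `summary.json`.
#' @export
run_audit <- function(input = "fixture", out_dir = NULL,
                      policy = default_policy(), seed = 7L,
                      stages = c("reclassify", "audit", "stats", "train")) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed)
  manifest <- NULL
  if (identical(input, "fixture")) {
    fx <- build_fixture(seed)
    tab <- fx$table
    manifest <- fx$manifest
    source_note <- sprintf("fixture seed %d", seed)
  } else if (identical(input, "realistic")) {
    tab <- generate_realistic(generator_config(seed = seed))
    source_note <- sprintf("realistic generator seed %d", seed)
  } else {
    tab <- read_samples(input)
    source_note <- input
  }
  if (nrow(tab) == 0L) stop("input table has zero records")
  summary <- list(source = source_note, n = nrow(tab), seed = seed,
                  policy = unclass(policy))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(obj, file.path(out_dir, file), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
  if ("reclassify" %in% stages) {
    rc <- reclassify_table(tab, policy)
    tab <- rc$table
    summary$reclassification <- rc$report[c("moved", "moved_in", "moved_out",
                                            "final_honeydew")]
    if (!is.null(out_dir)) write_samples(tab, file.path(out_dir, "table_final.csv"))
  }
  if ("audit" %in% stages) {
    cs <- summarize_compliance(tab, policy)
    summary$grades <- as.list(cs$grade_counts)
    summary$violations <- as.list(cs$code_counts)
    summary$violations_suspect_grade <- as.list(cs$code_counts_suspect_grade)
    summary$blend_flags <- cs$blend_flags
    summary$nonconforming_pct <- cs$nonconforming_pct
    emit(summary["grades"], "audit.json")
  }
  if ("stats" %in% stages) {
    by_type <- describe_by(tab, "final_type")
    summary$descriptives_groups <- length(unique(by_type$group))
    if (!is.null(out_dir)) {
      utils::write.csv(by_type, file.path(out_dir, "summary_by_type.csv"),
                       row.names = FALSE)
      corr <- pearson_matrix(tab)
      utils::write.csv(data.frame(parameter = rownames(corr$r),
                                  round(corr$r, 3), check.names = FALSE),
                       file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
  }
  if ("train" %in% stages) {
    fit <- train_classifier(tab, split_seed = seed, init_seed = seed + 1L)
    summary$classifier <- list(
      train_accuracy = fit$evaluation$train$accuracy,
      test_accuracy = fit$evaluation$test$accuracy,
      test_per_class = as.list(fit$evaluation$test$per_class_rate)
    )
  }
  if (!is.null(manifest)) summary$manifest <- manifest
  emit(summary, "summary.json")
  invisible(summary)
}

#' Grouped descriptive statistics table
#'
#' One [describe()] row per group x parameter, in the canonical reporting
#' column order (N, mean, SD, CI bounds, variance, min, max, quartiles).
#'
#' @param table a sample table.
#' @param by grouping column (`"final_type"`, `"declared_type"`, `"year"` or
#'   `"region"`).
#' @param parameters measurement columns to summarize.
#' @return A tibble with columns `parameter`, `group`, and the descriptive
#'   columns.
#' @export
describe_by <- function(table, by = "final_type",
                        parameters = measurement_cols()) {
  if (!by %in% names(table)) stop("grouping column not found: ", by)
  groups <- split(seq_len(nrow(table)), table[[by]])
  out <- list()
  for (pm in parameters) {
    for (g in names(groups)) {
      d <- describe(table[[pm]][groups[[g]]])
      out[[length(out) + 1L]] <- tibble::tibble(parameter = pm, group = g, d)
    }
  }
  dplyr::bind_rows(out)
}

#' Render a descriptive report with out-of-range flags
#'
#' Formats a [describe_by()] table in the standard reporting layout and
#' marks extreme values (min or max) lying outside the policy limits for
#' their parameter — the printed analogue of boldface in published tables.
#' Letters from [tukey_hsd()] can be appended per group.
#'
#' @param summaries a [describe_by()] tibble.
#' @param policy a [default_policy()].
#' @param letters optional named list: `letters[[parameter]][group]`.
#' @param format `"csv"` (flag column) or `"markdown"` (bold markers).
#' @param path optional output file.
#' @return A data frame (csv) or character vector of lines (markdown).
#' @export
render_tables <- function(summaries, policy = default_policy(),
                          letters = NULL, format = c("csv", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  flag_extreme <- function(parameter, value) {
    if (is.na(value)) return(FALSE)
    switch(parameter,
      suc = value > policy$sucrose_max_default,
      hmf = value > policy$hmf_max,
      acid = value > policy$acidity_max,
      dia = value < policy$diastase_min,
      mc = value > policy$moisture_max,
      ins = value > policy$insoluble_max,
      econd = value < policy$econd_low_flag,
      FALSE)
  }
  out <- summaries
  out$min_flag <- mapply(flag_extreme, summaries$parameter, summaries$min)
  out$max_flag <- mapply(flag_extreme, summaries$parameter, summaries$max)
  out$letter <- ""
  if (!is.null(letters)) {
    for (i in seq_len(nrow(out))) {
      l <- letters[[out$parameter[i]]]
      if (!is.null(l) && out$group[i] %in% names(l)) {
        out$letter[i] <- l[[out$group[i]]]
      }
    }
  }
  if (format == "csv") {
    if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
    return(out)
  }
  fmt_num <- function(x) ifelse(is.na(x), "/", sprintf("%.2f", x))
  bold <- function(x, flag) ifelse(flag, paste0("**", fmt_num(x), "**"),
                                   fmt_num(x))
  header <- paste("| Parameter | Group | N | Mean ± SD | CI -95% |",
                  "CI +95% | Var | Min | Max | Q25 | Median | Q75 |")
  sep <- paste(c("|", rep(" --- |", 12)), collapse = "")
  lines <- c(header, sep)
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    ms <- sprintf("%.2f ± %s%s", r$mean,
                  ifelse(is.na(r$sd), "/", sprintf("%.2f", r$sd)),
                  ifelse(nzchar(r$letter), paste0(" ^", r$letter, "^"), ""))
    lines <- c(lines, paste(
      "|", r$parameter, "|", r$group, "|", r$n, "|", ms, "|",
      fmt_num(r$ci_low), "|", fmt_num(r$ci_high), "|", fmt_num(r$var), "|",
      bold(r$min, r$min_flag), "|", bold(r$max, r$max_flag), "|",
      fmt_num(r$q25), "|", fmt_num(r$median), "|", fmt_num(r$q75), "|"))
  }
  if (!is.null(path)) writeLines(lines, path)
  lines
}
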