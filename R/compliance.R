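#' Violation codes
#'
#' The eight regulatory deviation classes screened per sample. The first
#' four are adulteration-grade (markers of syrup addition, overheating or
#' poor freshness); the rest are suspect-grade (explainable by
#' crystallization, storage or botanical origin).
#'
#' @return Character vectors of codes.
#' @export
adulteration_codes <- function() {
  c("HIGH_SUCROSE", "HIGH_HMF", "HIGH_ACIDITY", "LOW_DIASTASE")
}

#' @rdname adulteration_codes
#' @export
suspect_codes <- function() {
  c("LOW_SUGAR_SUM", "HIGH_MOISTURE", "LOW_ECOND", "HIGH_INSOLUBLE")
}

#' Screen one sample against the threshold policy
#'
#' All comparisons are strict ("higher than" / "lower than"), so
#' boundary-equal values are compliant. Type-aware rules use the *final*
#' (post-reclassification) type: the sucrose ceiling rises to 10 g/100 g
#' for acacia; the glucose + fructose floor drops to 45 g/100 g for
#' honeydew (60 g/100 g for blossom honey).
#'
#' @param sample one-row sample table (with `final_type` set).
#' @param policy a [default_policy()].
#' @param pressed logical; use the pressed-honey insoluble-matter ceiling.
#' @return A list with `sample_id`, `codes` (character vector of violation
#'   codes), `blend_suspect` and `sugar_sum`.
#' @export
check_sample <- function(sample, policy = default_policy(), pressed = FALSE) {
  ft <- sample$final_type
  if (is.null(ft) || is.na(ft)) stop("final_type must be set; reclassify first")
  sugar_sum <- sample$glu + sample$fru
  suc_max <- if (ft %in% policy$sucrose_exception_types) {
    policy$sucrose_max_exception
  } else {
    policy$sucrose_max_default
  }
  sum_min <- if (ft == "honeydew") policy$sugar_sum_min_honeydew
             else policy$sugar_sum_min_blossom
  ins_max <- if (pressed) policy$insoluble_max_pressed else policy$insoluble_max
  codes <- c(
    HIGH_SUCROSE = sample$suc > suc_max,
    HIGH_HMF = sample$hmf > policy$hmf_max,
    HIGH_ACIDITY = sample$acid > policy$acidity_max,
    LOW_DIASTASE = sample$dia < policy$diastase_min,
    LOW_SUGAR_SUM = sugar_sum < sum_min,
    HIGH_MOISTURE = sample$mc > policy$moisture_max,
    LOW_ECOND = sample$econd < policy$econd_low_flag,
    HIGH_INSOLUBLE = sample$ins > ins_max
  )
  list(
    sample_id = sample$sample_id,
    codes = names(codes)[codes],
    blend_suspect = flag_blend(sample, policy),
    sugar_sum = sugar_sum
  )
}

#' Flag a possible nectar/honeydew blend
#'
#' A flower-type sample whose glucose + fructose sum falls below the blossom
#' floor but stays at or above the honeydew floor, with conductivity in the
#' band just below the honeydew threshold (default 0.70-0.8 mS/cm), has the
#' profile of a nectar and honeydew honey blend. The flag is informational
#' only; it never changes the grade.
#'
#' @inheritParams check_sample
#' @return Logical.
#' @export
flag_blend <- function(sample, policy = default_policy()) {
  ft <- sample$final_type
  if (is.null(ft) || is.na(ft) || ft == "honeydew") return(FALSE)
  sugar_sum <- sample$glu + sample$fru
  sugar_sum < policy$sugar_sum_min_blossom &&
    sugar_sum >= policy$sugar_sum_min_honeydew &&
    sample$econd >= policy$blend_econd_min &&
    sample$econd < policy$econd_flower_max
}

#' Grade a violation report
#'
#' Two-tier grading: any adulteration-grade code (high sucrose, high 5-HMF,
#' high acidity, low diastase) makes the sample `ADULTERATED`; any remaining
#' violation makes it `SUSPECT`; an empty violation set is `COMPLIANT`.
#' Adulteration-grade codes dominate, so a sample with both a sucrose
#' excess and a low sugar sum is counted once, in the adulterated tier.
#'
#' @param report as returned by [check_sample()] (any list with a `codes`
#'   element).
#' @return A list with `grade` and `triggering` codes.
#' @export
grade_verdict <- function(report) {
  codes <- report$codes
  adux <- intersect(codes, adulteration_codes())
  if (length(adux)) {
    list(grade = "ADULTERATED", triggering = adux)
  } else if (length(codes)) {
    list(grade = "SUSPECT", triggering = codes)
  } else {
    list(grade = "COMPLIANT", triggering = character(0))
  }
}

#' Audit a whole table
#'
#' Runs [check_sample()] and [grade_verdict()] on every row of a
#' reclassified table.
#'
#' @param table a sample table with `final_type` set.
#' @inheritParams check_sample
#' @return A tibble with one row per sample: `sample_id`, `final_type`,
#'   `grade`, `codes` (list column), `blend_suspect`, `sugar_sum`.
#' @export
audit_table <- function(table, policy = default_policy(), pressed = FALSE) {
  table <- validate_samples(table)
  if (!"final_type" %in% names(table)) {
    stop("final_type must be set; run reclassify_table() first")
  }
  n <- nrow(table)
  codes <- vector("list", n)
  blend <- logical(n)
  grade <- character(n)
  for (i in seq_len(n)) {
    rep_i <- check_sample(table[i, ], policy, pressed)
    codes[[i]] <- rep_i$codes
    blend[i] <- rep_i$blend_suspect
    grade[i] <- grade_verdict(rep_i)$grade
  }
  tibble::tibble(
    sample_id = table$sample_id,
    final_type = table$final_type,
    region = table$region,
    year = table$year,
    grade = grade,
    codes = codes,
    blend_suspect = blend,
    sugar_sum = table$glu + table$fru
  )
}

#' Summarize a compliance audit
#'
#' Aggregates an [audit_table()] result: counts per grade and violation
#' code, blend flags, the non-conforming percentage (half-up rounding to 1
#' decimal), and grade breakdowns by final type, region and year.
#'
#' @param table a reclassified sample table.
#' @inheritParams check_sample
#' @return A list (`compliance_summary`).
#' @export
summarize_compliance <- function(table, policy = default_policy(),
                                 pressed = FALSE) {
  if (nrow(table) == 0L) stop("cannot summarize an empty table")
  audit <- audit_table(table, policy, pressed)
  all_codes <- c(adulteration_codes(), suspect_codes())
  code_counts <- vapply(all_codes, function(cd) {
    sum(vapply(audit$codes, function(x) cd %in% x, logical(1)))
  }, integer(1))
  # suspect-grade incidence of a code: samples carrying it whose verdict is
  # SUSPECT (adulterated duals counted in their own tier)
  code_counts_suspect <- vapply(all_codes, function(cd) {
    sum(vapply(audit$codes, function(x) cd %in% x, logical(1)) &
          audit$grade == "SUSPECT")
  }, integer(1))
  grades <- c(ADULTERATED = sum(audit$grade == "ADULTERATED"),
              SUSPECT = sum(audit$grade == "SUSPECT"),
              COMPLIANT = sum(audit$grade == "COMPLIANT"))
  nonconf <- grades[["ADULTERATED"]] + grades[["SUSPECT"]]
  structure(list(
    n = nrow(audit),
    grade_counts = grades,
    code_counts = code_counts,
    code_counts_suspect_grade = code_counts_suspect,
    blend_flags = sum(audit$blend_suspect),
    nonconforming = nonconf,
    nonconforming_pct = round_half_up(nonconf / nrow(audit) * 100, 1),
    by_final_type = grade_crosstab(audit$final_type, audit$grade),
    by_region = grade_crosstab(audit$region, audit$grade),
    by_year = grade_crosstab(audit$year, audit$grade),
    audit = audit
  ), class = "compliance_summary")
}

grade_crosstab <- function(key, grade) {
  tb <- table(key, factor(grade, levels = c("ADULTERATED", "SUSPECT",
                                            "COMPLIANT")))
  as.data.frame.matrix(tb)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @export
print.compliance_summary <- function(x, ...) {
  cat("Compliance audit of", x$n, "samples\n")
  cat(sprintf("  adulterated: %d  suspect: %d  compliant: %d (%.1f%% non-conforming)\n",
              x$grade_counts[["ADULTERATED"]], x$grade_counts[["SUSPECT"]],
              x$grade_counts[["COMPLIANT"]], x$nonconforming_pct))
  cat("  violations:",
      paste(names(x$code_counts), x$code_counts, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
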