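#' Honey sample tables
#'
#' A sample table is a tibble with one row per honey sample: identity labels
#' (`sample_id`, `declared_type`, optional `final_type`, `region`, `year`)
#' and nine measured physicochemical parameters — glucose `glu`, fructose
#' `fru` and sucrose `suc` in g/100 g, 5-hydroxymethylfurfural `hmf` in
#' mg/kg, moisture content `mc` in %, free acidity `acid` in meq/kg,
#' diastase activity `dia` in Schade units, insoluble matter `ins` in % and
#' electrical conductivity `econd` in mS/cm. Sucrose and 5-HMF below the
#' 0.50 limit of quantification are stored at 0.50 with logical flags
#' `suc_censored` / `hmf_censored`.
#'
#' @name sample_table
NULL

measurement_cols <- function() {
  c("glu", "fru", "suc", "hmf", "mc", "acid", "dia", "ins", "econd")
}

sample_csv_cols <- function() {
  c("sample_id", "declared_type", "region", "year", measurement_cols())
}

#' Read a honey sample table from CSV
#'
#' Expects a comma-separated UTF-8 file with a mandatory header naming at
#' least the columns `sample_id, declared_type, region, year, glu, fru, suc,
#' hmf, mc, acid, dia, ins, econd` (dot decimal separator). Sucrose or 5-HMF
#' cells written `"<0.50"` parse to the 0.50 limit of quantification with the
#' corresponding censored flag set. A `final_type` column, if present, is
#' kept (it is normally produced by [reclassify_table()]).
#'
#' @param path path to the CSV file.
#' @return A validated sample table (tibble).
#' @seealso [write_samples()]
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(sample_csv_cols(), names(raw))
  if (length(missing)) {
    stop("missing column(s) in sample table: ", paste(missing, collapse = ", "))
  }
  parse_meas <- function(col, censorable) {
    cells <- trimws(raw[[col]])
    cens <- cells == "<0.50"
    if (any(cens) && !censorable) {
      stop("censored cells are only allowed for suc and hmf (column ", col, ")")
    }
    vals <- suppressWarnings(as.numeric(ifelse(cens, "0.50", cells)))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1L],
           ": '", cells[bad[1L]], "'")
    }
    list(value = vals, censored = cens)
  }
  suc_p <- parse_meas("suc", TRUE)
  hmf_p <- parse_meas("hmf", TRUE)
  tab <- tibble::tibble(
    sample_id     = raw$sample_id,
    declared_type = raw$declared_type,
    region        = raw$region,
    year          = {
      y <- suppressWarnings(as.integer(raw$year))
      if (anyNA(y)) stop("non-integer year at data row ", which(is.na(y))[1L])
      y
    },
    glu  = parse_meas("glu", FALSE)$value,
    fru  = parse_meas("fru", FALSE)$value,
    suc  = suc_p$value,
    suc_censored = suc_p$censored,
    hmf  = hmf_p$value,
    hmf_censored = hmf_p$censored,
    mc   = parse_meas("mc", FALSE)$value,
    acid = parse_meas("acid", FALSE)$value,
    dia  = parse_meas("dia", FALSE)$value,
    ins  = parse_meas("ins", FALSE)$value,
    econd = parse_meas("econd", FALSE)$value
  )
  if ("final_type" %in% names(raw)) {
    tab$final_type <- raw$final_type
  }
  validate_samples(tab)
}

#' Write a honey sample table to CSV
#'
#' Inverse of [read_samples()]: censored sucrose / 5-HMF cells are written
#' `"<0.50"`, so a read → write → read round trip reproduces the table
#' exactly. Output formatting is deterministic (fixed 15-significant-digit
#' rendering), so identical tables yield byte-identical files.
#'
#' @param table a sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  table <- validate_samples(table)
  fmt <- function(x) {
    out <- vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                        trim = TRUE),
                  character(1))
    out
  }
  out <- data.frame(
    sample_id = table$sample_id,
    declared_type = table$declared_type,
    region = table$region,
    year = as.character(table$year),
    glu = fmt(table$glu),
    fru = fmt(table$fru),
    suc = ifelse(table$suc_censored, "<0.50", fmt(table$suc)),
    hmf = ifelse(table$hmf_censored, "<0.50", fmt(table$hmf)),
    mc = fmt(table$mc),
    acid = fmt(table$acid),
    dia = fmt(table$dia),
    ins = fmt(table$ins),
    econd = fmt(table$econd),
    stringsAsFactors = FALSE
  )
  if ("final_type" %in% names(table)) out$final_type <- table$final_type
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a honey sample table
#'
#' Checks the schema invariants: unique ids, closed type/region vocabularies,
#' years within the study window, non-negative measurements, and censored
#' flags implying the stored 0.50 limit of quantification.
#'
#' @param table candidate sample table.
#' @return The table, invisibly unchanged (as a tibble), or an error.
#' @export
validate_samples <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("sample_id", "declared_type", "region", "year",
            "glu", "fru", "suc", "suc_censored", "hmf", "hmf_censored",
            "mc", "acid", "dia", "ins", "econd")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(table$sample_id)) {
    dup <- table$sample_id[duplicated(table$sample_id)][1L]
    stop("duplicate sample_id: ", dup)
  }
  bad_type <- setdiff(unique(table$declared_type), honey_types())
  if (length(bad_type)) stop("unknown honey type: ", bad_type[1L])
  if ("final_type" %in% names(table)) {
    bad_final <- setdiff(unique(table$final_type), honey_types())
    if (length(bad_final)) stop("unknown final honey type: ", bad_final[1L])
  }
  bad_region <- setdiff(unique(table$region), honey_regions())
  if (length(bad_region)) stop("unknown region: ", bad_region[1L])
  if (any(!table$year %in% honey_years())) {
    stop("year outside study window 2018-2023")
  }
  for (m in measurement_cols()) {
    v <- table[[m]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("measurement '", m, "' must be finite and non-negative")
    }
  }
  if (any(table$suc_censored & table$suc != loq_value()) ||
      any(table$hmf_censored & table$hmf != loq_value())) {
    stop("censored values must be stored at the 0.50 limit of quantification")
  }
  invisible(table)
}
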