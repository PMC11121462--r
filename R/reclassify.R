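#' Conductivity-based botanical reclassification
#'
#' Electrical conductivity separates honeydew from flower honey: values
#' above 0.8 mS/cm indicate honeydew origin, values below indicate nectar
#' (flower) origin. Before any compliance check, each sample's declared type
#' is revised accordingly: a flower type with conductivity strictly above
#' the threshold becomes honeydew; a declared honeydew strictly below it
#' becomes polyfloral (the mixed-nectar class — no attempt is made to
#' recover a monofloral label). A value exactly at the threshold leaves the
#' declaration unchanged.
#'
#' @param declared declared botanical type.
#' @param econd electrical conductivity in mS/cm, non-negative.
#' @param policy a [default_policy()] (uses `econd_flower_max`).
#' @return For `reclassify_sample`, a list with `final` and `direction`
#'   (`"into-honeydew"`, `"out-of-honeydew"` or `"none"`).
#' @examples
#' reclassify_sample("acacia", 0.9)$final     # "honeydew"
#' reclassify_sample("honeydew", 0.5)$final   # "polyfloral"
#' reclassify_sample("linden", 0.8)$direction # "none" (boundary)
#' @export
reclassify_sample <- function(declared, econd, policy = default_policy()) {
  if (!declared %in% honey_types()) stop("unknown honey type: ", declared)
  if (!is.finite(econd) || econd < 0) stop("econd must be non-negative")
  thr <- policy$econd_flower_max
  if (declared != "honeydew" && econd > thr) {
    list(final = "honeydew", direction = "into-honeydew")
  } else if (declared == "honeydew" && econd < thr) {
    list(final = "polyfloral", direction = "out-of-honeydew")
  } else {
    list(final = declared, direction = "none")
  }
}

#' @rdname reclassify_sample
#' @param table a sample table.
#' @return For `reclassify_table`, a list with `table` (input with
#'   `final_type` set) and `report` (per-sample moves plus totals). The
#'   operation is idempotent: out-moves land in polyfloral with conductivity
#'   below the threshold, which cannot re-trigger.
#' @export
reclassify_table <- function(table, policy = default_policy()) {
  table <- validate_samples(table)
  res <- Map(reclassify_sample, table$declared_type, table$econd,
             MoreArgs = list(policy = policy))
  final <- vapply(res, `[[`, character(1), "final")
  direction <- vapply(res, `[[`, character(1), "direction")
  table$final_type <- unname(final)
  per_sample <- tibble::tibble(
    sample_id = table$sample_id,
    declared_type = table$declared_type,
    final_type = table$final_type,
    moved = direction != "none",
    direction = direction
  )
  report <- list(
    samples = per_sample,
    moved = sum(per_sample$moved),
    moved_in = sum(direction == "into-honeydew"),
    moved_out = sum(direction == "out-of-honeydew"),
    final_honeydew = sum(final == "honeydew")
  )
  list(table = table, report = report)
}
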