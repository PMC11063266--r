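#' Build a machine-readable planning report
#'
#' Collects ranked plan results, the coefficient table and provenance
#' (tool version, config hash, seed, input checksums) into a stable,
#' reproducible report structure: re-running on identical inputs yields
#' byte-identical JSON.
#'
#' @param results List of `plan_result` from [rank_plans()].
#' @param coeffs Risk coefficients used.
#' @param provenance Named list; typically `seed` and input file checksums
#'   (see [file_checksum()]).
#' @return A list of class `plan_report`.
#' @export
plan_report <- function(results, coeffs = default_risk_coefficients(),
                        provenance = list()) {
  coeffs <- validate_risk_coefficients(coeffs)
  plans <- lapply(results, function(r) {
    breakdowns <- if (is.null(r$breakdowns)) NULL else
      lapply(r$breakdowns, function(b) list(
        path_id = b$path_id,
        tissue_volumes_mm3 = as.list(b$tissue_volumes),
        injury_risk = b$injury_risk,
        surgical_freedom = b$surgical_freedom,
        weight = b$weight))
    list(plan_id = r$plan_id,
         approach_label = r$approach_label,
         rank = r$rank,
         total_weight = r$total_weight,
         injury_risk_sum = if (is.null(breakdowns)) NA_real_ else
           sum(vapply(breakdowns, `[[`, 0, "injury_risk")),
         freedom_sum = if (is.null(breakdowns)) NA_real_ else
           sum(vapply(breakdowns, `[[`, 0, "surgical_freedom")),
         paths = r$path_ids,
         breakdowns = breakdowns)
  })
  structure(
    list(tool = list(name = "cliviplan",
                     version = as.character(utils::packageVersion("cliviplan"))),
         provenance = provenance,
         coefficients = as.list(coeffs),
         winner = list(plan_id = results[[1]]$plan_id,
                       approach_label = results[[1]]$approach_label,
                       total_weight = results[[1]]$total_weight),
         plans = plans),
    class = "plan_report"
  )
}

#' Serialize a plan report
#'
#' `write_plan_report()` writes deterministic JSON (fixed key order, full
#' precision) and optionally a one-row-per-plan CSV summary with columns
#' `plan_id, label, total_weight, injury_risk_sum, freedom_sum, rank`.
#'
#' @param report A [plan_report()].
#' @param json_path Output JSON path.
#' @param csv_path Optional output CSV path.
#' @return `json_path` invisibly.
#' @export
write_plan_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "plan_report"))
  jsonlite::write_json(unclass(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    df <- do.call(rbind, lapply(report$plans, function(p) data.frame(
      plan_id = p$plan_id, label = p$approach_label,
      total_weight = p$total_weight,
      injury_risk_sum = p$injury_risk_sum,
      freedom_sum = p$freedom_sum,
      rank = p$rank)))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Validate a plan report against the bundled schema
#'
#' Structural validation against `inst/extdata/plan_report_schema.json`
#' (required fields and types); returns `TRUE` or raises an error naming the
#' first violation.
#'
#' @param report A [plan_report()] or a list parsed from report JSON.
#' @return `TRUE` invisibly.
#' @export
validate_plan_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "plan_report_schema.json",
                                            package = "cliviplan", mustWork = TRUE))
  for (f in names(schema$required_fields))
    if (is.null(report[[f]]))
      stop("plan report is missing required field '", f, "'")
  if (!is.list(report$plans) || !length(report$plans))
    stop("plan report must contain a non-empty 'plans' array")
  for (p in report$plans)
    for (f in unlist(schema$required_plan_fields))
      if (is.null(p[[f]]))
        stop("plan entry is missing required field '", f, "'")
  if (is.null(report$winner$plan_id))
    stop("plan report winner must name a plan_id")
  invisible(TRUE)
}

#' MD5 checksum of a file
#'
#' @param path File path.
#' @return Character checksum.
#' @export
file_checksum <- function(path) unname(tools::md5sum(path))

# Stable hash of an in-memory config (canonical JSON, then MD5).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  file_checksum(f)
}
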