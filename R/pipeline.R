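# End-to-end driver: ingest -> step-down -> RAM build/apply -> unit
# expenditure -> analytics, with a run manifest recording input hashes, row
# counts and the global conservation check.

#' Run the full pipeline
#'
#' Chains every stage over in-memory input tables (a generated
#' `rems_bundle` or the list returned by [read_bundle()]): HIV isolation and
#' step-down of the ledger, operational-budget and RAM construction from the
#' facility assessment, RAM application to facility inflows, unit-expenditure
#' estimation against output volumes, and the data-quality report. The
#' manifest records input hashes, row counts and the end-to-end conservation
#' residual (facility cell allocations + above-facility vs HIV-share ledger
#' expenditure, per quarter and funding source).
#'
#' @param inputs A `rems_bundle` or [read_bundle()] list (needs `hierarchy`,
#'   `ledger`, `volumes`, `hiv_weights`, `flow_rules`, `assessment`,
#'   `schedule`, `config`).
#' @param on_missing_ram `"error"` (default) aborts when a facility with
#'   inflow has no RAM; `"report"` routes it to the data-quality report.
#' @param conservation_tol Currency tolerance for the conservation check.
#' @return A `rems_run` object: `inflows`, `above_facility`, `provenance`,
#'   `budget`, `ram`, `allocated`, `unit_expenditure`, `quality`, `manifest`.
#' @export
run_pipeline <- function(inputs, on_missing_ram = c("error", "report"),
                         conservation_tol = 1e-6) {
  on_missing_ram <- match.arg(on_missing_ram)
  config <- inputs$config
  hierarchy <- inputs$hierarchy
  sd_out <- step_down(inputs$ledger, inputs$hiv_weights, inputs$flow_rules,
                      hierarchy, config, tol = conservation_tol)
  budget <- build_budget(inputs$assessment, inputs$schedule, config)
  ram <- compute_ram(budget)
  allocated <- allocate_ram(sd_out$inflows, ram,
                            on_missing_ram = on_missing_ram)
  unallocated <- attr(allocated, "unallocated")
  units <- compute_unit_expenditure(allocated, inputs$volumes)
  quality <- data_quality_report(units, sd_out$inflows, ram, hierarchy)

  total_hiv <- sd_out$hiv %>%
    group_by(.data$year, .data$quarter, .data$funding_source) %>%
    summarise(hiv_amount = sum(.data$hiv_amount), .groups = "drop")
  total_out <- bind_rows(
    allocated %>% select("year", "quarter", "funding_source", "amount"),
    if (!is.null(unallocated) && nrow(unallocated) > 0) {
      unallocated %>% select("year", "quarter", "funding_source", "amount")
    },
    sd_out$above_facility %>%
      select("year", "quarter", "funding_source", "amount")
  ) %>%
    group_by(.data$year, .data$quarter, .data$funding_source) %>%
    summarise(allocated = sum(.data$amount), .groups = "drop")
  conservation <- full_join(total_hiv, total_out,
                            by = c("year", "quarter", "funding_source")) %>%
    mutate(residual = ifelse(is.na(.data$allocated), 0, .data$allocated) -
             ifelse(is.na(.data$hiv_amount), 0, .data$hiv_amount))
  conservation_pass <- all(abs(conservation$residual) <= conservation_tol)
  if (!conservation_pass && on_missing_ram == "error") {
    abort(sprintf("End-to-end conservation violated: max |residual| = %.3g",
                  max(abs(conservation$residual))),
          class = "rems_conservation_error")
  }
  manifest <- list(
    input_hashes = vapply(
      inputs[intersect(names(inputs),
                       c("ledger", "volumes", "hiv_weights", "flow_rules",
                         "assessment", "schedule", "org_units"))],
      hash, character(1)),
    row_counts = c(
      ledger = nrow(inputs$ledger), volumes = nrow(inputs$volumes),
      inflows = nrow(sd_out$inflows),
      above_facility = nrow(sd_out$above_facility),
      allocated = nrow(allocated),
      unit_expenditure = nrow(units),
      quality_issues = nrow(quality$issues)
    ),
    conservation = conservation,
    conservation_check = if (conservation_pass) "pass" else "fail",
    on_missing_ram = on_missing_ram
  )
  structure(list(
    config = config, hierarchy = hierarchy,
    inflows = sd_out$inflows, above_facility = sd_out$above_facility,
    provenance = sd_out$provenance, hiv = sd_out$hiv,
    budget = budget, ram = ram, allocated = allocated,
    unit_expenditure = units, quality = quality, manifest = manifest
  ), class = "rems_run")
}

#' @export
print.rems_run <- function(x, ...) {
  rc <- x$manifest$row_counts
  cat(sprintf(paste0(
    "<rems_run> conservation: %s\n",
    "  inflow rows %d | above-facility rows %d | allocated cells %d\n",
    "  unit-expenditure records %d (%d quality issues)\n"),
    x$manifest$conservation_check, rc[["inflows"]], rc[["above_facility"]],
    rc[["allocated"]], rc[["unit_expenditure"]], rc[["quality_issues"]]))
  invisible(x)
}

#' Tidy a pipeline run
#'
#' @param x A `rems_run`.
#' @param ... Unused.
#' @return The unit-expenditure tibble (one row per facility x service x
#'   quarter with volume, total and per-category unit amounts and status).
#' @exportS3Method generics::tidy
#' @export
tidy.rems_run <- function(x, ...) {
  x$unit_expenditure
}

#' One-row summary of a pipeline run
#'
#' @param x A `rems_run`.
#' @param ... Unused.
#' @return Tibble with totals, the above-facility share, counts and the
#'   maximum conservation residual.
#' @exportS3Method generics::glance
#' @export
glance.rems_run <- function(x, ...) {
  above <- sum(x$above_facility$amount)
  inflow <- sum(x$inflows$amount)
  tibble(
    n_facilities = n_distinct(x$inflows$facility),
    n_quarters = nrow(distinct(x$inflows, .data$year, .data$quarter)),
    total_hiv_expenditure = sum(x$hiv$hiv_amount),
    total_facility_inflow = inflow,
    total_above_facility = above,
    above_facility_share = ifelse(above + inflow > 0,
                                  above / (above + inflow), NA_real_),
    n_unit_records = nrow(x$unit_expenditure),
    n_quality_issues = nrow(x$quality$issues),
    max_conservation_residual = max(abs(x$manifest$conservation$residual))
  )
}

#' Write all run outputs to a directory
#'
#' Serializes every result table with the deterministic writer; allocation
#' tables use conserving (largest-remainder) rounding within their inflow
#' groups so written rows sum to written totals.
#'
#' @param run A `rems_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(run$inflows, file.path(dir, "facility_inflows.csv"))
  write_table(run$above_facility, file.path(dir, "above_facility.csv"))
  write_table(run$provenance, file.path(dir, "provenance.csv"))
  write_table(run$budget, file.path(dir, "operational_budget.csv"))
  write_table(tidy(run$ram) %>%
                mutate(weight = formatC(.data$weight, format = "f", digits = 9)),
              file.path(dir, "ram_weights.csv"))
  write_table(run$allocated, file.path(dir, "allocated_expenditure.csv"),
              conserve_by = c("facility", "year", "quarter", "funding_source"))
  write_table(run$unit_expenditure, file.path(dir, "unit_expenditure.csv"))
  write_table(run$quality$issues, file.path(dir, "data_quality.csv"))
  manifest <- run$manifest
  manifest$conservation <- as.list(manifest$conservation)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Bundle dashboard views into one JSON export
#'
#' Computes the comparison views (outliers, trends, cost-volume, data quality,
#' roll-up) for a selection and writes them as a single JSON document with the
#' selection parameters echoed.
#'
#' @param run A `rems_run`.
#' @param path Output JSON path.
#' @param service Optional service filter for the cost-volume view (defaults
#'   to the first service present).
#' @param year,quarter Optional period for the cost-volume view (defaults to
#'   the first period present).
#' @param scope Outlier comparison scope.
#' @return `path`, invisibly.
#' @export
export_dashboard <- function(run, path, service = NULL, year = NULL,
                             quarter = NULL, scope = NULL) {
  units <- run$unit_expenditure
  scope <- scope %||% run$config$outlier_scope
  ok <- filter(units, .data$status == "ok")
  service <- service %||% sort(unique(ok$service))[1]
  if (is.null(year) || is.null(quarter)) {
    first <- ok %>% arrange(.data$year, .data$quarter) %>% slice(1)
    year <- year %||% first$year
    quarter <- quarter %||% first$quarter
  }
  cv <- cost_volume_view(units, service, year, quarter)
  out <- list(
    selection = list(service = service, period = quarter_label(year, quarter),
                     scope = scope,
                     outlier_threshold = run$config$outlier_threshold),
    outliers = flag_outliers(units, run$hierarchy, scope = scope,
                             threshold = run$config$outlier_threshold,
                             min_group = run$config$outlier_min_group),
    trends = trend(units),
    cost_volume = as_tibble(cv),
    rollup = rollup(units, run$hierarchy,
                    by = c("district", "service", "quarter")),
    above_facility_share = above_facility_share(run$above_facility,
                                                run$inflows, by = "quarter"),
    data_quality = run$quality$issues
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
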