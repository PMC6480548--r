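# The resource allocation matrix (RAM): per-facility weights over service x
# resource-category cells, built from an ingredients-based facility assessment
# summarized as an annual operational budget, then applied to facility inflows.

#' Annualize assessment line items
#'
#' Recurrent items cost `annual_quantity x standard_unit_cost` per year.
#' Capital items (categories `equipment` and `vehicles`) are annualized
#' straight-line: purchase cost divided by the item's useful life, falling
#' back to the configured default life per category.
#'
#' @param assessment Tibble from [read_assessment()].
#' @param config A [rems_config()] (supplies default useful lives).
#' @return The assessment with an `annual_cost` column added.
#' @export
cost_lines <- function(assessment, config = rems_config()) {
  capital <- assessment$resource_category %in% c("equipment", "vehicles")
  life <- assessment$useful_life_years
  life[capital & is.na(life) & assessment$resource_category == "equipment"] <-
    config$equipment_life_years
  life[capital & is.na(life) & assessment$resource_category == "vehicles"] <-
    config$vehicle_life_years
  if (any(capital & (is.na(life) | life <= 0))) {
    bad <- assessment$item_id[capital & (is.na(life) | life <= 0)]
    abort(paste0("Capital item(s) without a usable useful life: ",
                 paste(bad, collapse = ", ")), class = "rems_config_error")
  }
  purchase <- assessment$annual_quantity * assessment$standard_unit_cost
  mutate(assessment,
         annual_cost = ifelse(capital, purchase / life, purchase))
}

#' Apportion a shared line across services
#'
#' Splits one shared annual cost over a facility's services in proportion to
#' the session-weighted relative volume
#' (`sessions_per_week x relative_annual_volume`, renormalized). Shares sum
#' exactly to the line cost.
#'
#' @param line_cost A single annual cost.
#' @param schedule Schedule rows for one facility
#'   (see [read_schedule()]).
#' @return Tibble `service`, `annual_cost`.
#' @export
apportion_shared <- function(line_cost, schedule) {
  if (nrow(schedule) == 0) {
    abort("Shared line at a facility with no service schedule.",
          class = "rems_config_error")
  }
  w <- schedule$sessions_per_week * schedule$relative_annual_volume
  if (sum(w) <= 0) {
    abort("Shared line cannot be apportioned: all schedule weights are zero.",
          class = "rems_config_error")
  }
  tibble(service = schedule$service, annual_cost = line_cost * w / sum(w))
}

#' Build annual operational budgets
#'
#' Annualizes each assessment line and allocates it across services: dedicated
#' lines map wholly to their service; `SHARED` lines are split with
#' [apportion_shared()].
#'
#' @param assessment Tibble from [read_assessment()].
#' @param schedule Tibble from [read_schedule()].
#' @param config A [rems_config()].
#' @return Tibble `facility_id`, `item_id`, `service`, `resource_category`,
#'   `annual_cost`.
#' @export
build_budget <- function(assessment, schedule, config = rems_config()) {
  costed <- cost_lines(assessment, config)
  rows <- lapply(seq_len(nrow(costed)), function(i) {
    line <- costed[i, ]
    if (line$dedicated_service == "SHARED") {
      sched <- schedule[schedule$facility_id == line$facility_id, , drop = FALSE]
      split <- apportion_shared(line$annual_cost, sched)
      tibble(facility_id = line$facility_id, item_id = line$item_id,
             service = split$service,
             resource_category = line$resource_category,
             annual_cost = split$annual_cost)
    } else {
      tibble(facility_id = line$facility_id, item_id = line$item_id,
             service = line$dedicated_service,
             resource_category = line$resource_category,
             annual_cost = line$annual_cost)
    }
  })
  bind_rows(rows) %>%
    arrange(.data$facility_id, .data$item_id, .data$service)
}

#' Compute resource allocation matrices
#'
#' Per facility, the weight of each (service, resource category) cell is that
#' cell's share of the total annual operational budget, so weights are
#' nonnegative and sum to 1 per facility. Facilities with a zero total budget
#' are an error: they cannot receive allocations.
#'
#' @param budget Tibble from [build_budget()].
#' @return A `rems_ram` tibble: `facility_id`, `service`, `resource_category`,
#'   `weight`.
#' @export
compute_ram <- function(budget) {
  totals <- budget %>%
    group_by(.data$facility_id) %>%
    summarise(total = sum(.data$annual_cost), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("Zero total operational budget for facilit(y/ies): ",
                 paste(totals$facility_id[totals$total <= 0], collapse = ", ")),
          class = "rems_config_error")
  }
  ram <- budget %>%
    group_by(.data$facility_id, .data$service, .data$resource_category) %>%
    summarise(cell = sum(.data$annual_cost), .groups = "drop") %>%
    left_join(totals, by = "facility_id") %>%
    mutate(weight = .data$cell / .data$total) %>%
    select("facility_id", "service", "resource_category", "weight") %>%
    arrange(.data$facility_id, .data$service, .data$resource_category)
  check <- ram %>%
    group_by(.data$facility_id) %>%
    summarise(s = sum(.data$weight), .groups = "drop")
  stopifnot(all(abs(check$s - 1) <= 1e-9), all(ram$weight >= 0))
  class(ram) <- c("rems_ram", class(ram))
  ram
}

#' Validate a loaded RAM table
#'
#' Re-checks the invariants (nonnegative weights summing to 1 per facility)
#' on a RAM read back from disk.
#'
#' @param ram Tibble `facility_id`, `service`, `resource_category`, `weight`.
#' @return The RAM with class `rems_ram`.
#' @export
validate_ram <- function(ram) {
  ram <- as_tibble(ram)
  if (any(ram$weight < 0)) abort("RAM weights must be nonnegative.")
  sums <- ram %>%
    group_by(.data$facility_id) %>%
    summarise(s = sum(.data$weight), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort(paste0("RAM weights do not sum to 1 for facilit(y/ies): ",
                 paste(sums$facility_id[abs(sums$s - 1) > 1e-9], collapse = ", ")),
          class = "rems_config_error")
  }
  if (!inherits(ram, "rems_ram")) class(ram) <- c("rems_ram", class(ram))
  ram
}

#' Distribute facility inflows across RAM cells
#'
#' Each inflow amount is multiplied by the facility's RAM weights, so every
#' Kwacha reaching the facility is assigned to a (service, resource category)
#' cell and cells sum back to the inflow.
#'
#' @param inflows Tibble from [cascade()] (`facility`, `year`, `quarter`,
#'   `funding_source`, `amount`).
#' @param ram A `rems_ram`.
#' @param on_missing_ram `"error"` aborts listing facilities with inflow but
#'   no RAM; `"report"` leaves those inflows unallocated so they surface in
#'   the data-quality report.
#' @return Tibble `facility`, `year`, `quarter`, `service`,
#'   `resource_category`, `funding_source`, `amount`; attribute
#'   `unallocated` holds skipped inflows under `"report"`.
#' @export
allocate_ram <- function(inflows, ram, on_missing_ram = c("error", "report")) {
  on_missing_ram <- match.arg(on_missing_ram)
  ram <- validate_ram(ram)
  missing <- setdiff(unique(inflows$facility), unique(ram$facility_id))
  if (length(missing) > 0 && on_missing_ram == "error") {
    abort(paste0("No RAM for facilit(y/ies) with inflow: ",
                 paste(sort(missing), collapse = ", ")),
          class = "rems_config_error")
  }
  covered <- filter(inflows, !.data$facility %in% missing)
  skipped <- filter(inflows, .data$facility %in% missing)
  out <- covered %>%
    inner_join(ram, by = c("facility" = "facility_id"),
               relationship = "many-to-many") %>%
    mutate(amount = .data$amount * .data$weight) %>%
    select("facility", "year", "quarter", "service", "resource_category",
           "funding_source", "amount") %>%
    arrange(.data$facility, .data$year, .data$quarter, .data$service,
            .data$resource_category, .data$funding_source)
  attr(out, "unallocated") <- skipped
  out
}

#' @export
print.rems_ram <- function(x, ...) {
  cat(sprintf("<rems_ram> %d facilities x %d services x %d categories\n",
              n_distinct(x$facility_id), n_distinct(x$service),
              n_distinct(x$resource_category)))
  NextMethod()
}

#' Tidy a RAM
#'
#' @param x A `rems_ram`.
#' @param ... Unused.
#' @return The weight tibble (one row per facility x service x category cell).
#' @exportS3Method generics::tidy
#' @export
tidy.rems_ram <- function(x, ...) {
  as_tibble(unclass_ram(x))
}

#' Summarise a RAM
#'
#' @param x A `rems_ram`.
#' @param ... Unused.
#' @return One-row tibble: facility, service, category counts and the maximum
#'   deviation of per-facility weight sums from 1.
#' @exportS3Method generics::glance
#' @export
glance.rems_ram <- function(x, ...) {
  sums <- x %>% group_by(.data$facility_id) %>%
    summarise(s = sum(.data$weight), .groups = "drop")
  tibble(
    n_facilities = n_distinct(x$facility_id),
    n_services = n_distinct(x$service),
    n_categories = n_distinct(x$resource_category),
    max_weight_sum_error = max(abs(sums$s - 1))
  )
}

unclass_ram <- function(x) {
  class(x) <- setdiff(class(x), "rems_ram")
  x
}
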