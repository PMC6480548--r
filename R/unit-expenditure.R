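# Step two of the linkage: divide allocated service expenditure by same-
# quarter output volume, decomposed by resource category, plus roll-ups and
# the above-facility share.

#' Compute quarterly unit expenditure
#'
#' Joins allocated expenditure with output volumes on (facility, service,
#' quarter). Resource categories are summed into the total before division;
#' per-category unit values are carried in wide `unit_<category>` columns.
#' Anomalies never abort — they become statused records: `zero_volume`
#' (reported 0 output), `missing_volume` (no volume row at all) and
#' `zero_expenditure` (output with no allocated money, a possible RAM
#' omission). Division is performed only for `ok` records, so
#' `unit_total x volume` reconstructs `total_amount` exactly.
#'
#' @param allocated Tibble from [allocate_ram()].
#' @param volumes Tibble from [read_volumes()].
#' @return Tibble `facility`, `service`, `year`, `quarter`, `volume`,
#'   `total_amount`, `unit_total`, `unit_<category>`..., `status`.
#' @export
compute_unit_expenditure <- function(allocated, volumes) {
  categories <- sort(unique(allocated$resource_category))
  by_cat <- allocated %>%
    group_by(.data$facility, .data$service, .data$year, .data$quarter,
             .data$resource_category) %>%
    summarise(amount = sum(.data$amount), .groups = "drop")
  spent <- by_cat %>%
    group_by(.data$facility, .data$service, .data$year, .data$quarter) %>%
    summarise(total_amount = sum(.data$amount), .groups = "drop")
  vol <- volumes %>%
    rename(facility = "facility_id") %>%
    select("facility", "service", "year", "quarter", "count")
  joined <- full_join(spent, vol,
                      by = c("facility", "service", "year", "quarter")) %>%
    mutate(
      total_amount = ifelse(is.na(.data$total_amount), 0, .data$total_amount),
      status = case_when(
        is.na(.data$count) ~ "missing_volume",
        .data$count == 0 ~ "zero_volume",
        .data$total_amount == 0 ~ "zero_expenditure",
        TRUE ~ "ok"
      ),
      unit_total = ifelse(.data$status == "ok",
                          .data$total_amount / .data$count, NA_real_)
    ) %>%
    rename(volume = "count")
  cat_wide <- by_cat %>%
    tidyr::pivot_wider(names_from = "resource_category",
                       values_from = "amount",
                       names_prefix = "cat_", values_fill = 0)
  out <- left_join(joined, cat_wide,
                   by = c("facility", "service", "year", "quarter"))
  for (cc in categories) {
    amt <- out[[paste0("cat_", cc)]]
    amt[is.na(amt)] <- 0
    out[[paste0("unit_", cc)]] <- ifelse(out$status == "ok", amt / out$volume,
                                         NA_real_)
    out[[paste0("cat_", cc)]] <- NULL
  }
  out %>%
    select("facility", "service", "year", "quarter", "volume", "total_amount",
           "unit_total", dplyr::starts_with("unit_"), "status") %>%
    arrange(.data$facility, .data$service, .data$year, .data$quarter)
}

#' Roll up unit expenditure
#'
#' Aggregates facility-level unit-expenditure records over any subset of
#' `district`, `province`, `facility`, `service`, `quarter`. Group unit
#' expenditure is the volume-weighted ratio of sums
#' (total amount of ok records / total volume of ok records) — never the mean
#' of facility unit values — so aggregation conserves money. Records without
#' a usable denominator are excluded from the ratio but counted in
#' `n_flagged`. A `mean_unit` diagnostic column (simple mean of ok facility
#' unit values) is included for comparison.
#'
#' @param units Tibble from [compute_unit_expenditure()].
#' @param hierarchy A `rems_hierarchy`, used to map facilities to districts
#'   and provinces.
#' @param by Character vector of grouping keys, a subset of
#'   `c("province", "district", "facility", "service", "quarter")`.
#' @return Aggregated tibble with `total_amount`, `volume`, `unit_total`,
#'   `mean_unit`, `n_ok`, `n_flagged`.
#' @export
rollup <- function(units, hierarchy, by = c("district", "service", "quarter")) {
  allowed <- c("province", "district", "facility", "service", "quarter")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown roll-up key(s): ", paste(bad, collapse = ", ")))
  }
  fm <- facility_lookup(hierarchy)
  df <- units %>% left_join(fm, by = "facility")
  keys <- character()
  if ("province" %in% by) keys <- c(keys, "province")
  if ("district" %in% by) keys <- c(keys, "district")
  if ("facility" %in% by) keys <- c(keys, "facility")
  if ("service" %in% by) keys <- c(keys, "service")
  if ("quarter" %in% by) keys <- c(keys, "year", "quarter")
  df %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      grp_amount = sum(.data$total_amount),
      grp_ok_amount = sum(.data$total_amount[.data$status == "ok"]),
      grp_volume = sum(.data$volume[.data$status == "ok"]),
      grp_n_ok = sum(.data$status == "ok"),
      grp_n_flagged = sum(.data$status != "ok"),
      grp_mean_unit = if (any(.data$status == "ok")) {
        mean(.data$unit_total[.data$status == "ok"])
      } else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(unit_total = ifelse(.data$grp_volume > 0,
                               .data$grp_ok_amount / .data$grp_volume,
                               NA_real_)) %>%
    select(all_of(keys), total_amount = "grp_amount", volume = "grp_volume",
           "unit_total", mean_unit = "grp_mean_unit", n_ok = "grp_n_ok",
           n_flagged = "grp_n_flagged") %>%
    arrange(across(all_of(keys)))
}

#' Above-facility expenditure share
#'
#' The fraction of HIV-related expenditure retained above the facility level:
#' `above / (above + inflows)` per group, in `[0, 1]`. Groups with no money at
#' all get `NA`.
#'
#' @param above Tibble from [cascade()] (`above_facility`).
#' @param inflows Tibble from [cascade()] (`inflows`).
#' @param by Grouping keys, a subset of `c("quarter", "level",
#'   "funding_source")`.
#' @return Tibble with `above_amount`, `inflow_amount`, `share`.
#' @export
above_facility_share <- function(above, inflows, by = "quarter") {
  allowed <- c("quarter", "level", "funding_source")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown grouping key(s): ", paste(bad, collapse = ", ")))
  }
  keys <- character()
  if ("quarter" %in% by) keys <- c(keys, "year", "quarter")
  if ("level" %in% by) keys <- c(keys, "level")
  if ("funding_source" %in% by) keys <- c(keys, "funding_source")
  ab_keys <- keys
  in_keys <- setdiff(keys, "level")
  ab <- above %>%
    group_by(across(all_of(ab_keys))) %>%
    summarise(above_amount = sum(.data$amount), .groups = "drop")
  fl <- inflows %>%
    group_by(across(all_of(in_keys))) %>%
    summarise(inflow_amount = sum(.data$amount), .groups = "drop")
  joined <- if ("level" %in% by) {
    # inflows have no level; compare each level's retention against all
    # facility inflows in the same period/source group
    full_join(ab, fl, by = in_keys)
  } else {
    full_join(ab, fl, by = keys)
  }
  joined %>%
    mutate(
      above_amount = ifelse(is.na(.data$above_amount), 0, .data$above_amount),
      inflow_amount = ifelse(is.na(.data$inflow_amount), 0, .data$inflow_amount),
      share = ifelse(.data$above_amount + .data$inflow_amount > 0,
                     .data$above_amount /
                       (.data$above_amount + .data$inflow_amount),
                     NA_real_)
    ) %>%
    arrange(across(all_of(keys)))
}
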