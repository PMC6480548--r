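# Dashboard-style comparisons: robust outlier flags, trends, unit-cost vs
# volume quadrant views and data-quality reporting. All functions are pure:
# identical inputs give identical outputs.

#' Flag unit-expenditure outliers
#'
#' Within comparison groups (same service x quarter x district by default, or
#' province), each facility's unit expenditure is scored with a robust z:
#' `(x - median) / (1.4826 * MAD)`. Facilities with `|z|` above the threshold
#' are flagged high or low relative to the group standard. Groups smaller than
#' `min_group` yield no flags and a `group_too_small` note; groups with zero
#' MAD (all equal) yield a `degenerate_spread` note. Only `status == "ok"`
#' records are scored.
#'
#' @param units Tibble from [compute_unit_expenditure()].
#' @param hierarchy A `rems_hierarchy`.
#' @param scope `"district"` or `"province"` comparison groups.
#' @param threshold Robust-z threshold (default 3).
#' @param min_group Minimum group size (default 5).
#' @param facility_type Optional facility-type filter (hospitals and health
#'   centres differ structurally).
#' @return Tibble of flags (`facility`, `service`, `year`, `quarter`,
#'   `unit_total`, `center`, `spread`, `score`, `direction`, `note`) with a
#'   `notes` attribute listing skipped groups and why.
#' @export
flag_outliers <- function(units, hierarchy, scope = c("district", "province"),
                          threshold = 3, min_group = 5, facility_type = NULL) {
  scope <- match.arg(scope)
  fm <- facility_lookup(hierarchy)
  df <- units %>%
    filter(.data$status == "ok") %>%
    left_join(fm, by = "facility")
  if (!is.null(facility_type)) {
    df <- filter(df, .data$facility_type %in% !!facility_type)
  }
  group_col <- scope
  group_keys <- c("service", "year", "quarter", group_col)
  scored <- df %>%
    group_by(across(all_of(group_keys))) %>%
    mutate(
      n_group = n(),
      center = median(.data$unit_total),
      spread = mad(.data$unit_total, constant = 1.4826)
    ) %>%
    ungroup()
  notes <- scored %>%
    distinct(across(all_of(c(group_keys, "n_group", "spread")))) %>%
    mutate(note = case_when(
      .data$n_group < min_group ~ "group_too_small",
      .data$spread == 0 ~ "degenerate_spread",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$note)) %>%
    select(all_of(c("service", "year", "quarter", group_col, "note")))
  flags <- scored %>%
    filter(.data$n_group >= min_group, .data$spread > 0) %>%
    mutate(score = (.data$unit_total - .data$center) / .data$spread,
           direction = ifelse(.data$score > 0, "high", "low")) %>%
    filter(abs(.data$score) > threshold) %>%
    select("facility", "service", "year", "quarter", "unit_total", "volume",
           all_of(group_col), "center", "spread", "score", "direction") %>%
    arrange(.data$service, .data$year, .data$quarter, .data$facility)
  attr(flags, "notes") <- notes
  flags
}

#' Quarterly unit-expenditure trends
#'
#' Orders each facility x service series by quarter and computes the
#' quarter-over-quarter relative change `(current - previous) / previous`.
#' The first quarter of a series, and any quarter following a zero, has no
#' change value; the latter is flagged `previous_zero`.
#'
#' @param units Tibble from [compute_unit_expenditure()] (or a roll-up with a
#'   `unit_total` column and `facility`/`service` keys).
#' @param facility,service Optional filters.
#' @return `rems_trend` tibble with `unit_total`, `change`, `change_note`.
#' @export
trend <- function(units, facility = NULL, service = NULL) {
  df <- if ("status" %in% names(units)) {
    filter(units, .data$status == "ok")
  } else {
    filter(units, !is.na(.data$unit_total))
  }
  if (!is.null(facility)) df <- filter(df, .data$facility %in% !!facility)
  if (!is.null(service)) df <- filter(df, .data$service %in% !!service)
  out <- df %>%
    mutate(qidx = .data$year * 4L + .data$quarter) %>%
    arrange(.data$facility, .data$service, .data$qidx) %>%
    group_by(.data$facility, .data$service) %>%
    mutate(
      prev = dplyr::lag(.data$unit_total),
      change = ifelse(!is.na(.data$prev) & .data$prev != 0,
                      (.data$unit_total - .data$prev) / .data$prev, NA_real_),
      change_note = case_when(
        is.na(.data$prev) ~ "first_quarter",
        .data$prev == 0 ~ "previous_zero",
        TRUE ~ NA_character_
      )
    ) %>%
    ungroup() %>%
    select("facility", "service", "year", "quarter", "unit_total", "change",
           "change_note")
  class(out) <- c("rems_trend", class(out))
  out
}

#' Unit-cost versus volume view
#'
#' For one service and quarter, tabulates each facility's unit expenditure
#' against its output volume and tags quadrants split at the group medians —
#' the view used to spot facilities whose costs do not fall with scale (high
#' volume, high unit cost) or that run small and cheap. Facilities sitting
#' exactly on a median are tagged `boundary`. Rows are ordered by descending
#' unit expenditure.
#'
#' @param units Tibble from [compute_unit_expenditure()].
#' @param service Service code.
#' @param year,quarter Period.
#' @param scope_facilities Optional facility-id filter (e.g. one district).
#' @return `rems_cost_volume` tibble: `facility`, `unit_total`, `volume`,
#'   `quadrant`.
#' @export
cost_volume_view <- function(units, service, year, quarter,
                             scope_facilities = NULL) {
  df <- units %>%
    filter(.data$status == "ok", .data$service == !!service,
           .data$year == !!year, .data$quarter == !!quarter)
  if (!is.null(scope_facilities)) {
    df <- filter(df, .data$facility %in% !!scope_facilities)
  }
  if (nrow(df) == 0) {
    out <- tibble(facility = character(), unit_total = numeric(),
                  volume = integer(), quadrant = character())
    class(out) <- c("rems_cost_volume", class(out))
    return(out)
  }
  med_cost <- median(df$unit_total)
  med_vol <- median(df$volume)
  out <- df %>%
    mutate(quadrant = case_when(
      .data$unit_total == med_cost | .data$volume == med_vol ~ "boundary",
      .data$unit_total > med_cost & .data$volume > med_vol ~ "high_volume_high_cost",
      .data$unit_total > med_cost & .data$volume < med_vol ~ "low_volume_high_cost",
      .data$unit_total < med_cost & .data$volume > med_vol ~ "high_volume_low_cost",
      TRUE ~ "low_volume_low_cost"
    )) %>%
    select("facility", "unit_total", "volume", "quadrant") %>%
    arrange(dplyr::desc(.data$unit_total), .data$facility)
  attr(out, "medians") <- c(unit_total = med_cost, volume = med_vol)
  attr(out, "service") <- service
  attr(out, "period") <- quarter_label(year, quarter)
  class(out) <- c("rems_cost_volume", class(out))
  out
}

#' Data-quality report
#'
#' Lists the anomalies the dashboard is designed to surface — facilities whose
#' unit-expenditure records carry `missing_volume`, `zero_volume` or
#' `zero_expenditure` status, and facilities that received inflows but have no
#' RAM — with counts per district.
#'
#' @param units Tibble from [compute_unit_expenditure()].
#' @param inflows Tibble from [cascade()].
#' @param ram A `rems_ram` (or `NULL` when unavailable).
#' @param hierarchy A `rems_hierarchy`.
#' @return A list: `issues` (one row per facility x service x quarter issue)
#'   and `by_district` (issue counts per district x type).
#' @export
data_quality_report <- function(units, inflows, ram, hierarchy) {
  fm <- facility_lookup(hierarchy)
  issues <- units %>%
    filter(.data$status != "ok") %>%
    select("facility", "service", "year", "quarter", issue = "status")
  if (!is.null(ram)) {
    no_ram <- setdiff(unique(inflows$facility), unique(ram$facility_id))
  } else {
    no_ram <- unique(inflows$facility)
  }
  if (length(no_ram) > 0) {
    ram_issues <- inflows %>%
      filter(.data$facility %in% no_ram) %>%
      distinct(.data$facility, .data$year, .data$quarter) %>%
      mutate(service = NA_character_, issue = "ram_missing") %>%
      select("facility", "service", "year", "quarter", "issue")
    issues <- bind_rows(issues, ram_issues)
  }
  issues <- issues %>%
    left_join(fm, by = "facility") %>%
    select("district", "facility", "service", "year", "quarter", "issue") %>%
    arrange(.data$district, .data$facility, .data$issue, .data$year,
            .data$quarter)
  by_district <- issues %>%
    count(.data$district, .data$issue, name = "n_issues") %>%
    arrange(.data$district, .data$issue)
  list(issues = issues, by_district = by_district)
}
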