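# Administrative hierarchy, chart-of-accounts keys, calendar quarters and the
# service / resource-category configuration consumed by every other stage.

ORG_LEVELS <- c("national", "provincial", "district", "facility")

#' Default resource categories
#'
#' The expense classes into which facility expenditure is decomposed.
#' @return Character vector of category codes.
#' @export
default_resource_categories <- function() {
  c("personnel", "drugs", "supplies", "equipment", "vehicles", "other")
}

#' Default service lines
#'
#' The HIV service lines tracked by default: testing and counselling (HTC),
#' elimination of mother-to-child transmission (EMTCT) and antiretroviral
#' therapy (ART), each with the output indicator whose count is the unit-cost
#' denominator.
#' @return A tibble with columns `code`, `label`, `output_indicator`.
#' @export
default_services <- function() {
  tibble(
    code = c("HTC", "EMTCT", "ART"),
    label = c(
      "HIV testing and counselling",
      "Elimination of mother-to-child transmission",
      "Antiretroviral therapy"
    ),
    output_indicator = c(
      "clients tested and counselled",
      "patient visits for EMTCT",
      "ART patient visits"
    )
  )
}

# ---------------------------------------------------------------------------
# Account codes: "head/department/unit/programme[/activity]" opaque segments.

#' Parse hierarchical account codes
#'
#' Account codes join 4 or 5 non-empty segments with `/`
#' (head/department/unit/programme and optionally activity). Segments are
#' opaque text, so zero-padded codes round-trip unchanged.
#'
#' @param code_text Character vector of account codes.
#' @return A tibble with one row per code: `code`, `head`, `department`,
#'   `unit`, `programme`, `activity` (`NA` for 4-segment codes), `n_segments`.
#' @examples
#' parse_account("01/02/03/04")
#' @export
parse_account <- function(code_text) {
  stopifnot(is.character(code_text))
  parts <- strsplit(code_text, "/", fixed = TRUE)
  bad <- vapply(parts, function(p) {
    !(length(p) %in% c(4L, 5L)) || any(!nzchar(p)) || any(is.na(p))
  }, logical(1)) | is.na(code_text) |
    # a trailing "/" is dropped by strsplit; catch it explicitly
    grepl("/$", code_text)
  if (any(bad)) {
    abort(paste0(
      "Malformed account code(s): ",
      paste(sprintf("'%s'", code_text[bad]), collapse = ", "),
      ". Expected 4 or 5 non-empty '/'-separated segments."
    ), class = "rems_parse_error")
  }
  tibble(
    code = code_text,
    head = vapply(parts, `[`, "", 1L),
    department = vapply(parts, `[`, "", 2L),
    unit = vapply(parts, `[`, "", 3L),
    programme = vapply(parts, `[`, "", 4L),
    activity = vapply(parts, function(p) if (length(p) == 5L) p[5L] else NA_character_, ""),
    n_segments = lengths(parts)
  )
}

#' Format parsed account codes back to text
#'
#' Inverse of [parse_account()]: joins the non-missing segments with `/`.
#'
#' @param accounts Tibble as returned by [parse_account()].
#' @return Character vector of account codes.
#' @export
format_account <- function(accounts) {
  base <- paste(accounts$head, accounts$department, accounts$unit,
                accounts$programme, sep = "/")
  ifelse(is.na(accounts$activity), base, paste(base, accounts$activity, sep = "/"))
}

# Number of segments of each pattern/code; prefix patterns may have 1..5.
account_segments <- function(x) lengths(strsplit(x, "/", fixed = TRUE))

# TRUE where `pattern` is a segment-wise prefix of `code` (both scalars or
# equal-length vectors).
account_prefix_match <- function(pattern, code) {
  startsWith(code, pattern) &
    (nchar(code) == nchar(pattern) |
       substr(code, nchar(pattern) + 1L, nchar(pattern) + 1L) == "/")
}

# ---------------------------------------------------------------------------
# Calendar quarters, encoded as "YYYYQn" labels with year/q companion columns.

#' Quarter helpers
#'
#' Quarters are calendar quarters labelled `"2016Q1"`. `parse_quarter()`
#' splits labels into year and quarter number, `quarter_label()` rebuilds
#' them, `quarter_index()` maps to a totally ordered integer, and
#' `quarter_range()` enumerates the inclusive sequence between two quarters.
#'
#' @param x Character vector of quarter labels.
#' @return `parse_quarter()`: tibble with `year` and `quarter`;
#'   `quarter_range()`: character vector of labels.
#' @examples
#' quarter_range("2015Q4", "2016Q2")
#' @export
parse_quarter <- function(x) {
  ok <- grepl("^[0-9]{4}Q[1-4]$", x)
  if (any(!ok)) {
    abort(paste0("Malformed quarter label(s): ",
                 paste(sprintf("'%s'", x[!ok]), collapse = ", ")),
          class = "rems_parse_error")
  }
  tibble(year = as.integer(substr(x, 1, 4)),
         quarter = as.integer(substr(x, 6, 6)))
}

#' @rdname parse_quarter
#' @param year,quarter Integer vectors.
#' @export
quarter_label <- function(year, quarter) sprintf("%04dQ%d", year, quarter)

#' @rdname parse_quarter
#' @export
quarter_index <- function(x) {
  q <- parse_quarter(x)
  q$year * 4L + (q$quarter - 1L)
}

#' @rdname parse_quarter
#' @param start,end Quarter labels, `start <= end`.
#' @export
quarter_range <- function(start, end) {
  i0 <- quarter_index(start)
  i1 <- quarter_index(end)
  if (i0 > i1) abort(sprintf("Quarter range start %s is after end %s.", start, end))
  idx <- seq(i0, i1)
  quarter_label(idx %/% 4L, idx %% 4L + 1L)
}

# ---------------------------------------------------------------------------
# Administrative hierarchy.

#' Validate an administrative hierarchy
#'
#' Checks that org units form a strict four-level tree
#' (national > provincial > district > facility): one national root, unique
#' ids, every child exactly one level below its parent, no cycles. All
#' violations are collected and reported together.
#'
#' @param units Data frame with columns `id`, `name`, `level`, `parent_id`
#'   (`NA` for the root) and `facility_type` (`NA` above facility level).
#' @return A `rems_hierarchy` object: the validated tibble plus facility,
#'   district and province lookups.
#' @export
validate_hierarchy <- function(units) {
  units <- as_tibble(units)
  required <- c("id", "name", "level", "parent_id", "facility_type")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    abort(paste0("org_units is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  if (anyDuplicated(units$id)) {
    dups <- unique(units$id[duplicated(units$id)])
    problems <- c(problems, paste0("duplicate unit id(s): ", paste(dups, collapse = ", ")))
  }
  bad_level <- !units$level %in% ORG_LEVELS
  if (any(bad_level)) {
    problems <- c(problems, paste0("unknown level(s): ",
                                   paste(unique(units$level[bad_level]), collapse = ", ")))
  }
  roots <- units$id[units$level == "national" | is.na(units$parent_id)]
  is_root_ok <- units$level == "national" & is.na(units$parent_id)
  if (sum(is_root_ok) != 1 || length(unique(roots)) != sum(is_root_ok)) {
    problems <- c(problems, sprintf(
      "expected exactly one national root without a parent; found %d candidate(s)",
      length(unique(roots))))
  }
  non_root <- units[!(units$level == "national" & is.na(units$parent_id)), , drop = FALSE]
  orphan <- !is.na(non_root$parent_id) & !non_root$parent_id %in% units$id
  if (any(orphan)) {
    problems <- c(problems, paste0("orphan parent id(s): ",
                                   paste(unique(non_root$parent_id[orphan]), collapse = ", ")))
  }
  no_parent <- is.na(non_root$parent_id) & non_root$level != "national"
  if (any(no_parent)) {
    problems <- c(problems, paste0("non-national unit(s) without a parent: ",
                                   paste(non_root$id[no_parent], collapse = ", ")))
  }
  # level-step check: each child exactly one rank below its parent
  lvl <- setNames(match(units$level, ORG_LEVELS), units$id)
  has_parent <- !is.na(units$parent_id) & units$parent_id %in% units$id
  child_lvl <- lvl[units$id[has_parent]]
  parent_lvl <- lvl[units$parent_id[has_parent]]
  skip <- which(child_lvl != parent_lvl + 1L)
  if (length(skip) > 0) {
    ids <- units$id[has_parent][skip]
    problems <- c(problems, paste0("level skip at unit(s): ", paste(ids, collapse = ", ")))
  }
  # cycle check via repeated parent-hops (a valid tree terminates in <= 4 hops)
  if (!anyDuplicated(units$id)) {
    parent <- setNames(units$parent_id, units$id)
    cur <- units$id
    for (i in seq_len(length(ORG_LEVELS) + 1L)) cur <- unname(parent[cur])
    cyc <- units$id[!is.na(cur)]
    if (length(cyc) > 0) {
      problems <- c(problems, paste0("cycle involving unit(s): ", paste(cyc, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid org hierarchy:\n- ", paste(problems, collapse = "\n- ")),
          class = "rems_hierarchy_error")
  }

  parent <- setNames(units$parent_id, units$id)
  fac <- units$id[units$level == "facility"]
  facility_map <- tibble(
    facility = fac,
    facility_type = units$facility_type[match(fac, units$id)],
    district = unname(parent[fac]),
    province = unname(parent[unname(parent[fac])])
  )
  structure(
    list(units = units, facility_map = facility_map, parent = parent),
    class = "rems_hierarchy"
  )
}

#' @export
print.rems_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<rems_hierarchy> %d units: %d province(s), %d district(s), %d facilit(y/ies)\n",
    nrow(x$units),
    sum(x$units$level == "provincial"),
    sum(x$units$level == "district"),
    nrow(x$facility_map)
  ))
  invisible(x)
}

#' Hierarchy accessors
#'
#' @param hierarchy A `rems_hierarchy` from [validate_hierarchy()].
#' @param unit_id A unit id.
#' @return `hierarchy_children()`: tibble of direct children;
#'   `hierarchy_facilities()`: character vector of facility ids at or below
#'   `unit_id` (all facilities when `unit_id` is `NULL`);
#'   `facility_lookup()`: facility/district/province/facility_type tibble.
#' @export
hierarchy_children <- function(hierarchy, unit_id) {
  stopifnot(inherits(hierarchy, "rems_hierarchy"))
  filter(hierarchy$units, .data$parent_id == unit_id)
}

#' @rdname hierarchy_children
#' @export
hierarchy_facilities <- function(hierarchy, unit_id = NULL) {
  stopifnot(inherits(hierarchy, "rems_hierarchy"))
  fm <- hierarchy$facility_map
  if (is.null(unit_id)) return(fm$facility)
  lvl <- hierarchy$units$level[match(unit_id, hierarchy$units$id)]
  switch(lvl,
    national = fm$facility,
    provincial = fm$facility[fm$province == unit_id],
    district = fm$facility[fm$district == unit_id],
    facility = unit_id
  )
}

#' @rdname hierarchy_children
#' @export
facility_lookup <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "rems_hierarchy"))
  hierarchy$facility_map
}

unit_level <- function(hierarchy, unit_id) {
  hierarchy$units$level[match(unit_id, hierarchy$units$id)]
}

# ---------------------------------------------------------------------------
# Run configuration.

#' Run configuration
#'
#' Collects the service registry, resource categories and policy toggles used
#' across the pipeline. `read_rems_config()` loads the same structure from a
#' YAML file with top-level keys `services:`, `resource_categories:` and
#' `policies:`.
#'
#' @param services Tibble of service lines (`code`, `label`,
#'   `output_indicator`).
#' @param resource_categories Character vector of category codes.
#' @param negative_amount `"net"` (journal corrections net within key) or
#'   `"reject"`.
#' @param default_hiv_share HIV share for accounts matching no weight pattern.
#' @param equipment_life_years,vehicle_life_years Straight-line annualization
#'   defaults for capital items without an explicit useful life.
#' @param outlier_threshold Robust-z threshold for outlier flags.
#' @param outlier_min_group Minimum comparison-group size.
#' @param outlier_scope `"district"` or `"province"` comparison groups.
#' @return A `rems_config` list.
#' @export
rems_config <- function(services = default_services(),
                        resource_categories = default_resource_categories(),
                        negative_amount = c("net", "reject"),
                        default_hiv_share = 0,
                        equipment_life_years = 5,
                        vehicle_life_years = 8,
                        outlier_threshold = 3,
                        outlier_min_group = 5,
                        outlier_scope = c("district", "province")) {
  negative_amount <- match.arg(negative_amount)
  outlier_scope <- match.arg(outlier_scope)
  services <- as_tibble(services)
  stopifnot(all(c("code", "label", "output_indicator") %in% names(services)))
  if (anyDuplicated(services$code)) abort("Duplicate service codes in config.")
  if (anyDuplicated(resource_categories)) abort("Duplicate resource categories in config.")
  stopifnot(default_hiv_share >= 0, default_hiv_share <= 1,
            equipment_life_years > 0, vehicle_life_years > 0,
            outlier_threshold > 0, outlier_min_group >= 1)
  structure(list(
    services = services,
    resource_categories = resource_categories,
    negative_amount = negative_amount,
    default_hiv_share = default_hiv_share,
    equipment_life_years = equipment_life_years,
    vehicle_life_years = vehicle_life_years,
    outlier_threshold = outlier_threshold,
    outlier_min_group = outlier_min_group,
    outlier_scope = outlier_scope
  ), class = "rems_config")
}

#' @rdname rems_config
#' @param path Path to a YAML config file.
#' @export
read_rems_config <- function(path) {
  raw <- yaml::read_yaml(path)
  services <- if (!is.null(raw$services)) {
    bind_rows(lapply(raw$services, as_tibble))
  } else {
    default_services()
  }
  cats <- raw$resource_categories %||% default_resource_categories()
  pol <- raw$policies %||% list()
  rems_config(
    services = services,
    resource_categories = unlist(cats),
    negative_amount = pol$negative_amount %||% "net",
    default_hiv_share = pol$default_hiv_share %||% 0,
    equipment_life_years = pol$equipment_life_years %||% 5,
    vehicle_life_years = pol$vehicle_life_years %||% 8,
    outlier_threshold = pol$outlier_threshold %||% 3,
    outlier_min_group = pol$outlier_min_group %||% 5,
    outlier_scope = pol$outlier_scope %||% "district"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
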