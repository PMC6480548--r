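# Readers, validators and the deterministic CSV writer for all pipeline
# tables. Every reader validates against the hierarchy/config and reports all
# offending rows at once, with 1-based data line numbers for provenance.

read_csv_checked <- function(path, col_types) {
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0(
      "Malformed CSV ", path, ":\n",
      paste(sprintf("- row %d col %s: expected %s, got '%s'",
                    prob$row, prob$col, prob$expected, prob$actual),
            collapse = "\n")
    ), class = "rems_io_error")
  }
  df
}

fail_rows <- function(df, bad, what, detail) {
  if (!any(bad)) return(invisible(NULL))
  rows <- df$.row[bad]
  abort(paste0(
    what, ":\n",
    paste(sprintf("- row %d: %s", rows, detail[bad]), collapse = "\n")
  ), class = "rems_io_error")
}

#' Read an expenditure ledger
#'
#' Reads `account_code,org_unit_id,year,quarter,amount,funding_source` rows,
#' validates account codes, org units and periods, and aggregates duplicate
#' `(account, org unit, quarter, funding source)` keys by summation. Negative
#' amounts (journal corrections) are netted within the key under the default
#' `negative_amount = "net"` policy; a key whose net is negative is an error,
#' as is any negative row under `"reject"`.
#'
#' @param path CSV path.
#' @param hierarchy A [validate_hierarchy()] result.
#' @param config A [rems_config()].
#' @return Tibble with one row per key: `account_code`, `org_unit_id`, `year`,
#'   `quarter`, `funding_source`, `amount`.
#' @export
read_ledger <- function(path, hierarchy, config = rems_config()) {
  df <- read_csv_checked(path, readr::cols(
    account_code = readr::col_character(),
    org_unit_id = readr::col_character(),
    year = readr::col_integer(),
    quarter = readr::col_integer(),
    amount = readr::col_double(),
    funding_source = readr::col_character()
  ))
  df$.row <- seq_len(nrow(df))
  df$funding_source[is.na(df$funding_source)] <- "unspecified"
  validate_ledger(df, hierarchy, config)
}

validate_ledger <- function(df, hierarchy, config = rems_config()) {
  if (!".row" %in% names(df)) df$.row <- seq_len(nrow(df))
  acc_ok <- vapply(df$account_code, function(a) {
    !inherits(try(parse_account(a), silent = TRUE), "try-error")
  }, logical(1))
  fail_rows(df, !acc_ok, "Unparseable account code(s) in ledger",
            sprintf("'%s'", df$account_code))
  fail_rows(df, !df$org_unit_id %in% hierarchy$units$id,
            "Unknown org unit(s) in ledger", sprintf("'%s'", df$org_unit_id))
  fail_rows(df, is.na(df$amount), "Non-numeric amount(s) in ledger",
            rep("amount missing or not a number", nrow(df)))
  fail_rows(df, is.na(df$quarter) | !df$quarter %in% 1:4 | is.na(df$year),
            "Invalid period(s) in ledger",
            sprintf("year=%s quarter=%s", df$year, df$quarter))
  if (config$negative_amount == "reject") {
    fail_rows(df, df$amount < 0, "Negative amount(s) in ledger (policy: reject)",
              sprintf("%.2f", df$amount))
  }
  out <- df %>%
    group_by(.data$account_code, .data$org_unit_id, .data$year, .data$quarter,
             .data$funding_source) %>%
    summarise(amount = sum(.data$amount), .groups = "drop") %>%
    arrange(.data$account_code, .data$org_unit_id, .data$year, .data$quarter,
            .data$funding_source)
  if (any(out$amount < 0)) {
    bad <- out[out$amount < 0, , drop = FALSE]
    abort(paste0(
      "Ledger key(s) net to a negative amount:\n",
      paste(sprintf("- %s @ %s %dQ%d [%s]: %.2f", bad$account_code,
                    bad$org_unit_id, bad$year, bad$quarter,
                    bad$funding_source, bad$amount), collapse = "\n")
    ), class = "rems_io_error")
  }
  out
}

#' Read facility output volumes
#'
#' Reads `facility_id,service,year,quarter,count` rows as reported by a
#' routine health-information system. A missing (facility, service, quarter)
#' combination stays absent — absence is a data-quality signal, distinct from
#' a reported zero. Duplicate keys are an error: the reporting system carries
#' one value per indicator-period, so a duplicate indicates a broken export.
#'
#' @inheritParams read_ledger
#' @return Tibble `facility_id`, `service`, `year`, `quarter`, `count`.
#' @export
read_volumes <- function(path, hierarchy, config = rems_config()) {
  df <- read_csv_checked(path, readr::cols(
    facility_id = readr::col_character(),
    service = readr::col_character(),
    year = readr::col_integer(),
    quarter = readr::col_integer(),
    count = readr::col_integer()
  ))
  df$.row <- seq_len(nrow(df))
  validate_volumes(df, hierarchy, config)
}

validate_volumes <- function(df, hierarchy, config = rems_config()) {
  if (!".row" %in% names(df)) df$.row <- seq_len(nrow(df))
  lvl <- unit_level(hierarchy, df$facility_id)
  fail_rows(df, is.na(lvl) | lvl != "facility",
            "Volume rows for non-facility org unit(s)",
            sprintf("'%s'", df$facility_id))
  fail_rows(df, !df$service %in% config$services$code,
            "Unregistered service(s) in volumes", sprintf("'%s'", df$service))
  fail_rows(df, is.na(df$count) | df$count < 0,
            "Negative or missing count(s) in volumes", sprintf("%s", df$count))
  key <- paste(df$facility_id, df$service, df$year, df$quarter, sep = "\r")
  fail_rows(df, duplicated(key) | duplicated(key, fromLast = TRUE),
            "Duplicate (facility, service, quarter) volume row(s)",
            sprintf("%s/%s %dQ%d", df$facility_id, df$service, df$year, df$quarter))
  df %>%
    select(-".row") %>%
    arrange(.data$facility_id, .data$service, .data$year, .data$quarter)
}

#' Read HIV-share weights
#'
#' `account_pattern,hiv_share` rows: the fraction of each matching account's
#' expenditure that supports the programme. Patterns are account-code
#' prefixes; duplicates are a load-time error.
#'
#' @param path CSV path.
#' @return Tibble `account_pattern`, `hiv_share`.
#' @export
read_hiv_weights <- function(path) {
  df <- read_csv_checked(path, readr::cols(
    account_pattern = readr::col_character(),
    hiv_share = readr::col_double()
  ))
  validate_hiv_weights(df)
}

validate_hiv_weights <- function(df) {
  df <- as_tibble(df)
  if (anyDuplicated(df$account_pattern)) {
    dups <- unique(df$account_pattern[duplicated(df$account_pattern)])
    abort(paste0("Duplicate HIV-share pattern(s): ", paste(dups, collapse = ", ")),
          class = "rems_io_error")
  }
  if (any(df$hiv_share < 0 | df$hiv_share > 1 | is.na(df$hiv_share))) {
    abort("hiv_share values must lie in [0, 1].", class = "rems_io_error")
  }
  arrange(df, .data$account_pattern)
}

#' Read flow-down rules
#'
#' One row per (account pattern, source unit, child): `account_pattern,
#' source_unit_id,retained_share,child_unit_id,child_share` with
#' `retained_share` repeated across a rule's rows. A blank `child_share`
#' requests the documented fallback split, proportional to the number of
#' facilities beneath each child. Shares of each rule must total 1.
#'
#' @inheritParams read_ledger
#' @return Tibble of validated rule rows.
#' @export
read_flow_rules <- function(path, hierarchy) {
  df <- read_csv_checked(path, readr::cols(
    account_pattern = readr::col_character(),
    source_unit_id = readr::col_character(),
    retained_share = readr::col_double(),
    child_unit_id = readr::col_character(),
    child_share = readr::col_double()
  ))
  validate_flow_rules(df, hierarchy)
}

validate_flow_rules <- function(df, hierarchy) {
  df <- as_tibble(df)
  problems <- character()
  parent_of <- hierarchy$parent
  bad_child <- !is.na(df$child_unit_id) &
    (is.na(parent_of[df$child_unit_id]) |
       parent_of[df$child_unit_id] != df$source_unit_id)
  if (any(bad_child)) {
    problems <- c(problems, sprintf(
      "child '%s' is not a hierarchy child of '%s'",
      df$child_unit_id[bad_child], df$source_unit_id[bad_child]))
  }
  if (any(df$retained_share < 0 | df$retained_share > 1, na.rm = TRUE)) {
    problems <- c(problems, "retained_share outside [0, 1]")
  }
  by_rule <- df %>%
    group_by(.data$account_pattern, .data$source_unit_id) %>%
    summarise(
      retained = .data$retained_share[1],
      consistent = n_distinct(.data$retained_share) == 1,
      explicit = sum(.data$child_share, na.rm = TRUE),
      n_fallback = sum(is.na(.data$child_share) & !is.na(.data$child_unit_id)),
      .groups = "drop"
    )
  if (any(!by_rule$consistent)) {
    problems <- c(problems, sprintf(
      "rule (%s @ %s) repeats different retained_share values",
      by_rule$account_pattern[!by_rule$consistent],
      by_rule$source_unit_id[!by_rule$consistent]))
  }
  closed <- by_rule$n_fallback == 0 &
    abs(by_rule$retained + by_rule$explicit - 1) > 1e-9
  if (any(closed, na.rm = TRUE)) {
    problems <- c(problems, sprintf(
      "rule (%s @ %s): retained + child shares = %.12f, expected 1",
      by_rule$account_pattern[closed], by_rule$source_unit_id[closed],
      by_rule$retained[closed] + by_rule$explicit[closed]))
  }
  key <- paste(df$account_pattern, df$source_unit_id, df$child_unit_id, sep = "\r")
  if (anyDuplicated(key)) {
    problems <- c(problems, "duplicate (pattern, source, child) rows")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid flow-down rules:\n- ", paste(problems, collapse = "\n- ")),
          class = "rems_io_error")
  }
  arrange(df, .data$account_pattern, .data$source_unit_id, .data$child_unit_id)
}

#' Read a facility assessment
#'
#' Ingredients-based line items: `facility_id,item_id,description,
#' resource_category,annual_quantity,standard_unit_cost,dedicated_service,
#' useful_life_years`. `dedicated_service` is a service code or `SHARED`.
#'
#' @inheritParams read_ledger
#' @return Validated tibble of assessment line items.
#' @export
read_assessment <- function(path, hierarchy, config = rems_config()) {
  df <- read_csv_checked(path, readr::cols(
    facility_id = readr::col_character(),
    item_id = readr::col_character(),
    description = readr::col_character(),
    resource_category = readr::col_character(),
    annual_quantity = readr::col_double(),
    standard_unit_cost = readr::col_double(),
    dedicated_service = readr::col_character(),
    useful_life_years = readr::col_double()
  ))
  df$.row <- seq_len(nrow(df))
  lvl <- unit_level(hierarchy, df$facility_id)
  fail_rows(df, is.na(lvl) | lvl != "facility",
            "Assessment rows for non-facility unit(s)", sprintf("'%s'", df$facility_id))
  fail_rows(df, !df$resource_category %in% config$resource_categories,
            "Unregistered resource categor(y/ies)", sprintf("'%s'", df$resource_category))
  fail_rows(df, !(df$dedicated_service %in% c(config$services$code, "SHARED")),
            "Unregistered dedicated service(s)", sprintf("'%s'", df$dedicated_service))
  fail_rows(df, is.na(df$annual_quantity) | df$annual_quantity < 0,
            "Negative annual quantity", sprintf("%s", df$annual_quantity))
  fail_rows(df, is.na(df$standard_unit_cost) | df$standard_unit_cost < 0,
            "Negative standard unit cost", sprintf("%s", df$standard_unit_cost))
  df %>% select(-".row") %>% arrange(.data$facility_id, .data$item_id)
}

#' Read service schedules
#'
#' `facility_id,service,sessions_per_week,location,relative_annual_volume`:
#' when and where each service runs and its relative volume, used to apportion
#' shared resources.
#'
#' @inheritParams read_ledger
#' @return Validated schedule tibble.
#' @export
read_schedule <- function(path, hierarchy, config = rems_config()) {
  df <- read_csv_checked(path, readr::cols(
    facility_id = readr::col_character(),
    service = readr::col_character(),
    sessions_per_week = readr::col_double(),
    location = readr::col_character(),
    relative_annual_volume = readr::col_double()
  ))
  df$.row <- seq_len(nrow(df))
  lvl <- unit_level(hierarchy, df$facility_id)
  fail_rows(df, is.na(lvl) | lvl != "facility",
            "Schedule rows for non-facility unit(s)", sprintf("'%s'", df$facility_id))
  fail_rows(df, !df$service %in% config$services$code,
            "Unregistered service(s) in schedule", sprintf("'%s'", df$service))
  fail_rows(df, is.na(df$sessions_per_week) | df$sessions_per_week < 0 |
              is.na(df$relative_annual_volume) | df$relative_annual_volume < 0,
            "Negative schedule value(s)", rep("sessions/volume < 0", nrow(df)))
  has_live <- df %>%
    group_by(.data$facility_id) %>%
    summarise(live = any(.data$relative_annual_volume > 0), .groups = "drop")
  if (any(!has_live$live)) {
    abort(paste0("Facilit(y/ies) with no service of positive relative volume: ",
                 paste(has_live$facility_id[!has_live$live], collapse = ", ")),
          class = "rems_io_error")
  }
  df %>% select(-".row") %>% arrange(.data$facility_id, .data$service)
}

#' Read org units
#'
#' `id,name,level,parent_id,facility_type` rows; validation is delegated to
#' [validate_hierarchy()].
#'
#' @param path CSV path.
#' @return A `rems_hierarchy`.
#' @export
read_org_units <- function(path) {
  df <- read_csv_checked(path, readr::cols(
    id = readr::col_character(),
    name = readr::col_character(),
    level = readr::col_character(),
    parent_id = readr::col_character(),
    facility_type = readr::col_character()
  ))
  validate_hierarchy(df)
}

# ---------------------------------------------------------------------------
# Deterministic writer.

MONEY_COL_RE <- "^(amount|total_amount|contribution|annual_cost|unit_total|unit_[a-z]+)$"

#' Write a result table deterministically
#'
#' Emits UTF-8, comma-separated, LF-terminated CSV with all fields quoted.
#' Rows are sorted ascending by every non-money column (left to right) and
#' money columns (`amount`, `total_amount`, `annual_cost`, `unit_*`,
#' `contribution`) are serialized at fixed 2-decimal precision using
#' round-half-even, so a write/read cycle reproduces the file exactly.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param conserve_by Optional character vector of grouping columns: within
#'   each group, money columns are rounded with a largest-remainder adjustment
#'   so written rows still sum to the written group total.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, conserve_by = NULL) {
  df <- as_tibble(records)
  money <- grepl(MONEY_COL_RE, names(df)) &
    vapply(df, is.numeric, logical(1))
  keys <- names(df)[!money]
  if (length(keys) > 0 && nrow(df) > 0) {
    df <- arrange(df, across(all_of(keys)))
  }
  for (col in names(df)[money]) {
    if (!is.null(conserve_by) && nrow(df) > 0) {
      df <- df %>%
        group_by(across(all_of(conserve_by))) %>%
        mutate(!!col := round_conserving(.data[[col]], digits = 2)) %>%
        ungroup()
    } else {
      df[[col]] <- round(df[[col]], 2)
    }
    df[[col]] <- formatC(df[[col]], format = "f", digits = 2)
  }
  # quote = "all" only quotes character columns, so make every cell character
  df <- mutate(df, across(everything(), as.character))
  readr::write_csv(df, path, quote = "all", eol = "\n", progress = FALSE, na = "")
  invisible(path)
}

#' Round a vector while conserving its sum
#'
#' Rounds each element to `digits` decimals with a largest-remainder
#' adjustment so the rounded elements sum exactly to the (half-even) rounded
#' total. Used at write time so serialized allocation rows still add up to the
#' serialized total.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector, same length and (rounded) sum as `x`.
#' @export
round_conserving <- function(x, digits = 2) {
  if (length(x) == 0) return(x)
  f <- 10^digits
  target <- round(sum(x) * f)
  lo <- floor(x * f + 1e-9)
  rem <- x * f - lo
  need <- as.integer(target - sum(lo))
  add <- integer(length(x))
  if (need > 0) {
    ord <- order(rem, decreasing = TRUE)
    idx <- rep_len(ord, need)
    for (i in idx) add[i] <- add[i] + 1L
  } else if (need < 0) {
    ord <- order(rem, decreasing = FALSE)
    idx <- rep_len(ord, -need)
    for (i in idx) add[i] <- add[i] - 1L
  }
  (lo + add) / f
}
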