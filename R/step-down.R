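# Step one of the expenditure-output linkage: isolate the HIV-related portion
# of each ledger line with elicited account-level shares, then cascade it down
# the administrative hierarchy with flow-down rules, retaining above-facility
# expenses at each level.

#' Match the most specific HIV-share weight
#'
#' Weight patterns are account-code prefixes. An account takes the share of
#' the most specific (longest) matching pattern; accounts matching nothing
#' take `default` (0 = non-HIV unless stated otherwise).
#'
#' @param account_code Character vector of full account codes.
#' @param weights Tibble `account_pattern`, `hiv_share`
#'   (see [read_hiv_weights()]).
#' @param default Share for unmatched accounts.
#' @return Numeric vector of shares in `[0, 1]`.
#' @export
match_weight <- function(account_code, weights, default = 0) {
  weights <- validate_hiv_weights(weights)
  pat_depth <- account_segments(weights$account_pattern)
  vapply(account_code, function(code) {
    hits <- account_prefix_match(weights$account_pattern, code)
    if (!any(hits)) return(default)
    d <- pat_depth[hits]
    best <- max(d)
    cand <- which(hits)[d == best]
    if (length(cand) > 1) {
      abort(sprintf(
        "Account '%s' matches %d equally specific patterns: %s", code,
        length(cand), paste(weights$account_pattern[cand], collapse = ", ")),
        class = "rems_config_error")
    }
    weights$hiv_share[cand]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Apply an HIV share to an amount
#'
#' @param amount Nonnegative currency amounts.
#' @param share Fractions in `[0, 1]`.
#' @return `amount * share`.
#' @export
apply_hiv_share <- function(amount, share) {
  if (any(share < 0 | share > 1)) abort("HIV shares must lie in [0, 1].")
  amount * share
}

#' Isolate HIV-related expenditure
#'
#' Applies [match_weight()] to an aggregated ledger and scales each amount by
#' its HIV share, dropping keys whose share is zero.
#'
#' @param ledger Tibble from [read_ledger()].
#' @param weights HIV-share weight table.
#' @param default Share for unmatched accounts.
#' @return The ledger with columns `hiv_share` and `hiv_amount` added,
#'   zero-share rows removed.
#' @export
isolate_hiv <- function(ledger, weights, default = 0) {
  shares <- match_weight(unique(ledger$account_code), weights, default = default)
  lut <- setNames(shares, unique(ledger$account_code))
  ledger %>%
    mutate(hiv_share = unname(lut[.data$account_code]),
           hiv_amount = .data$amount * .data$hiv_share) %>%
    filter(.data$hiv_share > 0)
}

# Most specific flow-down rule for (account, unit); NULL when none exists.
find_rule <- function(rules, account_code, unit_id) {
  cand <- rules[rules$source_unit_id == unit_id &
                  account_prefix_match(rules$account_pattern, account_code), ,
                drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  depth <- account_segments(cand$account_pattern)
  best <- cand[depth == max(depth), , drop = FALSE]
  if (n_distinct(best$account_pattern) > 1) {
    abort(sprintf(
      "Account '%s' at unit '%s' matches equally specific rule patterns: %s",
      account_code, unit_id,
      paste(unique(best$account_pattern), collapse = ", ")),
      class = "rems_config_error")
  }
  best
}

# Resolve a rule's children into (child_unit_id, child_share), applying the
# facility-count-proportional fallback for NA shares.
rule_children <- function(rule, hierarchy) {
  kids <- rule[!is.na(rule$child_unit_id), , drop = FALSE]
  if (nrow(kids) == 0) {
    return(tibble(child_unit_id = character(), child_share = numeric()))
  }
  shares <- kids$child_share
  if (any(is.na(shares))) {
    remaining <- 1 - rule$retained_share[1] - sum(shares, na.rm = TRUE)
    nf <- vapply(kids$child_unit_id[is.na(shares)],
                 function(u) length(hierarchy_facilities(hierarchy, u)),
                 numeric(1))
    if (sum(nf) == 0) {
      abort(sprintf(
        "Fallback split for rule (%s @ %s) impossible: no facilities beneath children.",
        rule$account_pattern[1], rule$source_unit_id[1]),
        class = "rems_config_error")
    }
    shares[is.na(shares)] <- remaining * nf / sum(nf)
  }
  tibble(child_unit_id = kids$child_unit_id, child_share = shares)
}

#' Check flow-down rule coverage
#'
#' Walks every (account, controlling unit) present in the HIV expenditure
#' table down the hierarchy and collects all (account, unit) pairs lacking a
#' rule, so gaps are reported in full before any allocation runs.
#'
#' @param hiv Tibble from [isolate_hiv()].
#' @param rules Tibble from [read_flow_rules()].
#' @param hierarchy A `rems_hierarchy`.
#' @return Tibble of gaps (`account_code`, `org_unit_id`); zero rows when
#'   coverage is complete.
#' @export
flow_rule_gaps <- function(hiv, rules, hierarchy) {
  seeds <- distinct(hiv, .data$account_code, .data$org_unit_id)
  gaps <- list()
  walk <- function(account, unit) {
    if (unit_level(hierarchy, unit) == "facility") return(invisible(NULL))
    rule <- find_rule(rules, account, unit)
    if (is.null(rule)) {
      gaps[[length(gaps) + 1L]] <<- tibble(account_code = account, org_unit_id = unit)
      return(invisible(NULL))
    }
    if (rule$retained_share[1] < 1) {
      for (child in rule_children(rule, hierarchy)$child_unit_id) walk(account, child)
    }
  }
  for (i in seq_len(nrow(seeds))) walk(seeds$account_code[i], seeds$org_unit_id[i])
  if (length(gaps) == 0) {
    tibble(account_code = character(), org_unit_id = character())
  } else {
    distinct(bind_rows(gaps))
  }
}

#' Cascade HIV expenditure down to facilities
#'
#' Each HIV-share amount controlled above facility level is split by its
#' flow-down rule: the retained share becomes an above-facility expense at the
#' controlling unit's level and each child receives its fraction, recursively,
#' until money reaches facilities. Facility-controlled amounts pass straight
#' through. Money is conserved: for every quarter and funding source,
#' inflows + above-facility equals the HIV-share expenditure.
#'
#' @param hiv Tibble from [isolate_hiv()].
#' @param rules Tibble from [read_flow_rules()].
#' @param hierarchy A `rems_hierarchy`.
#' @return A list with tibbles `inflows` (`facility`, `year`, `quarter`,
#'   `funding_source`, `amount`), `above_facility` (`org_unit`, `level`,
#'   `year`, `quarter`, `funding_source`, `amount`) and `provenance`
#'   (per-inflow source-account contributions).
#' @export
cascade <- function(hiv, rules, hierarchy) {
  gaps <- flow_rule_gaps(hiv, rules, hierarchy)
  if (nrow(gaps) > 0) {
    abort(paste0(
      "Missing flow-down rule(s):\n",
      paste(sprintf("- account %s at unit %s", gaps$account_code, gaps$org_unit_id),
            collapse = "\n")
    ), class = "rems_config_error")
  }
  inflow_rows <- list()
  above_rows <- list()
  descend <- function(account, unit, amount, rec) {
    if (amount == 0) return(invisible(NULL))
    if (unit_level(hierarchy, unit) == "facility") {
      inflow_rows[[length(inflow_rows) + 1L]] <<- tibble(
        facility = unit, year = rec$year, quarter = rec$quarter,
        funding_source = rec$funding_source, source_account = account,
        source_unit = rec$org_unit_id, contribution = amount)
      return(invisible(NULL))
    }
    rule <- find_rule(rules, account, unit)
    retained <- rule$retained_share[1]
    if (retained > 0) {
      above_rows[[length(above_rows) + 1L]] <<- tibble(
        org_unit = unit, level = unit_level(hierarchy, unit),
        year = rec$year, quarter = rec$quarter,
        funding_source = rec$funding_source, source_account = account,
        amount = amount * retained)
    }
    kids <- rule_children(rule, hierarchy)
    for (i in seq_len(nrow(kids))) {
      descend(account, kids$child_unit_id[i], amount * kids$child_share[i], rec)
    }
  }
  for (i in seq_len(nrow(hiv))) {
    rec <- hiv[i, ]
    descend(rec$account_code, rec$org_unit_id, rec$hiv_amount, rec)
  }
  provenance <- if (length(inflow_rows) > 0) {
    bind_rows(inflow_rows) %>%
      group_by(.data$facility, .data$year, .data$quarter, .data$funding_source,
               .data$source_account, .data$source_unit) %>%
      summarise(contribution = sum(.data$contribution), .groups = "drop") %>%
      arrange(.data$facility, .data$year, .data$quarter, .data$funding_source,
              .data$source_account)
  } else {
    tibble(facility = character(), year = integer(), quarter = integer(),
           funding_source = character(), source_account = character(),
           source_unit = character(), contribution = numeric())
  }
  inflows <- provenance %>%
    group_by(.data$facility, .data$year, .data$quarter, .data$funding_source) %>%
    summarise(amount = sum(.data$contribution), .groups = "drop")
  above <- if (length(above_rows) > 0) {
    bind_rows(above_rows) %>%
      group_by(.data$org_unit, .data$level, .data$year, .data$quarter,
               .data$funding_source) %>%
      summarise(amount = sum(.data$amount), .groups = "drop") %>%
      arrange(.data$org_unit, .data$year, .data$quarter, .data$funding_source)
  } else {
    tibble(org_unit = character(), level = character(), year = integer(),
           quarter = integer(), funding_source = character(), amount = numeric())
  }
  list(inflows = inflows, above_facility = above, provenance = provenance)
}

#' Run step-down allocation end to end
#'
#' Convenience wrapper: [isolate_hiv()] then [cascade()], with a conservation
#' check that per (quarter, funding source) the cascade outputs equal the
#' HIV-share expenditure to within `tol` currency units.
#'
#' @inheritParams cascade
#' @param ledger Tibble from [read_ledger()].
#' @param weights HIV-share weight table.
#' @param config A [rems_config()]; supplies the unmatched-account default.
#' @param tol Conservation tolerance, currency units.
#' @return As [cascade()], plus a `conservation` tibble of residuals.
#' @export
step_down <- function(ledger, weights, rules, hierarchy,
                      config = rems_config(), tol = 1e-6) {
  hiv <- isolate_hiv(ledger, weights, default = config$default_hiv_share)
  out <- cascade(hiv, rules, hierarchy)
  total_in <- hiv %>%
    group_by(.data$year, .data$quarter, .data$funding_source) %>%
    summarise(hiv_amount = sum(.data$hiv_amount), .groups = "drop")
  total_out <- bind_rows(
    out$inflows %>% select("year", "quarter", "funding_source", "amount"),
    out$above_facility %>% select("year", "quarter", "funding_source", "amount")
  ) %>%
    group_by(.data$year, .data$quarter, .data$funding_source) %>%
    summarise(allocated = sum(.data$amount), .groups = "drop")
  conservation <- full_join(total_in, total_out,
                            by = c("year", "quarter", "funding_source")) %>%
    mutate(
      hiv_amount = ifelse(is.na(.data$hiv_amount), 0, .data$hiv_amount),
      allocated = ifelse(is.na(.data$allocated), 0, .data$allocated),
      residual = .data$allocated - .data$hiv_amount
    )
  if (any(abs(conservation$residual) > tol)) {
    abort(sprintf("Step-down conservation violated: max |residual| = %.3g",
                  max(abs(conservation$residual))),
          class = "rems_conservation_error")
  }
  c(out, list(conservation = conservation, hiv = hiv))
}
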