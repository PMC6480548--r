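# Shared fixtures and independent oracles used across the suite.

# A small fixed hierarchy: 1 national, 2 provinces, 2 districts each,
# 2 facilities per district (8 facilities).
toy_units <- function() {
  tibble::tibble(
    id = c("NAT",
           "P1", "P2",
           "P1D1", "P1D2", "P2D1", "P2D2",
           "F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8"),
    name = c("National", "Prov 1", "Prov 2",
             "Dist 11", "Dist 12", "Dist 21", "Dist 22",
             paste("Fac", 1:8)),
    level = c("national", rep("provincial", 2), rep("district", 4),
              rep("facility", 8)),
    parent_id = c(NA, "NAT", "NAT",
                  "P1", "P1", "P2", "P2",
                  "P1D1", "P1D1", "P1D2", "P1D2", "P2D1", "P2D1", "P2D2", "P2D2"),
    facility_type = c(rep(NA, 7),
                      rep(c("hospital", "rural health centre"), 4))
  )
}

toy_hierarchy <- function() validate_hierarchy(toy_units())

# Independent brute-force oracle for the step-down cascade: enumerates every
# (account -> ... -> facility) path in the rule table, multiplying fractions
# along the way. Deliberately naive and separate from the engine: it builds
# the full path list rather than recursing over amounts.
oracle_cascade <- function(hiv, rules, hierarchy) {
  # expand every rule into explicit child fractions (same fallback contract)
  expand_paths <- function(account, unit, frac) {
    lvl <- hierarchy$units$level[match(unit, hierarchy$units$id)]
    if (lvl == "facility") {
      return(list(list(kind = "inflow", unit = unit, frac = frac)))
    }
    cand <- rules[rules$source_unit_id == unit, , drop = FALSE]
    cand <- cand[vapply(cand$account_pattern, function(p) {
      startsWith(account, p) &&
        (nchar(account) == nchar(p) ||
           substr(account, nchar(p) + 1, nchar(p) + 1) == "/")
    }, logical(1)), , drop = FALSE]
    if (nrow(cand) == 0) stop("oracle: missing rule")
    depth <- lengths(strsplit(cand$account_pattern, "/", fixed = TRUE))
    cand <- cand[depth == max(depth), , drop = FALSE]
    retained <- cand$retained_share[1]
    out <- list()
    if (retained > 0) {
      out[[1]] <- list(kind = "above", unit = unit, frac = frac * retained)
    }
    kids <- cand[!is.na(cand$child_unit_id), , drop = FALSE]
    shares <- kids$child_share
    if (any(is.na(shares))) {
      remaining <- 1 - retained - sum(shares, na.rm = TRUE)
      nf <- vapply(kids$child_unit_id[is.na(shares)], function(u) {
        length(hierarchy_facilities(hierarchy, u))
      }, numeric(1))
      shares[is.na(shares)] <- remaining * nf / sum(nf)
    }
    for (i in seq_len(nrow(kids))) {
      out <- c(out, expand_paths(account, kids$child_unit_id[i],
                                 frac * shares[i]))
    }
    out
  }
  inflow <- list()
  above <- list()
  for (i in seq_len(nrow(hiv))) {
    rec <- hiv[i, ]
    paths <- expand_paths(rec$account_code, rec$org_unit_id, 1)
    for (p in paths) {
      row <- tibble::tibble(
        unit = p$unit, year = rec$year, quarter = rec$quarter,
        funding_source = rec$funding_source,
        amount = rec$hiv_amount * p$frac)
      if (p$kind == "inflow") inflow[[length(inflow) + 1]] <- row
      else above[[length(above) + 1]] <- row
    }
  }
  agg <- function(rows) {
    if (length(rows) == 0) {
      return(tibble::tibble(unit = character(), year = integer(),
                            quarter = integer(), funding_source = character(),
                            amount = numeric()))
    }
    dplyr::bind_rows(rows) |>
      dplyr::group_by(unit, year, quarter, funding_source) |>
      dplyr::summarise(amount = sum(amount), .groups = "drop") |>
      dplyr::arrange(unit, year, quarter, funding_source)
  }
  list(inflows = agg(inflow), above = agg(above))
}

# Random cascade instance generator for property/oracle tests: a random
# hierarchy slice plus random rules whose shares sum to 1 at every node.
random_cascade_instance <- function(n_accounts = 10, n_provinces = 2,
                                    n_districts = 2, n_facilities = 2,
                                    n_quarters = 2) {
  units <- list(tibble::tibble(id = "NAT", name = "National",
                               level = "national", parent_id = NA_character_,
                               facility_type = NA_character_))
  for (p in seq_len(n_provinces)) {
    pid <- paste0("P", p)
    units[[length(units) + 1]] <- tibble::tibble(
      id = pid, name = pid, level = "provincial", parent_id = "NAT",
      facility_type = NA_character_)
    for (d in seq_len(n_districts)) {
      did <- paste0(pid, "D", d)
      units[[length(units) + 1]] <- tibble::tibble(
        id = did, name = did, level = "district", parent_id = pid,
        facility_type = NA_character_)
      for (f in seq_len(n_facilities)) {
        units[[length(units) + 1]] <- tibble::tibble(
          id = paste0(did, "F", f), name = "fac", level = "facility",
          parent_id = did, facility_type = "hospital")
      }
    }
  }
  units <- dplyr::bind_rows(units)
  hierarchy <- validate_hierarchy(units)

  random_shares <- function(n) {
    x <- runif(n + 1)
    x / sum(x) # first = retained, rest = children
  }
  rules <- list()
  non_leaf <- units[units$level != "facility", , drop = FALSE]
  for (i in seq_len(nrow(non_leaf))) {
    u <- non_leaf$id[i]
    kids <- units$id[!is.na(units$parent_id) & units$parent_id == u]
    s <- random_shares(length(kids))
    rules[[length(rules) + 1]] <- tibble::tibble(
      account_pattern = "01", source_unit_id = u, retained_share = s[1],
      child_unit_id = kids, child_share = s[-1])
  }
  rules <- dplyr::bind_rows(rules)

  accounts <- sprintf("01/%02d/01/01", seq_len(n_accounts))
  ctrl_units <- sample(units$id, n_accounts, replace = TRUE)
  hiv <- tidyr::crossing(
    tibble::tibble(account_code = accounts, org_unit_id = ctrl_units),
    tibble::tibble(year = 2016L, quarter = seq_len(n_quarters))
  ) |>
    dplyr::mutate(funding_source = "GRZ",
                  amount = round(runif(dplyr::n(), 100, 10000), 2),
                  hiv_share = 1, hiv_amount = amount)
  list(hierarchy = hierarchy, rules = rules, hiv = hiv)
}

# Minimal single-facility inputs used in RAM / unit-expenditure tests.
toy_assessment <- function(facility = "F1") {
  tibble::tibble(
    facility_id = facility,
    item_id = c("I1", "I2", "I3"),
    description = c("HTC counsellor", "ARV drugs", "clinic microscope"),
    resource_category = c("personnel", "drugs", "equipment"),
    annual_quantity = c(1, 1200, 1),
    standard_unit_cost = c(5000, 12.5, 5000),
    dedicated_service = c("HTC", "ART", "SHARED"),
    useful_life_years = c(NA, NA, 5)
  )
}

toy_schedule <- function(facility = "F1") {
  tibble::tibble(
    facility_id = facility,
    service = c("HTC", "EMTCT", "ART"),
    sessions_per_week = c(5, 2, 5),
    location = "facility",
    relative_annual_volume = c(300, 100, 500)
  )
}

expect_tibble_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
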