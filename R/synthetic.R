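# Synthetic-data generator with known ground truth. Construction is
# truth-first: per-facility service volumes and true unit costs are fixed
# first, facility assessments are built so the RAM reproduces the intended
# service x category mix, and ledger accounts, HIV-share weights and flow-down
# rules are synthesized so the cascade delivers exactly the intended facility
# totals plus configured above-facility retention. Running the pipeline on a
# noiseless bundle therefore recovers every true unit cost exactly.

#' Default true unit costs and volume model
#'
#' Kwacha-per-visit unit costs and mean quarterly volumes by facility type and
#' service, on the scale of routinely reported EMTCT visit costs
#' (roughly 125-1300 Kwacha per visit).
#' @return Tibble `facility_type`, `service`, `unit_cost`, `volume_mean`.
#' @export
default_cost_model <- function() {
  tibble(
    facility_type = rep(c("hospital", "urban health centre",
                          "rural health centre"), each = 3),
    service = rep(c("HTC", "EMTCT", "ART"), times = 3),
    unit_cost = c(90, 650, 420, 55, 320, 300, 40, 180, 240),
    volume_mean = c(600, 150, 900, 350, 90, 500, 120, 40, 150)
  )
}

#' Default service resource-category mix
#'
#' Fractions of each service's annual resources by expense category; each
#' service's mix sums to 1.
#' @return Tibble `service`, `resource_category`, `mix`.
#' @export
default_category_mix <- function() {
  cats <- default_resource_categories()
  tibble(
    service = rep(c("HTC", "EMTCT", "ART"), each = length(cats)),
    resource_category = rep(cats, times = 3),
    mix = c(
      0.45, 0.05, 0.25, 0.10, 0.05, 0.10, # HTC
      0.40, 0.20, 0.15, 0.10, 0.05, 0.10, # EMTCT
      0.30, 0.45, 0.10, 0.05, 0.05, 0.05  # ART
    )
  )
}

#' Define a synthetic scenario
#'
#' Fixes the ground truth from which [generate_bundle()] synthesizes a full
#' input set: hierarchy shape, services, true unit costs and volume model per
#' facility type, category mix per service, above-facility retention per
#' level, HIV shares on the synthetic accounts, the fraction of facility
#' funding routed through the national cascading account, and multiplicative
#' ledger noise.
#'
#' @param seed Integer seed; the bundle is deterministic given it.
#' @param n_provinces,districts_per_province,facilities_per_district Hierarchy
#'   shape.
#' @param quarters Quarter labels covered by the run.
#' @param services Service registry tibble.
#' @param cost_model Tibble as [default_cost_model()].
#' @param category_mix Tibble as [default_category_mix()].
#' @param volume_dispersion Negative-binomial size for volume draws.
#' @param noise_sd Standard deviation of multiplicative ledger noise
#'   (`amount x (1 + e)`, `e ~ N(0, noise_sd)`).
#' @param above_facility_fraction Named fractions retained at `national`,
#'   `provincial`, `district` level.
#' @param cascade_fraction Fraction of each facility's (noiseless) funding
#'   delivered through the national step-down stream; the rest arrives through
#'   a facility-controlled account carrying the noise.
#' @param hiv_share_national,hiv_share_facility HIV shares attached to the
#'   synthetic national and facility account patterns.
#' @return A `rems_scenario` list.
#' @export
rems_scenario <- function(seed = 1L,
                          n_provinces = 2L,
                          districts_per_province = 2L,
                          facilities_per_district = 3L,
                          quarters = quarter_range("2016Q1", "2016Q4"),
                          services = default_services(),
                          cost_model = default_cost_model(),
                          category_mix = default_category_mix(),
                          volume_dispersion = 8,
                          noise_sd = 0.1,
                          above_facility_fraction = c(national = 0.15,
                                                      provincial = 0.10,
                                                      district = 0.05),
                          cascade_fraction = 0.5,
                          hiv_share_national = 0.8,
                          hiv_share_facility = 0.6) {
  stopifnot(n_provinces >= 1, districts_per_province >= 1,
            facilities_per_district >= 1, length(quarters) >= 1,
            noise_sd >= 0, volume_dispersion > 0,
            all(above_facility_fraction >= 0),
            all(above_facility_fraction < 1),
            cascade_fraction > 0, cascade_fraction <= 1,
            hiv_share_national > 0, hiv_share_national <= 1,
            hiv_share_facility > 0, hiv_share_facility <= 1)
  stopifnot(all(c("national", "provincial", "district") %in%
                  names(above_facility_fraction)))
  mix_ok <- category_mix %>%
    group_by(.data$service) %>%
    summarise(s = sum(.data$mix), .groups = "drop")
  stopifnot(all(abs(mix_ok$s - 1) < 1e-9), all(category_mix$mix >= 0))
  stopifnot(all(cost_model$unit_cost >= 0), all(cost_model$volume_mean >= 0))
  structure(list(
    seed = as.integer(seed),
    n_provinces = n_provinces,
    districts_per_province = districts_per_province,
    facilities_per_district = facilities_per_district,
    quarters = quarters,
    services = as_tibble(services),
    cost_model = as_tibble(cost_model),
    category_mix = as_tibble(category_mix),
    volume_dispersion = volume_dispersion,
    noise_sd = noise_sd,
    above_facility_fraction = above_facility_fraction,
    cascade_fraction = cascade_fraction,
    hiv_share_national = hiv_share_national,
    hiv_share_facility = hiv_share_facility
  ), class = "rems_scenario")
}

scenario_org_units <- function(sc) {
  types <- unique(sc$cost_model$facility_type)
  rows <- list(tibble(id = "NAT", name = "National", level = "national",
                      parent_id = NA_character_, facility_type = NA_character_))
  k <- 0L
  for (p in seq_len(sc$n_provinces)) {
    pid <- sprintf("P%02d", p)
    rows[[length(rows) + 1L]] <- tibble(
      id = pid, name = paste("Province", p), level = "provincial",
      parent_id = "NAT", facility_type = NA_character_)
    for (d in seq_len(sc$districts_per_province)) {
      did <- sprintf("%sD%02d", pid, d)
      rows[[length(rows) + 1L]] <- tibble(
        id = did, name = sprintf("District %d-%d", p, d), level = "district",
        parent_id = pid, facility_type = NA_character_)
      for (f in seq_len(sc$facilities_per_district)) {
        k <- k + 1L
        fid <- sprintf("%sF%02d", did, f)
        rows[[length(rows) + 1L]] <- tibble(
          id = fid, name = sprintf("Facility %d", k), level = "facility",
          parent_id = did,
          facility_type = types[(k - 1L) %% length(types) + 1L])
      }
    }
  }
  bind_rows(rows)
}

#' Generate a synthetic input bundle
#'
#' Draw order (fixed so new features never perturb earlier draws): (1) one
#' base quarterly volume per facility x service (negative binomial, floored at
#' 1, repeated across quarters — a steady-state caseload, which keeps
#' flow-down rules and RAMs legitimately time-invariant); (2) multiplicative
#' ledger noise per facility x quarter; (3) decoy non-HIV ledger amounts.
#'
#' The ledger carries three account families: a national HIV programme account
#' whose step-down rules retain the configured above-facility fractions and
#' deliver `cascade_fraction` of every facility's noiseless funding; a
#' facility-controlled HIV account carrying the remainder including noise; and
#' a non-HIV decoy matching no weight pattern.
#'
#' @param scenario A [rems_scenario()].
#' @return A `rems_bundle`: all loader-ready input tibbles plus `ground_truth`
#'   (`unit_costs` with the realized noise multiplier, and `above_facility`)
#'   and the validated `hierarchy`.
#' @export
generate_bundle <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "rems_scenario"))
  set.seed(sc$seed)
  org_units <- scenario_org_units(sc)
  hierarchy <- validate_hierarchy(org_units)
  fm <- facility_lookup(hierarchy)
  qt <- parse_quarter(sc$quarters)
  config <- rems_config(services = sc$services)

  # (1) volumes: one base count per facility x service, repeated per quarter
  base <- fm %>%
    inner_join(sc$cost_model, by = "facility_type",
               relationship = "many-to-many") %>%
    arrange(.data$facility, .data$service)
  base$volume <- pmax(1L, rnbinom(nrow(base), size = sc$volume_dispersion,
                                  mu = base$volume_mean))
  base <- base %>%
    mutate(exp_q = .data$unit_cost * .data$volume) # true quarterly expenditure
  volumes <- tidyr::crossing(base, tibble(year = qt$year, quarter = qt$quarter)) %>%
    mutate(count = as.integer(.data$volume)) %>%
    select("facility_id" = "facility", "service", "year", "quarter", "count") %>%
    arrange(.data$facility_id, .data$service, .data$year, .data$quarter)

  fac_total <- base %>%
    group_by(.data$facility, .data$district, .data$province) %>%
    summarise(exp_q = sum(.data$exp_q), .groups = "drop")

  # (2) multiplicative ledger noise per facility x quarter
  noise <- tidyr::crossing(tibble(facility = fac_total$facility),
                           tibble(year = qt$year, quarter = qt$quarter)) %>%
    arrange(.data$facility, .data$year, .data$quarter)
  noise$mult <- 1 + rnorm(nrow(noise), sd = sc$noise_sd)

  # (3) decoy non-HIV ledger amounts per quarter
  decoy_amount <- runif(length(sc$quarters), 1000, 5000)

  lam <- sc$cascade_fraction
  a <- sc$above_facility_fraction
  # step-down geometry, bottom-up: gross each level's receipt up so that after
  # retention the level passes down exactly what its children need
  dist_need <- fac_total %>%
    group_by(.data$district, .data$province) %>%
    summarise(send = lam * sum(.data$exp_q), .groups = "drop") %>%
    mutate(receive = .data$send / (1 - a[["district"]]))
  prov_need <- dist_need %>%
    group_by(.data$province) %>%
    summarise(send = sum(.data$receive), .groups = "drop") %>%
    mutate(receive = .data$send / (1 - a[["provincial"]]))
  nat_send <- sum(prov_need$receive)
  nat_receive <- nat_send / (1 - a[["national"]])

  acct_cascade <- "01/01/01/01"
  acct_facility <- "01/02/01/01"
  acct_decoy <- "02/01/01/01"
  pat_cascade <- "01/01"
  pat_facility <- "01/02"

  rules <- bind_rows(
    tibble(account_pattern = pat_cascade, source_unit_id = "NAT",
           retained_share = a[["national"]],
           child_unit_id = prov_need$province,
           child_share = (1 - a[["national"]]) * prov_need$receive / nat_send),
    dist_need %>%
      group_by(.data$province) %>%
      mutate(child_share = (1 - a[["provincial"]]) *
               .data$receive / sum(.data$receive)) %>%
      ungroup() %>%
      mutate(account_pattern = pat_cascade,
             source_unit_id = .data$province,
             retained_share = a[["provincial"]],
             child_unit_id = .data$district) %>%
      select("account_pattern", "source_unit_id", "retained_share",
             "child_unit_id", "child_share"),
    fac_total %>%
      group_by(.data$district) %>%
      mutate(child_share = (1 - a[["district"]]) *
               .data$exp_q / sum(.data$exp_q)) %>%
      ungroup() %>%
      mutate(account_pattern = pat_cascade,
             source_unit_id = .data$district,
             retained_share = a[["district"]],
             child_unit_id = .data$facility) %>%
      select("account_pattern", "source_unit_id", "retained_share",
             "child_unit_id", "child_share")
  )
  rules <- validate_flow_rules(rules, hierarchy)

  weights <- tibble(account_pattern = c(pat_cascade, pat_facility),
                    hiv_share = c(sc$hiv_share_national, sc$hiv_share_facility))

  fac_ledger <- noise %>%
    left_join(fac_total, by = "facility") %>%
    mutate(
      delivered = .data$exp_q * .data$mult,
      topup = .data$delivered - lam * .data$exp_q
    )
  if (any(fac_ledger$topup < 0)) {
    abort(paste0(
      "Infeasible scenario: noise draw pushes a facility's quarterly funding ",
      "below the cascaded share; lower noise_sd or cascade_fraction."),
      class = "rems_config_error")
  }
  ledger <- bind_rows(
    tibble(account_code = acct_cascade, org_unit_id = "NAT",
           year = qt$year, quarter = qt$quarter,
           amount = nat_receive / sc$hiv_share_national,
           funding_source = "GRZ"),
    fac_ledger %>%
      mutate(account_code = acct_facility, org_unit_id = .data$facility,
             amount = .data$topup / sc$hiv_share_facility,
             funding_source = "GRZ") %>%
      select("account_code", "org_unit_id", "year", "quarter", "amount",
             "funding_source"),
    tibble(account_code = acct_decoy, org_unit_id = "NAT",
           year = qt$year, quarter = qt$quarter, amount = decoy_amount,
           funding_source = "GRZ")
  ) %>%
    arrange(.data$account_code, .data$org_unit_id, .data$year, .data$quarter)

  # facility assessment reproducing unit_cost x volume x category mix
  cats <- config$resource_categories
  budget_truth <- base %>%
    inner_join(sc$category_mix, by = "service",
               relationship = "many-to-many") %>%
    mutate(annual_cost = 4 * .data$exp_q * .data$mix) %>%
    filter(.data$annual_cost > 0)
  capital <- budget_truth$resource_category %in% c("equipment", "vehicles")
  life <- ifelse(budget_truth$resource_category == "equipment",
                 config$equipment_life_years, config$vehicle_life_years)
  assessment <- budget_truth %>%
    mutate(
      item_id = sprintf("%s-%s-%s", .data$facility, .data$service,
                        .data$resource_category),
      description = sprintf("%s for %s", .data$resource_category,
                            .data$service),
      annual_quantity = 1,
      standard_unit_cost = ifelse(capital, .data$annual_cost * life,
                                  .data$annual_cost),
      useful_life_years = ifelse(capital, life, NA_real_)
    ) %>%
    select(facility_id = "facility", "item_id", "description",
           "resource_category", "annual_quantity", "standard_unit_cost",
           dedicated_service = "service", "useful_life_years") %>%
    arrange(.data$facility_id, .data$item_id)

  schedule <- base %>%
    mutate(sessions_per_week = 5, location = "facility",
           relative_annual_volume = 4 * .data$volume) %>%
    select(facility_id = "facility", "service", "sessions_per_week",
           "location", "relative_annual_volume") %>%
    arrange(.data$facility_id, .data$service)

  truth_units <- tidyr::crossing(
    base %>% select("facility", "service", "unit_cost", "volume", "exp_q"),
    tibble(year = qt$year, quarter = qt$quarter)
  ) %>%
    left_join(noise, by = c("facility", "year", "quarter")) %>%
    mutate(true_unit_cost = .data$unit_cost,
           noise_multiplier = .data$mult,
           expected_unit_total = .data$unit_cost * .data$mult,
           expected_total = .data$exp_q * .data$mult) %>%
    select("facility", "service", "year", "quarter", "volume",
           "true_unit_cost", "noise_multiplier", "expected_unit_total",
           "expected_total")

  truth_above <- bind_rows(
    tibble(org_unit = "NAT", level = "national",
           amount = a[["national"]] * nat_receive),
    tibble(org_unit = prov_need$province, level = "provincial",
           amount = a[["provincial"]] * prov_need$receive),
    tibble(org_unit = dist_need$district, level = "district",
           amount = a[["district"]] * dist_need$receive)
  ) %>%
    tidyr::crossing(tibble(year = qt$year, quarter = qt$quarter)) %>%
    arrange(.data$org_unit, .data$year, .data$quarter)

  structure(list(
    scenario = sc,
    config = config,
    org_units = org_units,
    hierarchy = hierarchy,
    ledger = ledger,
    volumes = volumes,
    hiv_weights = weights,
    flow_rules = rules,
    assessment = assessment,
    schedule = schedule,
    ground_truth = list(unit_costs = truth_units, above_facility = truth_above),
    fault_manifest = tibble(fault = character(), detail = character())
  ), class = "rems_bundle")
}

#' @export
print.rems_bundle <- function(x, ...) {
  cat(sprintf(
    "<rems_bundle> seed %d: %d facilities, %d quarters, %d ledger rows, noise_sd %.2f\n",
    x$scenario$seed, nrow(facility_lookup(x$hierarchy)),
    length(x$scenario$quarters), nrow(x$ledger), x$scenario$noise_sd))
  if (nrow(x$fault_manifest) > 0) {
    cat(sprintf("  injected faults: %d\n", nrow(x$fault_manifest)))
  }
  invisible(x)
}

#' Inject data faults into a bundle
#'
#' Deterministically corrupts a generated bundle so the data-quality and
#' outlier pathways can be exercised against a known manifest. Supported
#' faults: `drop_volume` (remove one volume row), `zero_volume` (set one count
#' to 0), `delete_ram` (remove a facility's assessment, so no RAM can be
#' built), `inflate_ledger` (multiply a facility's ledger rows by `factor`,
#' default 10). An empty fault list is the identity.
#'
#' @param bundle A `rems_bundle`.
#' @param faults List of fault descriptors, each a list with `type` and
#'   optional `facility`, `service`, `year`, `quarter`, `factor`. Omitted
#'   fields default to the first matching row/facility.
#' @return The corrupted bundle; `fault_manifest` records each fault.
#' @export
corrupt_bundle <- function(bundle, faults = list()) {
  stopifnot(inherits(bundle, "rems_bundle"))
  for (f in faults) {
    type <- f$type
    if (type %in% c("drop_volume", "zero_volume")) {
      v <- bundle$volumes
      i <- which(
        (is.null(f$facility) | v$facility_id == (f$facility %||% v$facility_id)) &
        (is.null(f$service) | v$service == (f$service %||% v$service)) &
        (is.null(f$year) | v$year == (f$year %||% v$year)) &
        (is.null(f$quarter) | v$quarter == (f$quarter %||% v$quarter))
      )[1]
      if (is.na(i)) abort(sprintf("No volume row matches fault %s.", type))
      detail <- sprintf("%s/%s %dQ%d", v$facility_id[i], v$service[i],
                        v$year[i], v$quarter[i])
      if (type == "drop_volume") {
        bundle$volumes <- v[-i, , drop = FALSE]
      } else {
        bundle$volumes$count[i] <- 0L
      }
    } else if (type == "delete_ram") {
      fac <- f$facility %||% bundle$assessment$facility_id[1]
      bundle$assessment <-
        filter(bundle$assessment, .data$facility_id != fac)
      bundle$schedule <- filter(bundle$schedule, .data$facility_id != fac)
      detail <- fac
    } else if (type == "inflate_ledger") {
      fac <- f$facility %||%
        bundle$ledger$org_unit_id[unit_level(bundle$hierarchy,
                                             bundle$ledger$org_unit_id) == "facility"][1]
      factor <- f$factor %||% 10
      hit <- bundle$ledger$org_unit_id == fac
      if (!any(hit)) abort(sprintf("No ledger rows for facility '%s'.", fac))
      bundle$ledger$amount[hit] <- bundle$ledger$amount[hit] * factor
      detail <- sprintf("%s x%g (%d rows)", fac, factor, sum(hit))
    } else {
      abort(sprintf("Unknown fault type '%s'.", type))
    }
    bundle$fault_manifest <- bind_rows(
      bundle$fault_manifest, tibble(fault = type, detail = detail))
  }
  bundle
}

#' Write / read a bundle as CSV inputs
#'
#' `write_bundle()` serializes every input table of a bundle into a directory
#' (the layout the command-line driver consumes); `read_bundle()` loads and
#' re-validates such a directory.
#'
#' @param bundle A `rems_bundle`.
#' @param dir Directory path.
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: a list of
#'   validated input tables plus the hierarchy and config.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(bundle$org_units, file.path(dir, "org_units.csv"))
  write_table(bundle$ledger, file.path(dir, "expenditures.csv"))
  write_table(bundle$volumes, file.path(dir, "output_volumes.csv"))
  write_table(bundle$hiv_weights, file.path(dir, "hiv_share_weights.csv"))
  write_table(bundle$flow_rules, file.path(dir, "flow_down_rules.csv"))
  write_table(bundle$assessment, file.path(dir, "facility_assessment.csv"))
  write_table(bundle$schedule, file.path(dir, "service_schedule.csv"))
  write_table(bundle$ground_truth$unit_costs,
              file.path(dir, "ground_truth.csv"))
  yaml::write_yaml(list(
    services = lapply(seq_len(nrow(bundle$config$services)), function(i) {
      as.list(bundle$config$services[i, ])
    }),
    resource_categories = as.list(bundle$config$resource_categories)
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @param config Optional [rems_config()]; defaults to `config.yaml` in `dir`
#'   when present.
#' @export
read_bundle <- function(dir, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(dir, "config.yaml")
    config <- if (file.exists(cfg_path)) read_rems_config(cfg_path) else rems_config()
  }
  hierarchy <- read_org_units(file.path(dir, "org_units.csv"))
  list(
    config = config,
    hierarchy = hierarchy,
    ledger = read_ledger(file.path(dir, "expenditures.csv"), hierarchy, config),
    volumes = read_volumes(file.path(dir, "output_volumes.csv"), hierarchy, config),
    hiv_weights = read_hiv_weights(file.path(dir, "hiv_share_weights.csv")),
    flow_rules = read_flow_rules(file.path(dir, "flow_down_rules.csv"), hierarchy),
    assessment = read_assessment(file.path(dir, "facility_assessment.csv"),
                                 hierarchy, config),
    schedule = read_schedule(file.path(dir, "service_schedule.csv"),
                             hierarchy, config)
  )
}
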