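test_that("weight matching picks the most specific prefix", {
  w <- tibble::tibble(account_pattern = c("01", "01/02/03"),
                      hiv_share = c(0.1, 0.5))
  expect_equal(match_weight("01/02/03/04", w), 0.5)
  expect_equal(match_weight("01/03/03/04", w), 0.1)
  expect_equal(match_weight("02/02/03/04", w), 0) # default non-HIV
  expect_equal(match_weight("02/02/03/04", w, default = 0.25), 0.25)
  # "01" must not match "011/..." (segment, not string, prefix)
  expect_equal(match_weight("011/02/03/04", w), 0)
})

test_that("hiv share application is proportional", {
  expect_equal(apply_hiv_share(1000, 0.25), 250)
  expect_equal(apply_hiv_share(1000, 0), 0)
  expect_equal(apply_hiv_share(1000, 1), 1000)
  expect_error(apply_hiv_share(100, 1.5), "\\[0, 1\\]")
})

test_that("cascade reproduces the hand-enumerated national example", {
  # national account, HIV amount 10,000; retain 20%; provinces split 60/40;
  # each province passes all to its single district; each district splits
  # equally between its two facilities
  units <- tibble::tibble(
    id = c("NAT", "P1", "P2", "P1D1", "P2D1", "F1", "F2", "F3", "F4"),
    name = id,
    level = c("national", "provincial", "provincial", "district", "district",
              rep("facility", 4)),
    parent_id = c(NA, "NAT", "NAT", "P1", "P2", "P1D1", "P1D1", "P2D1", "P2D1"),
    facility_type = c(rep(NA, 5), rep("hospital", 4)))
  h <- validate_hierarchy(units)
  rules <- dplyr::bind_rows(
    tibble::tibble(account_pattern = "01", source_unit_id = "NAT",
                   retained_share = 0.2, child_unit_id = c("P1", "P2"),
                   child_share = c(0.48, 0.32)), # 60/40 of the 80% passed down
    tibble::tibble(account_pattern = "01", source_unit_id = c("P1", "P2"),
                   retained_share = 0, child_unit_id = c("P1D1", "P2D1"),
                   child_share = 1),
    tibble::tibble(account_pattern = "01", source_unit_id = "P1D1",
                   retained_share = 0, child_unit_id = c("F1", "F2"),
                   child_share = 0.5),
    tibble::tibble(account_pattern = "01", source_unit_id = "P2D1",
                   retained_share = 0, child_unit_id = c("F3", "F4"),
                   child_share = 0.5))
  hiv <- tibble::tibble(account_code = "01/01/01/01", org_unit_id = "NAT",
                        year = 2016L, quarter = 1L, funding_source = "GRZ",
                        amount = 10000, hiv_share = 1, hiv_amount = 10000)
  out <- cascade(hiv, rules, h)
  expect_equal(out$above_facility$amount, 2000)
  expect_equal(out$above_facility$org_unit, "NAT")
  expect_equal(out$inflows$amount[match(c("F1", "F2", "F3", "F4"),
                                        out$inflows$facility)],
               c(2400, 2400, 1600, 1600))
  # provenance reconstructs each inflow
  expect_equal(sum(out$provenance$contribution), sum(out$inflows$amount))
})

test_that("cascade handles absorbing and pass-through cases", {
  h <- toy_hierarchy()
  absorb <- tibble::tibble(account_pattern = "01", source_unit_id = "NAT",
                           retained_share = 1, child_unit_id = NA_character_,
                           child_share = NA_real_)
  hiv <- tibble::tibble(account_code = "01/01/01/01", org_unit_id = "NAT",
                        year = 2016L, quarter = 1L, funding_source = "GRZ",
                        amount = 500, hiv_share = 1, hiv_amount = 500)
  out <- cascade(hiv, absorb, h)
  expect_equal(nrow(out$inflows), 0)
  expect_equal(out$above_facility$amount, 500)

  # facility-controlled account passes straight through
  hiv_fac <- dplyr::mutate(hiv, org_unit_id = "F3")
  out2 <- cascade(hiv_fac, absorb[0, ], h)
  expect_equal(out2$inflows$facility, "F3")
  expect_equal(out2$inflows$amount, 500)
  expect_equal(nrow(out2$above_facility), 0)
})

test_that("missing rules are reported as a complete gap list before allocating", {
  h <- toy_hierarchy()
  rules <- tibble::tibble(account_pattern = "01", source_unit_id = "NAT",
                          retained_share = 0, child_unit_id = c("P1", "P2"),
                          child_share = 0.5)
  hiv <- tibble::tibble(account_code = "01/01/01/01", org_unit_id = "NAT",
                        year = 2016L, quarter = 1L, funding_source = "GRZ",
                        amount = 100, hiv_share = 1, hiv_amount = 100)
  gaps <- flow_rule_gaps(hiv, rules, h)
  expect_equal(sort(gaps$org_unit_id), c("P1", "P2"))
  err <- tryCatch(cascade(hiv, rules, h), error = identity)
  expect_s3_class(err, "rems_config_error")
  expect_match(conditionMessage(err), "P1")
  expect_match(conditionMessage(err), "P2")
})

test_that("fallback child shares split by facility counts beneath each child", {
  h <- toy_hierarchy() # P1 and P2 hold 4 facilities each
  rules <- dplyr::bind_rows(
    tibble::tibble(account_pattern = "01", source_unit_id = "NAT",
                   retained_share = 0.5, child_unit_id = c("P1", "P2"),
                   child_share = NA_real_),
    tidyr::crossing(tibble::tibble(source_unit_id = c("P1", "P2")),
                    tibble::tibble(dk = 1:2)) |>
      dplyr::mutate(account_pattern = "01", retained_share = 0,
                    child_unit_id = paste0(source_unit_id, "D", dk),
                    child_share = 0.5) |>
      dplyr::select(account_pattern, source_unit_id, retained_share,
                    child_unit_id, child_share),
    tibble::tibble(account_pattern = "01",
                   source_unit_id = rep(c("P1D1", "P1D2", "P2D1", "P2D2"), each = 2),
                   retained_share = 0,
                   child_unit_id = paste0("F", 1:8),
                   child_share = 0.5))
  hiv <- tibble::tibble(account_code = "01/01/01/01", org_unit_id = "NAT",
                        year = 2016L, quarter = 1L, funding_source = "GRZ",
                        amount = 800, hiv_share = 1, hiv_amount = 800)
  out <- cascade(hiv, rules, h)
  # 50% retained, remainder split 4:4 across provinces -> 50 per facility
  expect_equal(out$inflows$amount, rep(50, 8))
  expect_equal(out$above_facility$amount, 400)
})

test_that("cascade equals the brute-force path-enumeration oracle", {
  set.seed(101)
  for (i in 1:10) {
    inst <- random_cascade_instance(
      n_accounts = sample(3:10, 1), n_provinces = sample(1:3, 1),
      n_districts = sample(1:3, 1), n_facilities = sample(1:3, 1))
    out <- cascade(inst$hiv, inst$rules, inst$hierarchy)
    ora <- oracle_cascade(inst$hiv, inst$rules, inst$hierarchy)
    expect_equal(out$inflows$facility, ora$inflows$unit)
    expect_equal(out$inflows$amount, ora$inflows$amount, tolerance = 1e-9)
    ao <- dplyr::arrange(out$above_facility, org_unit, year, quarter)
    expect_equal(ao$amount,
                 ora$above$amount[match(paste(ao$org_unit, ao$year, ao$quarter),
                                        paste(ora$above$unit, ora$above$year,
                                              ora$above$quarter))],
                 tolerance = 1e-9)
  }
})

test_that("cascade conserves money and is linear", {
  set.seed(202)
  for (i in 1:8) {
    inst <- random_cascade_instance()
    out <- cascade(inst$hiv, inst$rules, inst$hierarchy)
    total_in <- sum(inst$hiv$hiv_amount)
    total_out <- sum(out$inflows$amount) + sum(out$above_facility$amount)
    expect_lt(abs(total_in - total_out), 1e-6)

    # conservation per quarter x funding source
    per_q_in <- dplyr::summarise(
      dplyr::group_by(inst$hiv, year, quarter, funding_source),
      x = sum(hiv_amount), .groups = "drop")
    per_q_out <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(
        dplyr::select(out$inflows, year, quarter, funding_source, amount),
        dplyr::select(out$above_facility, year, quarter, funding_source, amount)),
        year, quarter, funding_source),
      x = sum(amount), .groups = "drop")
    expect_equal(per_q_in$x, per_q_out$x, tolerance = 1e-9)

    # homogeneity: cascade(3X) = 3 cascade(X)
    hiv3 <- dplyr::mutate(inst$hiv, hiv_amount = hiv_amount * 3)
    out3 <- cascade(hiv3, inst$rules, inst$hierarchy)
    expect_equal(out3$inflows$amount, out$inflows$amount * 3, tolerance = 1e-9)

    # additivity: cascade(X + X') = cascade(X) + cascade(X') on shared keys
    inst2 <- list(hiv = dplyr::mutate(inst$hiv, hiv_amount = runif(nrow(inst$hiv), 1, 100)),
                  rules = inst$rules, hierarchy = inst$hierarchy)
    outb <- cascade(inst2$hiv, inst$rules, inst$hierarchy)
    hiv_sum <- dplyr::mutate(inst$hiv, hiv_amount = hiv_amount + inst2$hiv$hiv_amount)
    out_sum <- cascade(hiv_sum, inst$rules, inst$hierarchy)
    expect_equal(out_sum$inflows$amount, out$inflows$amount + outb$inflows$amount,
                 tolerance = 1e-9)
  }
})

test_that("equally specific duplicate weight patterns error at match time", {
  w <- tibble::tibble(account_pattern = c("01/02", "01/03"),
                      hiv_share = c(0.3, 0.4))
  expect_equal(match_weight("01/02/03/04", w), 0.3) # distinct prefixes fine
  dup <- tibble::tibble(account_pattern = c("01/02", "01/02"),
                        hiv_share = c(0.3, 0.4))
  expect_error(match_weight("01/02/03/04", dup), "Duplicate")
})
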