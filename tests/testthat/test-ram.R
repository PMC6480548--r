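test_that("line costing annualizes recurrent and capital items", {
  a <- tibble::tibble(
    facility_id = "F1", item_id = c("a", "b", "c"),
    description = "x",
    resource_category = c("supplies", "equipment", "supplies"),
    annual_quantity = c(1200, 1, 0),
    standard_unit_cost = c(2.5, 5000, 10),
    dedicated_service = "HTC",
    useful_life_years = c(NA, 5, NA))
  costed <- cost_lines(a)
  expect_equal(costed$annual_cost, c(3000, 1000, 0))

  # default lives apply when the item has none
  b <- dplyr::mutate(a[2, ], useful_life_years = NA_real_)
  expect_equal(cost_lines(b)$annual_cost, 5000 / 5)
  v <- dplyr::mutate(b, resource_category = "vehicles")
  expect_equal(cost_lines(v)$annual_cost, 5000 / 8)
  expect_error(cost_lines(dplyr::mutate(b, useful_life_years = 0)),
               "useful life")
})

test_that("shared lines split by session-weighted relative volume", {
  sched <- tibble::tibble(
    facility_id = "F1", service = c("A", "B"),
    sessions_per_week = c(1, 1), location = "facility",
    relative_annual_volume = c(300, 100))
  split <- apportion_shared(400, sched)
  expect_equal(split$annual_cost, c(300, 100))
  expect_equal(sum(split$annual_cost), 400)

  # sessions weight the volumes multiplicatively
  sched2 <- dplyr::mutate(sched, sessions_per_week = c(3, 1))
  split2 <- apportion_shared(1000, sched2)
  expect_equal(split2$annual_cost, 1000 * c(900, 100) / 1000)

  # degenerate single-service facility takes the whole line
  expect_equal(apportion_shared(999, sched[1, ])$annual_cost, 999)
  expect_error(apportion_shared(10, sched[0, ]), "no service schedule")
})

test_that("RAM weights are budget shares and sum to one", {
  budget <- tibble::tibble(
    facility_id = "F1", item_id = c("i1", "i2"),
    service = c("HTC", "ART"),
    resource_category = c("personnel", "drugs"),
    annual_cost = c(5000, 15000))
  ram <- compute_ram(budget)
  expect_equal(ram$weight[ram$service == "HTC"], 0.25)
  expect_equal(ram$weight[ram$service == "ART"], 0.75)
  expect_equal(sum(ram$weight), 1)

  single <- compute_ram(budget[1, ])
  expect_equal(single$weight, 1)
  expect_error(compute_ram(dplyr::mutate(budget, annual_cost = 0)),
               "Zero total")
})

test_that("a 5% personnel-for-HTC budget share yields a 5% RAM weight and cell", {
  # operational budget where personnel supporting HTC are 5% of the total
  budget <- tibble::tibble(
    facility_id = "F1",
    item_id = c("htc-staff", "art-drugs", "emtct-staff"),
    service = c("HTC", "ART", "EMTCT"),
    resource_category = c("personnel", "drugs", "personnel"),
    annual_cost = c(500, 7000, 2500))
  ram <- compute_ram(budget)
  w <- ram$weight[ram$service == "HTC" & ram$resource_category == "personnel"]
  expect_equal(w, 0.05)
  inflow <- tibble::tibble(facility = "F1", year = 2016L, quarter = 1L,
                           funding_source = "GRZ", amount = 1000)
  cells <- allocate_ram(inflow, ram)
  cell <- cells$amount[cells$service == "HTC" &
                         cells$resource_category == "personnel"]
  expect_equal(cell, 50) # 5% of each Kwacha reaching the facility
})

test_that("RAM allocation conserves inflows and is linear", {
  budget <- build_budget(toy_assessment(), toy_schedule())
  ram <- compute_ram(budget)
  inflows <- tibble::tibble(
    facility = "F1", year = 2016L, quarter = c(1L, 2L),
    funding_source = "GRZ", amount = c(777, 0))
  cells <- allocate_ram(inflows, ram)
  sums <- dplyr::summarise(dplyr::group_by(cells, quarter),
                           s = sum(amount), .groups = "drop")
  expect_equal(sums$s, c(777, 0), tolerance = 1e-9)
  # linearity
  cells2 <- allocate_ram(dplyr::mutate(inflows, amount = amount * 2.5), ram)
  expect_equal(cells2$amount, cells$amount * 2.5, tolerance = 1e-12)
  # single-cell RAM is the identity
  one <- validate_ram(tibble::tibble(facility_id = "F1", service = "HTC",
                                     resource_category = "personnel",
                                     weight = 1))
  expect_equal(allocate_ram(inflows[1, ], one)$amount, 777)
  # missing RAM errors listing the facility
  expect_error(allocate_ram(dplyr::mutate(inflows, facility = "F9"), ram),
               "F9")
  skipped <- allocate_ram(dplyr::mutate(inflows, facility = "F9"), ram,
                          on_missing_ram = "report")
  expect_equal(nrow(skipped), 0)
  expect_equal(nrow(attr(skipped, "unallocated")), 2)
})

test_that("compute_ram is scale-invariant and matches a brute-force recomputation", {
  set.seed(55)
  services <- c("HTC", "EMTCT", "ART")
  cats <- default_resource_categories()
  for (i in 1:20) {
    n <- sample(3:12, 1)
    budget <- tibble::tibble(
      facility_id = "F1",
      item_id = sprintf("i%02d", seq_len(n)),
      service = sample(services, n, replace = TRUE),
      resource_category = sample(cats, n, replace = TRUE),
      annual_cost = runif(n, 10, 5000))
    ram <- compute_ram(budget)
    expect_equal(sum(ram$weight), 1, tolerance = 1e-12)
    # scale invariance
    k <- runif(1, 0.01, 100)
    ram_k <- compute_ram(dplyr::mutate(budget, annual_cost = annual_cost * k))
    expect_equal(ram_k$weight, ram$weight, tolerance = 1e-9)
    # brute force: loop over cells
    for (j in seq_len(nrow(ram))) {
      cell <- sum(budget$annual_cost[
        budget$service == ram$service[j] &
          budget$resource_category == ram$resource_category[j]])
      expect_equal(ram$weight[j], cell / sum(budget$annual_cost),
                   tolerance = 1e-12)
    }
  }
})

test_that("budget construction routes dedicated and shared lines correctly", {
  budget <- build_budget(toy_assessment(), toy_schedule())
  # dedicated lines keep their service
  expect_equal(budget$service[budget$item_id == "I1"], "HTC")
  expect_equal(budget$annual_cost[budget$item_id == "I1"], 5000)
  expect_equal(budget$annual_cost[budget$item_id == "I2"], 15000)
  # shared equipment line: 5000/5 = 1000/yr split by sessions x volume
  shared <- budget[budget$item_id == "I3", ]
  w <- c(5 * 300, 2 * 100, 5 * 500)
  expect_equal(shared$annual_cost[match(c("HTC", "EMTCT", "ART"), shared$service)],
               1000 * w / sum(w))
  expect_equal(sum(shared$annual_cost), 1000)
})

test_that("tidy and glance summarise a RAM", {
  ram <- compute_ram(build_budget(toy_assessment(), toy_schedule()))
  td <- generics::tidy(ram)
  expect_false(inherits(td, "rems_ram"))
  expect_true(all(c("facility_id", "service", "resource_category", "weight")
                  %in% names(td)))
  g <- generics::glance(ram)
  expect_equal(g$n_facilities, 1)
  expect_lt(g$max_weight_sum_error, 1e-12)
})
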