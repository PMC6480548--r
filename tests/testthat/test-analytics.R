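ok_unit <- function(facility, unit_total, volume = 10, service = "HTC",
                    q = 1L) {
  tibble::tibble(facility = facility, service = service, year = 2016L,
                 quarter = q, volume = as.integer(volume),
                 total_amount = unit_total * volume, unit_total = unit_total,
                 status = "ok")
}

test_that("robust-z outlier flags match a brute-force median/MAD computation", {
  h <- toy_hierarchy()
  # F1..F4 span two districts of P1; use province scope for one group of 4
  u <- ok_unit(c("F1", "F2", "F3", "F4"), c(100, 110, 105, 1000))
  flags <- flag_outliers(u, h, scope = "province", threshold = 3, min_group = 4)
  expect_equal(flags$facility, "F4")
  expect_equal(flags$direction, "high")
  # brute force
  x <- c(100, 110, 105, 1000)
  z <- (1000 - median(x)) / (1.4826 * median(abs(x - median(x))))
  expect_equal(flags$score, z, tolerance = 1e-12)
})

test_that("degenerate and undersized groups yield notes, not flags", {
  h <- toy_hierarchy()
  equal <- ok_unit(c("F1", "F2", "F3", "F4"), rep(50, 4))
  f1 <- flag_outliers(equal, h, scope = "province", min_group = 4)
  expect_equal(nrow(f1), 0)
  expect_true("degenerate_spread" %in% attr(f1, "notes")$note)

  small <- ok_unit(c("F1", "F2", "F3"), c(1, 2, 300))
  f2 <- flag_outliers(small, h, scope = "province", min_group = 5)
  expect_equal(nrow(f2), 0)
  expect_true("group_too_small" %in% attr(f2, "notes")$note)
})

test_that("outlier flags are invariant to currency rescaling and ignore the median", {
  h <- toy_hierarchy()
  set.seed(31)
  for (i in 1:10) {
    vals <- c(runif(7, 90, 110), runif(1, 900, 1100))
    u <- ok_unit(paste0("F", 1:8), vals)
    base <- flag_outliers(u, h, scope = "province", min_group = 4)
    k <- runif(1, 0.1, 1000)
    scaled <- flag_outliers(dplyr::mutate(u, unit_total = unit_total * k,
                                          total_amount = total_amount * k),
                            h, scope = "province", min_group = 4)
    expect_equal(scaled$facility, base$facility)
    expect_equal(scaled$score, base$score, tolerance = 1e-9)
  }
  # a facility exactly at the group median is never flagged
  vals <- c(10, 20, 30, 40, 999)
  u <- ok_unit(paste0("F", 1:5), vals)
  med_fac <- u$facility[u$unit_total == median(vals)]
  flags <- flag_outliers(u, h, scope = "province", min_group = 5, threshold = 0.1)
  expect_false(med_fac %in% flags$facility)
})

test_that("trend computes quarter-over-quarter relative change", {
  u <- dplyr::bind_rows(ok_unit("F1", 100, q = 1L), ok_unit("F1", 120, q = 2L))
  tr <- trend(u)
  expect_equal(tr$change, c(NA, 0.2))
  expect_equal(tr$change_note[1], "first_quarter")

  single <- trend(ok_unit("F1", 100, q = 1L))
  expect_true(all(is.na(single$change)))

  # previous value zero -> undefined, flagged
  u0 <- dplyr::bind_rows(ok_unit("F1", 0, q = 1L), ok_unit("F1", 50, q = 2L))
  tr0 <- trend(u0)
  expect_true(is.na(tr0$change[2]))
  expect_equal(tr0$change_note[2], "previous_zero")
})

test_that("cost-volume view tags quadrants at group medians", {
  u <- dplyr::bind_rows(
    ok_unit("F1", 10, volume = 100), ok_unit("F2", 20, volume = 100),
    ok_unit("F3", 10, volume = 400), ok_unit("F4", 20, volume = 400))
  cv <- cost_volume_view(u, "HTC", 2016L, 1L)
  # all four sit on a median boundary (even group): shift to break ties
  u2 <- dplyr::bind_rows(
    ok_unit("F1", 10, volume = 100), ok_unit("F2", 30, volume = 120),
    ok_unit("F3", 12, volume = 400), ok_unit("F4", 28, volume = 380),
    ok_unit("F5", 20, volume = 250))
  cv2 <- cost_volume_view(u2, "HTC", 2016L, 1L)
  expect_equal(cv2$quadrant[cv2$facility == "F2"], "low_volume_high_cost")
  expect_equal(cv2$quadrant[cv2$facility == "F1"], "low_volume_low_cost")
  expect_equal(cv2$quadrant[cv2$facility == "F4"], "high_volume_high_cost")
  expect_equal(cv2$quadrant[cv2$facility == "F3"], "high_volume_low_cost")
  expect_equal(cv2$quadrant[cv2$facility == "F5"], "boundary")
  # ranking: descending unit cost reproduces the comparison-panel order
  expect_equal(cv2$facility, c("F2", "F4", "F5", "F3", "F1"))
  # single facility -> boundary
  cv1 <- cost_volume_view(ok_unit("F1", 10), "HTC", 2016L, 1L)
  expect_equal(cv1$quadrant, "boundary")
})

test_that("data-quality report lists each anomaly with district counts", {
  h <- toy_hierarchy()
  u <- dplyr::bind_rows(
    ok_unit("F1", 10),
    tibble::tibble(facility = "F2", service = "HTC", year = 2016L,
                   quarter = 1L, volume = NA_integer_, total_amount = 100,
                   unit_total = NA_real_, status = "missing_volume"),
    tibble::tibble(facility = "F3", service = "ART", year = 2016L,
                   quarter = 1L, volume = 5L, total_amount = 0,
                   unit_total = NA_real_, status = "zero_expenditure"))
  inflows <- tibble::tibble(facility = c("F1", "F2", "F3", "F8"), year = 2016L,
                            quarter = 1L, funding_source = "GRZ", amount = 100)
  ram <- validate_ram(tibble::tibble(
    facility_id = c("F1", "F2", "F3"), service = "HTC",
    resource_category = "personnel", weight = 1))
  rep <- data_quality_report(u, inflows, ram, h)
  expect_setequal(rep$issues$issue,
                  c("missing_volume", "zero_expenditure", "ram_missing"))
  expect_equal(rep$issues$facility[rep$issues$issue == "ram_missing"], "F8")
  expect_equal(sum(rep$by_district$n_issues), 3)

  # clean run -> empty report
  clean <- data_quality_report(ok_unit("F1", 10), inflows[1, ],
                               ram, h)
  expect_equal(nrow(clean$issues), 0)
})

test_that("analytics are pure: identical inputs give identical outputs", {
  h <- toy_hierarchy()
  set.seed(5)
  u <- ok_unit(paste0("F", 1:8), runif(8, 50, 150))
  a <- flag_outliers(u, h, scope = "province", min_group = 4)
  b <- flag_outliers(u, h, scope = "province", min_group = 4)
  expect_identical(a, b)
  expect_identical(trend(u), trend(u))
  expect_identical(cost_volume_view(u, "HTC", 2016L, 1L),
                   cost_volume_view(u, "HTC", 2016L, 1L))
})

test_that("plot constructors return ggplot objects", {
  u <- dplyr::bind_rows(
    ok_unit(paste0("F", 1:4), c(10, 30, 12, 28), volume = c(100, 120, 400, 380)),
    ok_unit(paste0("F", 1:4), c(11, 29, 13, 27), volume = c(100, 120, 400, 380),
            q = 2L))
  u$unit_personnel <- u$unit_total * 0.6
  u$unit_drugs <- u$unit_total * 0.4
  cv <- cost_volume_view(u, "HTC", 2016L, 1L)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  expect_s3_class(ggplot2::autoplot(trend(u)), "ggplot")
  expect_s3_class(plot_facility_comparison(u, "HTC", 2016L, 1L), "ggplot")
  expect_s3_class(plot_facility_comparison(u, "HTC", 2016L, 1L,
                                           by_category = TRUE), "ggplot")
})
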