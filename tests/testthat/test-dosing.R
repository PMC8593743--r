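test_that("dose calendars expand loading doses then the steady interval", {
  ada <- base_cfg$drugs$adalimumab$schedule
  sec <- base_cfg$drugs$secukinumab$schedule
  tld <- base_cfg$drugs$tildrakizumab$schedule
  expect_equal(dose_times(ada, 12), c(0, 1, 3, 5, 7, 9, 11))
  expect_equal(dose_times(sec, 12), c(0, 1, 2, 3, 4, 8))
  expect_equal(dose_times(tld, 96), c(0, 4, seq(16, 88, by = 12)))
  expect_equal(dose_times(ada, 0), numeric(0))
  expect_error(dose_times(ada, -1), "non-negative")
})

test_that("interval dose counts follow the half-open convention", {
  tld <- base_cfg$drugs$tildrakizumab$schedule
  eta <- base_cfg$drugs$etanercept$schedule
  ixe <- base_cfg$drugs$ixekizumab$schedule
  expect_equal(doses_in_interval(tld, 0, 12), 2)
  expect_equal(doses_in_interval(tld, 12, 36), 2)  # weeks 16 and 28
  expect_equal(doses_in_interval(eta, 12, 36), 24) # weekly over 24 weeks
  # a dose exactly on a boundary belongs to the following period
  expect_equal(doses_in_interval(ixe, 0, 12), 6)
  expect_equal(doses_in_interval(ixe, 12, 16), 1)  # the week-12 dose
  expect_error(doses_in_interval(tld, 10, 5), "start_week")
})

test_that("dose counting is additive over interval partitions", {
  menu <- default_schedule_menu()
  set.seed(11)
  for (m in menu) {
    s <- dosing_schedule(m$loading, m$interval, m$units)
    for (rep in 1:20) {
      pts <- sort(sample(0:96, 3, replace = TRUE))
      a <- pts[1]; b <- pts[2]; cc <- pts[3]
      expect_equal(doses_in_interval(s, a, cc),
                   doses_in_interval(s, a, b) + doses_in_interval(s, b, cc))
      expect_equal(dose_units_in_interval(s, a, cc),
                   dose_units_in_interval(s, a, b) +
                     dose_units_in_interval(s, b, cc))
    }
    expect_equal(doses_in_interval(s, 0, 96), length(dose_times(s, 96)))
  }
})

test_that("loading-dose units weight double doses", {
  ada <- base_cfg$drugs$adalimumab$schedule  # 80 mg start = 2 units
  expect_equal(dose_units_in_interval(ada, 0, 12),
               doses_in_interval(ada, 0, 12) + 1)
  expect_equal(dose_units_in_interval(ada, 12, 24),
               doses_in_interval(ada, 12, 24))
})

test_that("schedule invariants are enforced", {
  expect_error(dosing_schedule(c(1, 2), 4), "start at 0")
  expect_error(dosing_schedule(c(0, 4, 4), 8), "strictly increasing")
  expect_error(dosing_schedule(0, 0), "steady_interval_weeks")
  expect_error(dosing_schedule(c(0, 4), 8, c(1, 0)), "loading_dose_units")
})
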