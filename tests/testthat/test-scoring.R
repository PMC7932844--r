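test_that("median response time ignores false starts", {
  expect_equal(median_response_time(make_pvt(c(300, 400, 500))), 400)
  expect_equal(median_response_time(make_pvt(c(300, 400))), 350)
  expect_equal(median_response_time(
    make_pvt(c(120, 300, 400, 500), c(TRUE, FALSE, FALSE, FALSE))), 400)
  expect_equal(median_response_time(make_pvt(234)), 234)
  expect_true(is.na(median_response_time(make_pvt(120, TRUE))))
  expect_true(is.na(median_response_time(make_pvt(numeric(0)))))
})

test_that("PVT filter applies first-instance, threshold, and SD rules in order", {
  # first session dropped; 850 > 800 dropped; survivors {420, 430} have
  # mean 425, population SD 5, so both are within 3 SD and retained
  keep <- filter_pvt(c(400, 850, 420, 430))
  expect_equal(keep, c(FALSE, FALSE, TRUE, TRUE))
  # the threshold is strictly greater: exactly 800 survives
  expect_true(filter_pvt(c(300, 800, 310, 320))[2])
  # the SD rule is strictly greater than sd_limit * SD of the survivors
  mrt <- c(500, 400, 400, 400, 400, 400, 401)  # first dropped, rest vary
  s <- sqrt(mean((mrt[-1] - mean(mrt[-1]))^2))
  expect_true(all(abs(mrt[-1] - mean(mrt[-1])) <= 3 * s))
  expect_equal(filter_pvt(mrt), c(FALSE, rep(TRUE, 6)))
})

test_that("SD rule with zero variance removes nothing", {
  expect_equal(filter_pvt(c(999, 400, 400, 400)),
               c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(filter_add(c(10, 20, 20, 20)), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("the PVT filter is idempotent on its survivors", {
  set.seed(7)
  mrt <- c(rnorm(30, 400, 60), 900, 1200)
  keep <- filter_pvt(mrt)
  again <- filter_pvt(mrt[keep], first_instance = FALSE)
  expect_true(all(again))
})

test_that("missing MRT is never retained", {
  expect_equal(filter_pvt(c(400, NA, 420, 430)), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("relative scores match the worked definitions", {
  tasks <- make_tasks("P01",
                      sprintf("2019-03-05 %02d:00", 8:10),
                      mrt = c(600, 300, 500), naa = c(10L, 15L, 25L))
  sc <- score_sessions(tasks)
  # first battery is the familiarisation instance
  expect_equal(sc$retained_pvt, c(FALSE, TRUE, TRUE))
  # baseline mean MRT over retained sessions is 400:
  # rrt = (1 - mrt/400) * 100
  expect_equal(sc$rrt, c(NA, 25, -25))
  # baseline mean NAA is 20: raa = (naa/20 - 1) * 100
  expect_equal(sc$raa, c(NA, -25, 25))
  # faster responses score positive, slower negative; more additions positive
  expect_true(sc$rrt[2] > 0 && sc$mrt[2] < 400)
  expect_true(sc$raa[3] > 0 && sc$naa[3] > 20)
})

test_that("per-participant mean relative score over retained sessions is zero", {
  set.seed(11)
  stamps <- format(ts_utc("2019-03-05 08:00") + (0:39) * 10800,
                   "%Y-%m-%d %H:%M", tz = "UTC")
  tasks <- rbind(
    make_tasks("P01", stamps, mrt = rnorm(40, 420, 70),
               naa = rpois(40, 18)),
    make_tasks("P02", stamps, mrt = c(rnorm(39, 380, 50), 950),
               naa = rpois(40, 22)))
  sc <- score_sessions(tasks)
  for (p in c("P01", "P02")) {
    i <- sc$participant_id == p
    expect_lt(abs(mean(sc$rrt[i & sc$retained_pvt])), 1e-9)
    expect_lt(abs(mean(sc$raa[i & sc$retained_add])), 1e-9)
  }
  # every retained MRT respects the absolute threshold
  expect_true(all(sc$mrt[sc$retained_pvt] <= 800))
})

test_that("participant inclusion uses the completed-battery count", {
  stamps42 <- format(ts_utc("2019-03-05 08:00") + (0:41) * 7200,
                     "%Y-%m-%d %H:%M", tz = "UTC")
  tasks <- rbind(make_tasks("P01", stamps42, mrt = rep(400, 42)),
                 make_tasks("P02", stamps42[1:41], mrt = rep(400, 41)))
  expect_equal(include_participants(tasks, 42), "P01")
  expect_equal(sort(include_participants(tasks, 41)), c("P01", "P02"))
  expect_error(include_participants(tasks, 100), "no participants")
})

test_that("daily relative scores use daily medians against their own mean", {
  tasks <- make_tasks("P01",
                      c("2019-03-05 08:00", "2019-03-05 12:00",
                        "2019-03-05 16:00", "2019-03-06 09:00",
                        "2019-03-06 13:00"),
                      mrt = c(600, 340, 360, 440, 460),
                      naa = c(10L, 20L, 20L, 20L, 20L))
  daily <- daily_relative_scores(score_sessions(tasks))
  # day 1 median over retained = 350, day 2 = 450, baseline mean = 400
  expect_equal(daily$daily_median_mrt, c(350, 450))
  expect_equal(daily$rel_daily_rrt, c(12.5, -12.5))
  expect_lt(abs(mean(daily$rel_daily_raa)), 1e-9)
})
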