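test_that("sensor CSV reads back the values it contains and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,time,X,Y,Z",
               "2019-04-01,11:00:00.00,0,0,1",
               "2019-04-01,11:00:00.20,0,1,0",
               "2019-04-01,11:00:00.40,1,0,0"), path)
  tr <- read_sensor_csv(path)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$x, c(0, 0, 1))
  expect_equal(tr$y, c(0, 1, 0))
  expect_equal(tr$z, c(1, 0, 0))
  expect_equal(as.numeric(diff(tr$time)), c(0.2, 0.2), tolerance = 1e-6)

  set.seed(42)
  tr2 <- accel_trace(tr$time[1] + (0:49) / 5,
                     rnorm(50), rnorm(50), rnorm(50))
  out <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(tr2, out)
  back <- read_sensor_csv(out)
  expect_equal(back$x, tr2$x, tolerance = 1e-6)
  expect_equal(back$y, tr2$y, tolerance = 1e-6)
  expect_equal(back$z, tr2$z, tolerance = 1e-6)
  expect_equal(as.numeric(back$time), as.numeric(tr2$time),
               tolerance = 0.011)
})

test_that("malformed rows and non-monotonic timestamps are rejected with a location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,time,X,Y,Z",
               "2019-04-01,11:00:00.00,0,0,1",
               "2019-04-01,11:00:00.20,oops,1,0"), path)
  expect_error(read_sensor_csv(path), "line 3")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,time,X,Y,Z",
               "2019-04-01,11:00:00.00,0,0,1",
               "2019-04-01,11:00:00.20,0,1,0",
               "2019-04-01,11:00:00.20,1,0,0"), dup)
  expect_error(read_sensor_csv(dup), "index 3")
  t0 <- as.POSIXct("2019-04-01 11:00:00", tz = "UTC")
  expect_error(accel_trace(c(t0, t0 + 0.2, t0 + 0.2), 1:3, 1:3, 1:3),
               "strictly increasing")
})

test_that("annotation intervals label samples under the half-open convention", {
  t0 <- as.POSIXct("2019-04-01 11:00:00", tz = "UTC")
  tr <- accel_trace(t0 + (0:99) / 5, rnorm(100), rnorm(100), rnorm(100))

  one <- annotation_intervals(t0, t0 + 20, "S", "feeding")
  lab <- apply_annotations(tr, one)
  expect_true(all(lab$posture == "S"))
  expect_true(all(lab$behavior == "feeding"))

  # two abutting intervals: the boundary sample belongs to the later one
  two <- annotation_intervals(c(t0, t0 + 10), c(t0 + 10, t0 + 20),
                              c("S", "RSR"), c("feeding", "resting"))
  lab2 <- apply_annotations(tr, two)
  expect_equal(lab2$posture[1:50], rep("S", 50))
  expect_equal(lab2$posture[51:100], rep("RSR", 50))

  # leading samples covered by nothing are AMBIGUOUS
  late <- annotation_intervals(t0 + 2, t0 + 20, "S", "feeding")
  lab3 <- apply_annotations(tr, late)
  expect_equal(lab3$posture[1:10], rep(ambiguous_label(), 10))
  expect_equal(lab3$posture[11:100], rep("S", 90))

  expect_error(
    annotation_intervals(c(t0, t0 + 5), c(t0 + 10, t0 + 20),
                         c("S", "S"), c("feeding", "feeding")),
    "overlap")
})

test_that("drop_ambiguous partitions the trace and reports counts and minutes", {
  tr <- make_trace(200)
  res <- drop_ambiguous(tr, "posture")
  expect_equal(res$report$n_removed, 0)
  expect_equal(nrow(res$trace), 200)

  tr$posture[c(3, 50:59)] <- ambiguous_label()
  res2 <- drop_ambiguous(tr, "posture")
  expect_equal(res2$report$n_removed, 11)
  expect_equal(res2$report$n_retained + res2$report$n_removed,
               res2$report$n_total)
  expect_equal(res2$report$minutes_removed, 11 * 0.2 / 60)
  expect_false(any(res2$trace$posture == ambiguous_label()))

  # a session built with a known ambiguous share reports exactly that share
  sched <- default_schedule(total_minutes = 20, ambiguous_fraction = 0.05,
                            seed = 7)
  sess <- simulate_session(sched)
  rep <- drop_ambiguous(sess$trace, "behavior")$report
  expect_equal(rep$n_removed, sess$n_ambiguous)
  expect_equal(rep$n_removed, round(0.05 * rep$n_total))
})

test_that("printed per-cow minutes equal samples x 0.2/60 at the printed precision", {
  tab <- cow_observation_table()
  expect_equal(nrow(tab), 13)  # 12 cows + total row
  expect_equal(tab$total, tab$removed + tab$used)
  half_ulp <- function(printed) {
    dp <- ifelse(printed == round(printed), 0,
                 nchar(sub(".*\\.", "", format(printed))))
    0.5 * 10^(-dp)
  }
  expect_true(all(abs(tab$removed * 0.2 / 60 - tab$minutes_removed) <=
                    half_ulp(tab$minutes_removed) + 1e-9))
  expect_true(all(abs(tab$used * 0.2 / 60 - tab$minutes_used) <=
                    half_ulp(tab$minutes_used) + 1e-9))
})
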