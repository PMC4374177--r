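# sleep-bout detection, exclusion filter, activity/speed/sleep variables and
# the two-stage aggregation

test_that("the five-minute rule defines bouts, with boundary runs included", {
  b <- detect_sleep_bouts(c(1, 0, 0, 0, 0, 0, 2))
  expect_identical(nrow(b), 1L)
  expect_identical(b$start_minute, 2L)
  expect_identical(b$duration, 5L)

  expect_identical(nrow(detect_sleep_bouts(c(1, 0, 0, 0, 0, 1))), 0L)  # 4 < 5
  # run touching the series end counts
  b2 <- detect_sleep_bouts(c(2, 0, 0, 0, 0, 0))
  expect_identical(b2$duration, 5L)
  # run touching the series start counts
  b3 <- detect_sleep_bouts(c(0, 0, 0, 0, 0, 2))
  expect_identical(b3$start_minute, 1L)
})

test_that("bout detection matches the brute-force linear-scan oracle", {
  set.seed(42)
  for (i in 1:200) {
    counts <- rbinom(1440, 1, runif(1, 0.2, 0.7))
    got <- detect_sleep_bouts(counts)
    want <- brute_bouts(counts)
    expect_identical(got$start_minute, want$start_minute)
    expect_identical(got$duration, want$duration)
  }
})

test_that("raising the bout threshold never increases sleep duration", {
  set.seed(7)
  for (i in 1:20) {
    s <- make_series(random_counts(2 * 1440))
    for (ph in c("photophase", "scotophase")) {
      d5 <- compute_sleep_variables(s, ph, threshold = 5)$sleep_duration
      d6 <- compute_sleep_variables(s, ph, threshold = 6)$sleep_duration
      expect_lte(d6, d5)
    }
  }
})

test_that("flies with any 24-h window of <= 24 crosses are discarded", {
  # exactly 24 crosses in the first day, active afterwards -> discarded
  low <- make_series(c(rep(1, 24), rep(0, 1440 - 24), rep(5, 1440)), fly_id = "low")
  # one cross every 55 minutes: >= 25 crosses in every sliding window -> kept
  steady <- make_series(rep(c(1, rep(0, 54)), length.out = 2880), fly_id = "steady")
  zero <- make_series(rep(0, 2880), fly_id = "zero")

  flt <- filter_individuals(list(low, steady, zero))
  expect_identical(vapply(flt$kept, `[[`, character(1), "fly_id"), "steady")
  expect_setequal(flt$discarded$fly_id, c("low", "zero"))
  expect_true(all(flt$discarded$window_sum <= 24))

  expect_error(filter_individuals(list(make_series(rep(1, 100)))), "shorter")
})

test_that("a fly with 25 crosses in its worst window is kept", {
  counts <- c(rep(1, 25), rep(0, 1440 - 25), rep(5, 1440))
  flt <- filter_individuals(list(make_series(counts)))
  expect_length(flt$kept, 1)
})

test_that("locomotor activity is crosses per phase minute averaged over days", {
  one <- make_series(c(rep(1, 720), rep(0, 720)))           # 720 crosses, photophase
  expect_equal(compute_locomotor_activity(one, "photophase"), 1.0)
  expect_equal(compute_locomotor_activity(one, "scotophase"), 0.0)

  two <- make_series(c(rep(1, 720), rep(0, 720), rep(0, 1440)))  # day2 silent
  expect_equal(compute_locomotor_activity(two, "photophase"), 0.5)
})

test_that("walking speed excludes inactive minutes and can be undefined", {
  counts <- c(rep(1, 10), rep(0, 710), rep(0, 720))  # 10 crosses in 10 active min
  s <- make_series(counts)
  expect_equal(compute_walking_speed(s, "photophase"), 1.0)
  expect_equal(compute_locomotor_activity(s, "photophase"), 10 / 720)
  expect_identical(compute_walking_speed(s, "scotophase"), NA_real_)

  allon <- make_series(rep(2, 1440))  # no zero minutes: speed equals activity
  expect_equal(compute_walking_speed(allon, "photophase"),
               compute_locomotor_activity(allon, "photophase"))
})

test_that("walking speed is at least locomotor activity whenever the fly moves", {
  set.seed(11)
  for (i in 1:20) {
    s <- make_series(random_counts(1440))
    for (ph in c("photophase", "scotophase")) {
      a <- compute_locomotor_activity(s, ph)
      w <- compute_walking_speed(s, ph)
      if (!is.na(w) && a > 0) expect_gte(w, a)
    }
  }
})

test_that("sleep variables: one 10-min bout per night over 4 nights", {
  counts <- rep(1, 4 * 1440)
  for (d in 0:3) counts[d * 1440 + 781:790] <- 0  # ZT13:00-13:09 each night
  s <- make_series(counts)
  sv <- compute_sleep_variables(s, "scotophase")
  expect_equal(sv$sleep_duration, 10)
  expect_equal(sv$bout_number, 1)
  expect_equal(sv$avg_bout_duration, 10)

  none <- compute_sleep_variables(make_series(rep(1, 1440)), "scotophase")
  expect_equal(none$sleep_duration, 0)
  expect_equal(none$bout_number, 0)
  expect_identical(none$avg_bout_duration, NA_real_)
})

test_that("a bout spanning lights-off splits its minutes but not its identity", {
  counts <- rep(1, 1440)
  counts[716:725] <- 0  # ZT11:55 to ZT12:04 -> 5 min photo, 5 min scoto
  s <- make_series(counts)

  photo <- compute_sleep_variables(s, "photophase")
  scoto <- compute_sleep_variables(s, "scotophase")
  expect_equal(photo$sleep_duration, 5)   # split minutes
  expect_equal(scoto$sleep_duration, 5)
  expect_equal(photo$bout_number, 1)      # bout belongs to its starting phase
  expect_equal(scoto$bout_number, 0)
  expect_equal(photo$avg_bout_duration, 10)  # full duration where it starts
  expect_identical(scoto$avg_bout_duration, NA_real_)

  # "start" attribution sends all minutes to the starting phase
  photo2 <- compute_sleep_variables(s, "photophase", attribution = "start")
  expect_equal(photo2$sleep_duration, 10)
  expect_equal(compute_sleep_variables(s, "scotophase",
                                       attribution = "start")$sleep_duration, 0)
})

test_that("split attribution conserves sleep minutes: phases sum to bout total", {
  set.seed(19)
  for (i in 1:10) {
    nd <- sample(1:3, 1)
    s <- make_series(random_counts(nd * 1440))
    bouts <- detect_sleep_bouts(s)
    tot <- sum(bouts$duration)
    ph <- compute_sleep_variables(s, "photophase")$sleep_duration
    sc <- compute_sleep_variables(s, "scotophase")$sleep_duration
    expect_equal((ph + sc) * nd, tot)
  }
})

test_that("hourly bout durations group bouts by starting ZT hour", {
  counts <- rep(1, 1440)
  counts[61:70] <- 0    # ZT1, 10 min
  counts[121:140] <- 0  # ZT2, 20 min
  counts[145:156] <- 0  # ZT2, 12 min
  h <- hourly_bout_duration(make_series(counts))
  expect_equal(unname(h["ZT01"]), 10)
  expect_equal(unname(h["ZT02"]), 16)
  expect_true(all(is.na(h[c("ZT00", "ZT05", "ZT23")])))
})

test_that("aggregation is strictly two-stage and unweighted", {
  mk <- function(fly, line, pop, lat, act) {
    data.frame(fly_id = fly, line_id = line, population_id = pop, latitude = lat,
               phase = "scotophase", locomotor_activity = act,
               walking_speed = NA_real_, sleep_duration = 0,
               sleep_bout_number = 0, avg_sleep_bout_duration = NA_real_)
  }
  # one fly per line: line mean equals the fly's value
  solo <- aggregate_phenotypes(mk("f1", "L1", "P1", 10, 3.5))
  expect_equal(solo$line$locomotor_activity, 3.5)

  # unbalanced design: population mean of line means != pooled fly mean
  df <- rbind(mk("a1", "L1", "P1", 10, 1), mk("a2", "L1", "P1", 10, 1),
              mk("a3", "L1", "P1", 10, 1), mk("b1", "L2", "P1", 10, 4))
  agg <- aggregate_phenotypes(df)
  expect_equal(agg$population$locomotor_activity, (1 + 4) / 2)  # line means 1, 4
  expect_false(isTRUE(all.equal(agg$population$locomotor_activity,
                                mean(df$locomotor_activity))))
  expect_equal(agg$population$n_lines, 2L)
  expect_equal(agg$population$locomotor_activity_sem,
               sd(c(1, 4)) / sqrt(2))
})

test_that("balanced designs make the population mean equal the grand mean", {
  set.seed(5)
  flies <- do.call(rbind, lapply(1:3, function(l)
    do.call(rbind, lapply(1:4, function(f) {
      s <- make_series(random_counts(1440), fly_id = sprintf("L%d_f%d", l, f),
                       line_id = sprintf("L%d", l), population_id = "P1")
      fly_phenotype(s)
    }))))
  agg <- aggregate_phenotypes(flies)
  night <- agg$population[agg$population$phase == "scotophase", ]
  direct <- mean(flies$locomotor_activity[flies$phase == "scotophase"])
  expect_equal(night$locomotor_activity, direct)  # balanced: 4 flies per line
})
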