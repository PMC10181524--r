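toy_predictions <- function() {
  # 6 short-stay and 6 long-stay patients with separated score levels
  set.seed(9)
  ids <- sprintf("S%02d", 1:12)
  los <- c(rep(5, 6), rep(12, 6))
  level <- c(rep(1.8, 6), rep(1.3, 6))
  pred <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(patient_id = ids[i], day = 0:14,
               pred = level[i] + 0.01 * (0:14) + rnorm(15, 0, 0.02),
               stringsAsFactors = FALSE)
  }))
  cohort_df <- data.frame(patient_id = ids, age = 60, gender = "female",
                          surgery_type = "Other", los = los,
                          n_complications = 0, stringsAsFactors = FALSE)
  list(pred = pred, cohort = cohort_df)
}

test_that("group bands split at the LOS threshold and bound the mean", {
  toy <- toy_predictions()
  gp <- group_profiles(toy$pred, toy$cohort, los_threshold = 8)
  expect_identical(unique(gp$short_los$n), 6L)
  expect_identical(unique(gp$long_los$n), 6L)
  for (g in gp) {
    expect_true(all(g$p10 <= g$mean & g$mean <= g$p90))
  }
  # all-identical patients collapse the band onto the mean
  flat <- toy$pred; flat$pred <- 1.5
  gp2 <- group_profiles(flat, toy$cohort)
  expect_true(all(gp2$short_los$p10 == 1.5 & gp2$short_los$p90 == 1.5))
  solo <- toy$cohort; solo$los <- 5
  expect_error(group_profiles(toy$pred, solo), "long_los")
})

test_that("band percentiles match a sort-based oracle", {
  set.seed(14)
  vals <- round(runif(10, 1, 2), 3)
  pred <- data.frame(patient_id = sprintf("Q%02d", 1:10), day = 0, pred = vals)
  cohort_df <- data.frame(patient_id = pred$patient_id, age = 60,
                          gender = "f", surgery_type = "O",
                          los = c(rep(4, 9), 12), n_complications = 0)
  gp <- group_profiles(pred, cohort_df, los_threshold = 8)
  x <- sort(vals[1:9])
  # linear interpolation between order statistics at h = (n-1)p + 1
  q_oracle <- function(p) {
    h <- (9 - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  }
  expect_equal(gp$short_los$p10, q_oracle(0.1), tolerance = 1e-12)
  expect_equal(gp$short_los$p90, q_oracle(0.9), tolerance = 1e-12)
})

test_that("patients classify as fast, slow, or indeterminate against the bands", {
  toy <- toy_predictions()
  gp <- group_profiles(toy$pred, toy$cohort, los_threshold = 8)
  short <- gp$short_los; long <- gp$long_los
  # a profile tracking the short-group mean is fast wherever bands separate
  fast_prof <- data.frame(day = short$day, pred = short$mean)
  cls <- classify_patient(fast_prof, short, long)
  sep <- short$p10 > long$p90
  expect_true(all(cls$class[sep] == "fast"))
  # a profile below both 10th percentiles is slow
  slow_prof <- data.frame(day = short$day, pred = pmin(short$p10, long$p10) - 0.1)
  expect_true(all(classify_patient(slow_prof, short, long)$class == "slow"))
  # a profile inside both bands is indeterminate
  both <- data.frame(day = short$day,
                     pred = (pmax(short$p10, long$p10) + pmin(short$p90, long$p90)) / 2)
  inside <- both$pred >= short$p10 & both$pred <= short$p90 &
    both$pred >= long$p10 & both$pred <= long$p90
  cls3 <- classify_patient(both, short, long)
  expect_true(all(cls3$class[inside] == "indeterminate"))
  # never slow while strictly above both 90th percentiles
  high <- data.frame(day = short$day, pred = pmax(short$p90, long$p90) + 0.05)
  expect_false(any(classify_patient(high, short, long)$class == "slow"))
  expect_error(classify_patient(data.frame(day = 99, pred = 1), short, long),
               "overlap")
})

test_that("discharge readiness finds the first threshold crossing", {
  prof <- data.frame(day = 0:10, pred = seq(1.0, 2.0, by = 0.1))
  rd <- discharge_readiness(prof)
  expect_identical(rd$ready_day, 8L)  # 1.8 first reached on day 8
  crossing4 <- data.frame(day = 0:10, pred = c(rep(1.2, 4), rep(1.85, 7)))
  expect_identical(discharge_readiness(crossing4)$ready_day, 4L)
  capped <- data.frame(day = 0:10, pred = rep(1.5, 11))
  expect_true(is.na(discharge_readiness(capped)$ready_day))
  # unready flag when the recorded discharge day scores below threshold
  low_at_dc <- data.frame(day = 0:10, pred = c(rep(1.9, 6), rep(1.6, 5)))
  rd2 <- discharge_readiness(low_at_dc, discharge_day = 8)
  expect_true(rd2$unready_at_discharge)
  rd3 <- discharge_readiness(low_at_dc, discharge_day = 3)
  expect_false(rd3$unready_at_discharge)
})

test_that("raising the readiness threshold never advances the ready day", {
  set.seed(5)
  for (i in 1:20) {
    prof <- data.frame(day = 0:14, pred = cumsum(runif(15, -0.05, 0.15)) + 1)
    days <- vapply(c(1.4, 1.6, 1.8, 2.0), function(th) {
      d <- discharge_readiness(prof, threshold = th)$ready_day
      if (is.na(d)) Inf else as.numeric(d)
    }, numeric(1))
    expect_false(is.unsorted(days))  # Inf encodes "never ready"
  }
})

test_that("decline flags mark strictly decreasing runs only", {
  up <- data.frame(day = 0:9, pred = seq(1, 1.9, by = 0.1))
  expect_length(decline_flags(up, 3), 0L)
  run <- data.frame(day = 0:2, pred = c(1.5, 1.4, 1.3))
  expect_identical(decline_flags(run, 3), 2L)
  plateau <- data.frame(day = 0:3, pred = c(1.5, 1.4, 1.4, 1.3))
  expect_length(decline_flags(plateau, 3), 0L)
  expect_error(decline_flags(up, 1), "k_days")
})

test_that("the interpretability table renders inactive days and abnormal HRR-1", {
  frames <- data.frame(
    patient_id = "Z", day = 1:4,
    steps = c(20, 1084, 1438, 809),
    upright_hours = c(0, 0.77, 0.77, 0.34),
    hrr1 = c(NA, 14.3, 8.2, 13.6),
    delta_upright_hours = c(NA, -0.08, 0, -0.43)
  )
  tab <- feature_frame_report(frames, "Z",
                              c("steps", "upright_hours", "hrr1",
                                "delta_upright_hours"))
  expect_identical(tab$hrr1[1], "inactive")
  expect_identical(tab$delta_upright_hours[1], "-")
  expect_false(tab$hrr1_abnormal[2])  # 14.3 bpm is normal
  expect_true(tab$hrr1_abnormal[3])   # 8.2 bpm is below the 12 bpm flag
  expect_false(tab$hrr1_abnormal[4])
  expect_error(feature_frame_report(frames, "nope", "steps"), "unknown patient")
})
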