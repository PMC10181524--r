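# deterministic synthetic frames: one informative feature plus noise
# fillers, grouped by patient
toy_frames <- function(n_patients = 20, days = 10, n_noise = 3, seed = 1,
                       noise_sd = 0.05) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_patients))
  frames <- expand.grid(patient_id = ids, day = seq_len(days) - 1L,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  frames <- frames[order(frames$patient_id, frames$day), ]
  k <- log(5) / 8
  target <- 2 - exp(-k * (frames$day + as.integer(factor(frames$patient_id)) %% 5))
  frames$signal <- target + rnorm(nrow(frames), 0, noise_sd)
  for (j in seq_len(n_noise)) {
    frames[[paste0("noise", j)]] <- rnorm(nrow(frames))
  }
  rownames(frames) <- NULL
  list(frames = frames, target = target)
}

fast_config <- function(...) {
  model_config(grid = list(eta = 0.3, max_depth = 3L, nrounds = 60L,
                           subsample = 1),
               early_stopping_rounds = 0L, ...)
}

test_that("standardization is z-scoring with population variance", {
  frames <- data.frame(patient_id = "A", day = 0:2,
                       x = c(1, 2, 3), flat = 1, holey = c(1, NA, 3))
  std <- standardize(frames)
  expect_equal(std$frames$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(std$frames$x[3], 1.224745, tolerance = 1e-6)
  expect_equal(std$frames$flat, c(0, 0, 0))  # zero-sd passes through
  expect_true(is.na(std$frames$holey[2]))    # missing stays missing
  # test-side transform reuses fitted parameters
  test <- data.frame(patient_id = "B", day = 0, x = 2, flat = 5, holey = 1)
  tz <- standardize(test, params = std$params)
  expect_equal(tz$frames$x, 0)
  expect_equal(tz$frames$flat, 4)  # shifted by the train mean, scale 1
})

test_that("hyperparameter search returns the grid minimum, first on ties", {
  toy <- toy_frames()
  single <- model_config(grid = list(eta = 0.2, max_depth = 2L, nrounds = 40L,
                                     subsample = 1),
                         early_stopping_rounds = 0L)
  got <- tune_hyperparameters(toy$frames, toy$target, single)
  expect_equal(got$eta, 0.2)
  expect_equal(got$max_depth, 2L)
  # a depth-1, 2-round model is dominated by a deeper, longer one
  two <- model_config(grid = list(eta = 0.3, max_depth = c(1L, 4L),
                                  nrounds = c(2L, 60L), subsample = 1),
                      early_stopping_rounds = 0L)
  got2 <- tune_hyperparameters(toy$frames, toy$target, two)
  expect_equal(got2$max_depth, 4L)
  expect_equal(got2$nrounds, 60L)
  empty <- fast_config()
  empty$grid <- list()
  expect_error(tune_hyperparameters(toy$frames, toy$target, empty), "empty")
})

test_that("cross-validation is grouped by patient and scores oracle features", {
  toy <- toy_frames(noise_sd = 0)
  cfg <- fast_config()
  cv <- cross_validate(toy$frames, toy$target, list(eta = 0.3, max_depth = 3,
                                                    nrounds = 60, subsample = 1),
                       k = 5, config = cfg)
  expect_identical(nrow(cv), 5L)
  expect_true(all(cv$mse < 0.01))  # feature equals target up to tree resolution
  expect_true(all(cv$srcc > 0.9))
  expect_error(cross_validate(toy$frames, toy$target,
                              list(eta = 0.3, max_depth = 3, nrounds = 10,
                                   subsample = 1),
                              k = 50, config = cfg), "exceeds")
})

test_that("pure-noise features give near-zero rank correlation", {
  toy <- toy_frames(n_patients = 30, noise_sd = 0)
  frames <- toy$frames[, c("patient_id", "day", "noise1", "noise2", "noise3")]
  cv <- cross_validate(frames, toy$target,
                       list(eta = 0.3, max_depth = 3, nrounds = 30, subsample = 1),
                       k = 5, config = fast_config())
  expect_lt(abs(mean(cv$srcc)), 0.35)
})

test_that("training is deterministic and tolerant of missing data", {
  toy <- toy_frames()
  cfg <- fast_config()
  hp <- list(eta = 0.3, max_depth = 3, nrounds = 60, subsample = 1)
  toy$frames$noise1[1:40] <- NA
  m1 <- train_final(toy$frames, toy$target, hp, config = cfg)
  m2 <- train_final(toy$frames, toy$target, hp, config = cfg)
  p1 <- predict(m1, toy$frames)
  expect_identical(p1$pred, predict(m2, toy$frames)$pred)
  # same row twice: same score
  expect_identical(predict(m1, toy$frames[c(1, 1), ])$pred[1],
                   predict(m1, toy$frames[c(1, 1), ])$pred[2])
  # an entirely missing feature warns but is retained
  toy$frames$noise2 <- NA_real_
  expect_warning(m3 <- train_final(toy$frames, toy$target, hp, config = cfg),
                 "missing")
  # a row with every feature missing still gets a prediction
  blank <- toy$frames[1, ]
  blank[, setdiff(names(blank), c("patient_id", "day"))] <- NA_real_
  expect_false(is.na(predict(m3, blank)$pred))
  # empty frames give empty predictions
  expect_identical(nrow(predict(m1, toy$frames[0, ])), 0L)
  # unknown feature columns are an input error
  expect_error(predict(m1, toy$frames[, c("patient_id", "day", "noise1")]),
               "unknown feature")
})

test_that("training ignores held-out patients entirely", {
  toy <- toy_frames(n_patients = 24)
  cfg <- fast_config()
  hp <- list(eta = 0.3, max_depth = 3, nrounds = 60, subsample = 1)
  train_rows <- toy$frames$patient_id %in% sprintf("P%02d", 1:16)
  m_a <- train_final(toy$frames[train_rows, ], toy$target[train_rows], hp,
                     config = cfg)
  # perturb the held-out patients wildly; the trained artifact is unchanged
  mutated <- toy$frames
  mutated[!train_rows, -(1:2)] <- mutated[!train_rows, -(1:2)] + 100
  m_b <- train_final(mutated[train_rows, ], toy$target[train_rows], hp,
                     config = cfg)
  probe <- toy$frames[train_rows, ][1:50, ]
  expect_identical(predict(m_a, probe)$pred, predict(m_b, probe)$pred)
})

test_that("evaluation identities hold", {
  profiles <- build_reference_profiles(list(fixed_patient("A", los = 6),
                                            fixed_patient("B", los = 12)))
  ref <- profiles_frame(profiles)
  pred <- data.frame(patient_id = ref$patient_id, day = ref$day,
                     pred = ref$score)
  ev <- evaluate_predictions(pred, profiles)
  expect_equal(ev$mse, 0)
  expect_equal(ev$srcc, 1)
  expect_equal(ev$discharge_error, 0)
  off <- pred; off$pred <- off$pred + 0.1
  ev2 <- evaluate_predictions(off, profiles)
  expect_equal(ev2$mse, 0.01, tolerance = 1e-12)
  expect_equal(ev2$srcc, 1)
  expect_equal(ev2$discharge_error, 0.1, tolerance = 1e-12)
  rev <- pred; rev$pred <- -rev$pred
  expect_equal(evaluate_predictions(rev, profiles)$srcc, -1)
  none <- pred; none$day <- none$day + 1000
  expect_error(evaluate_predictions(none, profiles), "overlap")
})

test_that("Friedman and Nemenyi agree with textbook formulas on a fixed matrix", {
  # 10 folds x 3 models, no ties within rows
  set.seed(77)
  mat <- cbind(a = rnorm(10, 0.020, 0.003),
               b = rnorm(10, 0.021, 0.003),
               c = rnorm(10, 0.035, 0.003))
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  # brute-force Friedman statistic and chi-square p
  chi <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  p_oracle <- pchisq(chi, df = k - 1, lower.tail = FALSE)
  expect_equal(stats::friedman.test(mat)$p.value, p_oracle, tolerance = 1e-12)
  # brute-force Nemenyi p for each pair via the studentized range
  got <- nemenyi_test(mat)
  for (i in 1:2) for (j in (i + 1):3) {
    q <- abs(mean(r[, i]) - mean(r[, j])) / sqrt(k * (k + 1) / (6 * n))
    p_ij <- ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    expect_equal(got[i, j], p_ij, tolerance = 1e-12)
  }
  expect_lt(got["a", "c"], 0.05)
  expect_gt(got["a", "b"], 0.5)
})

test_that("backward elimination keeps the informative feature and never empties", {
  toy <- toy_frames(n_patients = 20, n_noise = 9, seed = 3, noise_sd = 0.02)
  cfg <- fast_config(cv_folds_assess = 10L)
  hp <- list(eta = 0.3, max_depth = 3, nrounds = 60, subsample = 1)
  res <- backward_eliminate(toy$frames, toy$target, hp, config = cfg)
  expect_true("signal" %in% res$selected)
  expect_gte(length(res$selected), 1L)
  # only the terminating step (if any) is significant, so the selected set
  # never differs significantly from the full model
  sig <- which(res$history$significant)
  expect_true(length(sig) <= 1 && all(sig == nrow(res$history)))
  # duplicated copies of the target still terminate with a nonempty set
  dup <- toy$frames[, c("patient_id", "day")]
  dup$c1 <- toy$target; dup$c2 <- toy$target
  res2 <- backward_eliminate(dup, toy$target, hp, config = cfg)
  expect_gte(length(res2$selected), 1L)
})

test_that("the penalized-linear baseline fits an obvious linear signal", {
  toy <- toy_frames(noise_sd = 0.01)
  base <- train_baseline(toy$frames, toy$target, lambda = 0.01)
  pred <- predict(base, toy$frames)
  expect_gt(cor(pred$pred, toy$target), 0.95)
})
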