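printed_s <- c(0.278, 0.133, 0.154, 0.154, 0.280)

test_that("standard vector is the component-wise mean without renormalization", {
  expect_equal(estimate_standard_vector(matrix(printed_s, 1)), printed_s)
  expect_equal(estimate_standard_vector(rbind(rep(0.2, 5),
                                              c(0.4, 0.2, 0.1, 0.2, 0.1))),
               c(0.3, 0.2, 0.15, 0.2, 0.15))
  # mean of identical vectors is that vector; the 0.999 sum is preserved
  m <- estimate_standard_vector(rbind(printed_s, printed_s, printed_s))
  expect_equal(m, printed_s)
  expect_equal(sum(m), 0.999)
  expect_error(estimate_standard_vector(matrix(numeric(0), 0, 5)), "empty")
})

test_that("the distance statistic uses exactly four components", {
  expect_equal(wall_distance(printed_s, printed_s), 0)
  # 5th-coordinate degeneracy: changing only x5 leaves d = 0
  x <- printed_s; x[5] <- 0.9
  expect_equal(wall_distance(x, printed_s), 0)
  expect_gt(wall_distance(x, printed_s, include_fifth = TRUE), 0)
  # worked example with the printed ratio, against direct evaluation
  x_ex <- c(0.358, 0.189, 0.116, 0.2, 0.137)
  d_direct <- sqrt((0.358 - 0.278)^2 + (0.189 - 0.133)^2 +
                     (0.116 - 0.154)^2 + (0.2 - 0.154)^2)
  expect_equal(wall_distance(x_ex, printed_s), d_direct, tolerance = 1e-12)
  expect_equal(d_direct, 0.1144, tolerance = 1e-3)
})

test_that("the distance is a pseudometric, degenerate in the 5th coordinate", {
  set.seed(5)
  rnd_x <- function() { p <- runif(5); p / sum(p) }
  for (i in 1:30) {
    a <- rnd_x(); b <- rnd_x(); cc <- rnd_x()
    expect_equal(wall_distance(a, a), 0)
    expect_equal(wall_distance(a, b), wall_distance(b, a))
    expect_lte(wall_distance(a, cc),
               wall_distance(a, b) + wall_distance(b, cc) + 1e-12)
  }
  a <- rnd_x(); b <- a; b[5] <- b[5] + 0.3
  expect_equal(wall_distance(a, b), 0)
})

test_that("the cohort split is stratified, exhaustive and reproducible", {
  df <- tibble::tibble(id = 1:10,
                       label = rep(c("normal", "abnormal"), each = 5))
  sp <- split_cohort(df, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 7L)   # 70/30 on 10 records
  expect_equal(nrow(sp$test), 3L)
  expect_setequal(c(sp$train$id, sp$test$id), 1:10)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_true(all(c("normal", "abnormal") %in% sp$train$label))
  expect_true(all(c("normal", "abnormal") %in% sp$test$label))
  sp2 <- split_cohort(df, 0.7, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  # a class that cannot appear on both sides errors
  df_bad <- tibble::tibble(label = c("normal", rep("abnormal", 9)))
  expect_error(split_cohort(df_bad, 0.7, seed = 1), "absent")
})

test_that("threshold fitting maximizes training accuracy with smallest-tie rule", {
  d <- c(0.01, 0.02, 0.5, 0.6)
  labs <- c("normal", "normal", "abnormal", "abnormal")
  thr <- fit_threshold(d, labs)
  expect_equal(as.numeric(thr), 0.26)                 # midpoint of 0.02 and 0.5
  expect_equal(attr(thr, "train_accuracy"), 1)
  # perfectly interleaved distances: best accuracy is the majority fraction
  d2 <- 1:8 / 10
  labs2 <- rep(c("normal", "abnormal"), 4)
  expect_equal(attr(fit_threshold(d2, labs2), "train_accuracy"), 0.625)
  expect_error(fit_threshold(c(1, 2), c("normal", "normal")), "both classes")
})

test_that("fitted threshold accuracy equals the brute-force sweep", {
  set.seed(6)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    labs <- c("normal", "abnormal",
              sample(c("normal", "abnormal"), n - 2, replace = TRUE))
    d <- round(runif(n), sample(c(1, 2, 6), 1))   # ties likely at 1 digit
    thr <- fit_threshold(d, labs)
    expect_equal(attr(thr, "train_accuracy"),
                 threshold_sweep_oracle(d, labs), tolerance = 1e-12)
  }
})

test_that("classification uses the documented d >= threshold convention", {
  m <- screening_model(printed_s, 0.1)
  expect_equal(classify_wall(0, m), "normal")
  expect_equal(classify_wall(0.1, m), "abnormal")    # boundary -> abnormal
  expect_equal(classify_wall(1.0, m), "abnormal")
  expect_equal(classify_wall(c(0.05, 0.2), m), c("normal", "abnormal"))
})

test_that("metric formulas agree with direct evaluation", {
  expect_equal(as.list(compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))),
               list(ACC = 1, SENS = 1, SPEC = 1, PPV = 1, NPV = 1, MCC = 1, F1 = 1))
  half <- compute_metrics(list(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(half$ACC, 0.5); expect_equal(half$MCC, 0); expect_equal(half$F1, 0.5)
  und <- compute_metrics(list(TP = 0, TN = 3, FP = 0, FN = 2))
  expect_true(is.na(und$PPV))                        # zero denominator flagged
  expect_equal(und$SPEC, 1)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
  set.seed(7)
  for (i in 1:60) {
    cts <- as.list(stats::setNames(sample(1:40, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    got <- compute_metrics(cts)
    ref <- metrics_direct(cts$TP, cts$TN, cts$FP, cts$FN)
    for (nm in names(ref)) expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the Mann-Whitney pair count, with ties at half credit", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c("normal", "normal", "abnormal", "abnormal")), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c("normal", "abnormal"), 3)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("normal", "abnormal", "normal", "abnormal")),
               0.75)
  set.seed(8)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    labs <- c("normal", "abnormal",
              sample(c("normal", "abnormal"), max(0, n - 2), replace = TRUE))
    d <- sample(1:5, length(labs), replace = TRUE)    # heavy ties
    expect_equal(roc_auc(d, labs), auc_pair_oracle(d, labs), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c("normal", "normal")), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labs <- sample(c("normal", "abnormal"), 40, replace = TRUE, prob = c(0.6, 0.4))
  d <- rnorm(40) + (labs == "abnormal")
  ref <- as.numeric(pROC::auc(pROC::roc(response = labs, predictor = d,
                                        levels = c("normal", "abnormal"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(d, labs), ref, tolerance = 1e-12)
})

test_that("the fitted screening model exposes tidy and glance summaries", {
  set.seed(10)
  train <- tibble::tibble(
    x1 = c(rep(0.28, 6), rep(0.45, 4)) + runif(10, 0, 0.01),
    x2 = 0.13, x3 = 0.15, x4 = 0.15,
    x5 = 1 - (x1 + 0.13 + 0.15 + 0.15),
    label = c(rep("normal", 6), rep("abnormal", 4))
  )
  m <- fit_screening_model(train)
  expect_s3_class(m, "screening_model")
  expect_equal(m$train_accuracy, 1)
  # s is estimated from training normals by default
  expect_equal(m$s[1], mean(train$x1[1:6]))
  td <- tidy(m)
  expect_equal(td$term, c(paste0("s", 1:5), "threshold"))
  expect_equal(glance(m)$threshold, m$threshold)
  m_all <- fit_screening_model(train, use_all_for_s = TRUE)
  expect_equal(m_all$s[1], mean(train$x1))
})

test_that("oracle-mode pipeline separates distinct class templates perfectly", {
  base <- phantom_spec(height = 200, width = 64, wall_top_row = 50,
                       speckle_looks = Inf)
  cohort <- generate_cohort(8, 6, abnormal_effect = list(layer = 1, factor = 2),
                            base_spec = base, thickness_range = c(100, 120),
                            jitter_sd = 0.01, seed = 11)
  ev <- evaluate_pipeline(cohort, pipeline_config(srad_iterations = 0, seed = 11))
  expect_equal(ev$metrics$ACC, 1)
  expect_equal(ev$metrics$AUC, 1)
  expect_equal(ev$n_excluded, 0)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_true(all(c("d", "prediction", "set") %in% names(tidy(ev))))
  expect_equal(nrow(tidy(ev)), 14L)
  # rank-sum utility runs on the same distances
  ht <- d_rank_test(ev$records$d, ev$records$label)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)
  expect_s3_class(autoplot(ev), "ggplot")
})
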