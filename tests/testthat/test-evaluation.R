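# Metrics, aggregation convention, LOSO integrity and model comparison.

ns <- asNamespace("gaitkt")

loop_nrmse <- function(pred, truth) {
  ss <- 0
  for (i in seq_along(pred)) ss <- ss + (pred[i] - truth[i])^2
  100 * sqrt(ss / length(pred)) / (max(truth) - min(truth))
}

loop_pcc <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

test_that("NRMSE matches hand arithmetic and rejects degenerate ranges", {
  truth <- c(0, 1, 2, 3)
  expect_equal(nrmse(truth, truth), 0)
  expect_equal(nrmse(truth + 1, truth), 100 / 3, tolerance = 1e-12)
  expect_equal(round(nrmse(truth + 1, truth), 2), 33.33)
  expect_error(nrmse(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(nrmse(1:3, 1:4), "equal length")
  expect_error(nrmse(1, 1), "2 frames")
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(50); tr <- rnorm(50)
    expect_equal(nrmse(p, tr), loop_nrmse(p, tr))
  }
})

test_that("PCC matches hand computation and a brute-force loop", {
  x <- c(0.3, 1.7, 2.2, 5)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(-x, x), -1)
  expect_equal(round(pcc(c(1, 2, 4), c(1, 2, 3)), 4), 0.982)
  expect_equal(pcc(c(1, 2, 4), c(1, 2, 3)), loop_pcc(c(1, 2, 4), c(1, 2, 3)))
  expect_error(pcc(c(1, 1, 1), 1:3), "constant")
  set.seed(2)
  for (i in 1:20) {
    p <- rnorm(40); tr <- rnorm(40)
    expect_equal(pcc(p, tr), loop_pcc(p, tr))
  }
  # shuffled predictions decorrelate on long series
  tr <- rnorm(2000)
  expect_lt(abs(pcc(sample(tr), tr)), 0.1)
})

test_that("LOSO folds partition the subjects and never leak the test subject", {
  subs <- sprintf("S%02d", 1:17)
  folds <- loso_folds(subs, seed = 3)
  expect_length(folds, 17)
  expect_setequal(vapply(folds, `[[`, "", "test_subject"), subs)
  for (f in folds) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_false(f$test_subject == f$validation_subject)
    expect_true(f$validation_subject %in% setdiff(subs, f$test_subject))
    expect_setequal(c(f$train_subjects, f$validation_subject, f$test_subject), subs)
  }
  expect_error(loso_folds(c("a", "b")), "3 subjects")
  # deterministic given the seed
  expect_identical(loso_folds(subs, seed = 3), folds)
})

test_that("per-subject canary values never appear in another fold's training windows", {
  ds <- tiny_dataset()
  # plant a unique constant on one IMU channel per subject
  for (i in seq_along(ds)) {
    for (tr in seq_along(ds[[i]]$trials)) {
      ds[[i]]$trials[[tr]]$imu_gyr[, 24] <- i * 1000
    }
  }
  w <- window_dataset(ds)
  folds <- loso_folds(sort(unique(w$subject)), seed = 1)
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    train_w <- ns$windows_for_subjects(w, f$train_subjects)
    canary <- fi * 1000
    expect_false(any(train_w$imu_gyr[, , 24] == canary))
    test_w <- ns$windows_for_subjects(w, f$test_subject)
    expect_true(all(test_w$imu_gyr[, , 24] == canary))
  }
})

test_that("aggregation follows the unweighted component-mean convention", {
  comps <- c("kam", "kfm", "grf_ml", "grf_v", "grf_ap")
  per <- expand.grid(subject = c("a", "b", "c"), component = comps,
                     stringsAsFactors = FALSE)
  set.seed(4)
  per$nrmse <- runif(nrow(per), 3, 8)
  per$pcc <- runif(nrow(per), 0.8, 1)
  rep1 <- aggregate_report(per)
  expect_equal(rep1$overall$nrmse_mean, mean(rep1$by_component$nrmse_mean))
  expect_equal(rep1$overall$pcc_mean, mean(rep1$by_component$pcc_mean))
  # all-equal subjects collapse the sd to zero
  per2 <- per; per2$nrmse <- 5; per2$pcc <- 0.9
  rep2 <- aggregate_report(per2)
  expect_equal(rep2$by_component$nrmse_sd, rep(0, 5))
  expect_equal(rep2$overall$nrmse_mean, 5)
  # single subject: the mean is that subject's value
  per3 <- per[per$subject == "a", ]
  rep3 <- aggregate_report(per3)
  expect_equal(rep3$overall$nrmse_mean, mean(per3$nrmse))
  expect_error(aggregate_report(per[per$component != "kam", ]), "missing components")
})

test_that("the published component tables reproduce the published overalls", {
  ref <- reference_component_metrics()
  stu <- ref[ref$model == "student_kt", ]
  tea <- ref[ref$model == "teacher", ]
  expect_equal(round(overall_from_components(stu$nrmse), 2), 4.68)
  expect_equal(round(overall_from_components(stu$pcc), 3), 0.951)
  expect_equal(round(overall_from_components(tea$nrmse), 2), 3.63)
})

test_that("paired comparison handles ties, shifts and Bonferroni capping", {
  comps <- c("kam", "kfm", "grf_ml", "grf_v", "grf_ap")
  per <- expand.grid(subject = sprintf("s%d", 1:5), component = comps,
                     stringsAsFactors = FALSE)
  set.seed(5)
  per$nrmse <- runif(nrow(per), 4, 6)
  per$pcc <- runif(nrow(per), 0.9, 1)
  ra <- aggregate_report(per)
  # identical reports: adjusted p = 1, nothing flagged
  cmp <- compare_models(ra, ra)
  expect_identical(cmp$p_adjusted, 1)
  expect_false(cmp$significant_05)
  # constant positive shift: significant at any n >= 3 via the exact-tie rule
  perb <- per; perb$nrmse <- per$nrmse + 1
  rb <- aggregate_report(perb)
  cmp2 <- compare_models(rb, ra)
  expect_identical(cmp2$p_raw, 0)
  expect_true(cmp2$significant_01)
  # noisy difference: Bonferroni multiplies the raw p, capped at one
  perc <- per; perc$nrmse <- per$nrmse + rnorm(nrow(per), 0.1, 0.5)
  rc <- aggregate_report(perc)
  c1 <- compare_models(rc, ra, m = 1)
  c7 <- compare_models(rc, ra, m = 7)
  expect_equal(c7$p_raw, c1$p_raw)
  expect_equal(c7$p_adjusted, min(1, c1$p_raw * 7))
  # subject mismatch is an error
  perd <- per; perd$subject <- sub("s1", "zz", perd$subject)
  expect_error(compare_models(aggregate_report(perd), ra), "different subjects")
})

test_that("evaluate_fit computes metrics on exactly the test windows", {
  w <- tiny_windows()
  sp <- subject_split(w)
  m <- gait_model("joint_pos_bilstm", tiny_model_config(seed = 6))
  fit <- train_model(m, sp$data, tiny_train_config(epochs = 1, seed = 12))
  met <- evaluate_fit(fit, sp$test)
  expect_identical(nrow(met), 5L)
  expect_identical(met$component, ns$kinetics_names())
  expect_true(all(is.finite(met$nrmse)))
  expect_true(all(met$pcc >= -1 & met$pcc <= 1))
  # predictions cover every frame of the test subject once
  pr <- predict(fit, sp$test)
  expect_identical(dim(pr), c(ns$n_windows(sp$test), 50L, 5L))
})
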