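test_that("training reduces the loss on separable data and restores best weights", {
  sim <- quick_sim(n = 120, L = 21, noise = 0, seed = 21)
  fit <- m6a_cnn(sim$records, spec = tiny_spec(), seed = 3, patience = 4)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lte(attr(h, "stopped_epoch"), fit$spec$max_epochs)
  expect_gte(attr(h, "best_epoch"), 1)
  # restored weights reproduce the best validation loss
  expect_equal(bce_loss(fit$val_data$label, predict(fit, fit$val_data)),
               min(h$val_loss))
})

test_that("training is reproducible under a fixed seed", {
  sim <- quick_sim(n = 60, L = 13, seed = 8)
  f1 <- m6a_cnn(sim$records, spec = tiny_spec(max_epochs = 4), seed = 9,
                patience = 2)
  f2 <- m6a_cnn(sim$records, spec = tiny_spec(max_epochs = 4), seed = 9,
                patience = 2)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1), predict(f2))
})

test_that("zero patience stops at the first non-improving epoch", {
  sim <- quick_sim(n = 40, L = 13, seed = 5)
  net <- build_network(tiny_spec(max_epochs = 30), 13, seed = 1)
  rec <- sim$records
  fit <- train_network(net, rec[1:30, ], rec$label[1:30], rec[31:40, ],
                       rec$label[31:40], seed = 2, patience = 0)
  h <- fit$history
  first_bad <- which(diff(h$val_loss) >= 0)[1] + 1
  if (is.na(first_bad)) {
    expect_equal(attr(h, "stopped_epoch"), fit$spec$max_epochs)
  } else {
    expect_equal(attr(h, "stopped_epoch"), first_bad)
  }
})

test_that("empty training or validation sets are rejected", {
  net <- build_network(tiny_spec(), 13, seed = 1)
  rec <- quick_sim(n = 20, L = 13)$records
  expect_error(train_network(net, rec, rec$label, rec[0, ], integer(0)),
               "non-empty")
})

test_that("the fitted model exposes the standard modelling methods", {
  sim <- quick_sim(n = 80, L = 21, noise = 0, seed = 12)
  fit <- m6a_cnn(sim$records, spec = tiny_spec(), seed = 2, patience = 3)
  expect_s3_class(fit, "m6a_cnn")
  expect_output(print(fit), "Branch CNN")
  sm <- summary(fit)
  expect_s3_class(sm$train_metrics, "metrics_report")
  expect_true(all(predict(fit) >= 0 & predict(fit) <= 1))
  expect_true(all(predict(fit, type = "class") %in% 0:1))
  expect_equal(length(residuals(fit)), nrow(fit$data))
  expect_equal(fitted(fit), predict(fit))
  cf <- coef(fit)
  expect_true("head.Wo" %in% names(cf))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$data), 2))
  expect_true(all(unlist(sims) %in% 0:1))
  pdf(NULL); plot(fit); dev.off()
})

test_that("a trained model separates motif-positive from background sequences", {
  sim <- simulate_dataset(n_pos = 250, n_neg = 250, length = 21,
                          noise = 0.1, seed = 33)
  holdout <- simulate_dataset(n_pos = 80, n_neg = 80, length = 21,
                              noise = 0.1, seed = 34)
  fit <- m6a_cnn(sim$records, spec = network_spec(max_epochs = 15),
                 seed = 1, patience = 4)
  m <- compute_metrics(holdout$records$label, predict(fit, holdout$records))
  expect_gt(m$auc, 0.9)
  expect_gt(m$accuracy, 0.8)
})

test_that("cross-validation returns per-fold and averaged reports", {
  sim <- quick_sim(n = 90, L = 13, seed = 40)
  cv <- suppressWarnings(
    cross_validate(sim$records, spec = tiny_spec(max_epochs = 3),
                   k = 3, seed = 4, patience = 1))
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(unname(cv$mean["accuracy"]),
               mean(cv$per_fold$accuracy))
  expect_equal(unname(cv$sd["auc"]), sd(cv$per_fold$auc))
  expect_output(print(cv), "cross-validation")
})

test_that("ablation modes rewire the architecture as requested", {
  sim <- quick_sim(n = 60, L = 13, seed = 50)
  spec <- tiny_spec(max_epochs = 2)
  cv_one <- suppressWarnings(
    run_ablation(sim$records, spec, mode = "onehot", k = 3,
                 seed = 1, patience = 1))
  expect_equal(cv_one$branches, "onehot")
  cv_ic <- suppressWarnings(
    run_ablation(sim$records, spec, mode = "input_concat", k = 3,
                 seed = 1, patience = 1))
  expect_equal(cv_ic$arch, "input_concat")
  # three_branch mode is exactly cross_validate
  cv_tb <- suppressWarnings(
    run_ablation(sim$records, spec, mode = "three_branch", k = 3,
                 seed = 1, patience = 1))
  cv_ref <- suppressWarnings(
    cross_validate(sim$records, spec, k = 3, seed = 1, patience = 1))
  expect_equal(cv_tb$per_fold, cv_ref$per_fold)
  expect_error(run_ablation(sim$records, spec, mode = character(0)),
               "mode")
})
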