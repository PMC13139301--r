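# independent O(m^2) brute-force oracle for all four metrics
oracle_metrics <- function(y, yhat) {
  m <- length(y)
  num <- 0; Z <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (y[i] > y[j]) {
      Z <- Z + 1
      d <- yhat[i] - yhat[j]
      num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    }
  }
  list(mse = sum((y - yhat)^2) / m,
       ci = num / Z,
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       pcc = sum((yhat - mean(yhat)) * (y - mean(y))) /
         sqrt(sum((yhat - mean(yhat))^2) * sum((y - mean(y))^2)))
}

test_that("metrics match hand-derived values on the canonical cases", {
  id <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unclass(id)[c("mse", "ci", "r2", "pcc")],
               list(mse = 0, ci = 1, r2 = 1, pcc = 1))

  rev <- evaluate_predictions(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$ci, 0)
  expect_equal(rev$pcc, -1)

  # one tied prediction pair scores 0.5 of the 6 ordered pairs
  tie <- evaluate_predictions(c(1, 2, 3, 4), c(1, 1, 2, 3))
  expect_equal(tie$ci, 11 / 12)
})

test_that("metric edge cases raise explicit errors", {
  expect_error(evaluate_predictions(1:3, 1:4), "length mismatch")
  expect_error(evaluate_predictions(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(evaluate_predictions(1, 1), "at least 2")
  expect_error(evaluate_predictions(c(1, NA, 3), c(1, 2, 3)), "non-finite")
  expect_error(concordance_index(c(1, 1), c(1, 2)), "tied")
})

test_that("implementation equals the brute-force oracle on random pairs with ties", {
  withr::with_seed(99, {
    for (case in 1:100) {
      m <- sample(2:200, 1)
      y <- rnorm(m)
      # half the cases use coarsely rounded predictions to force ties
      yhat <- if (case %% 2) round(rnorm(m), 1) else rnorm(m)
      if (sd(y) == 0 || sd(yhat) == 0) next
      got <- evaluate_predictions(y, yhat)
      want <- oracle_metrics(y, yhat)
      expect_equal(got$mse, want$mse, tolerance = 1e-12)
      expect_equal(got$ci, want$ci, tolerance = 1e-12)
      expect_equal(got$r2, want$r2, tolerance = 1e-12)
      expect_equal(got$pcc, want$pcc, tolerance = 1e-12)
    }
  })
})

test_that("CI is anti-symmetric and PCC affine-invariant; MSE is not", {
  withr::with_seed(7, {
    for (case in 1:20) {
      m <- sample(5:60, 1)
      y <- rnorm(m); yhat <- rnorm(m)  # continuous: no ties a.s.
      expect_equal(concordance_index(y, yhat) + concordance_index(y, -yhat),
                   1, tolerance = 1e-12)
      a <- runif(1, 0.5, 3); b <- rnorm(1)
      scaled <- evaluate_predictions(y, a * yhat + b)
      plain <- evaluate_predictions(y, yhat)
      expect_equal(scaled$pcc, plain$pcc, tolerance = 1e-10)
      # R2 identity: r2 == 1 - mse * m / SStot
      expect_equal(plain$r2, 1 - plain$mse * m / sum((y - mean(y))^2),
                   tolerance = 1e-12)
    }
  })
  y <- c(1, 2, 3, 4); yhat <- c(1.1, 2.2, 2.8, 4.1)
  expect_false(isTRUE(all.equal(evaluate_predictions(y, 2 * yhat)$mse,
                                evaluate_predictions(y, yhat)$mse)))
})

test_that("the 1/6-test + 5-fold split is a seed-reproducible partition", {
  sp <- make_split(600, seed = 3)
  expect_length(sp$test_indices, 100L)
  expect_identical(lengths(sp$folds), rep(100L, 5L))

  sp245 <- make_split(245, seed = 3)
  expect_length(sp245$test_indices, 40L)
  expect_identical(lengths(sp245$folds), rep(41L, 5L))

  expect_identical(make_split(600, seed = 3), sp)
  expect_false(identical(make_split(600, seed = 4)$test_indices,
                         sp$test_indices))

  withr::with_seed(5, {
    for (n in sample(6:2000, 15)) {
      s <- make_split(n, seed = n)
      all_idx <- c(s$test_indices, unlist(s$folds))
      expect_identical(sort(all_idx), seq_len(n))  # disjoint + exhaustive
      expect_length(s$test_indices, floor(n / 6))
      expect_lte(diff(range(lengths(s$folds))), 1L)
    }
  })
  expect_error(make_split(5), "at least 6")
})

test_that("training reduces the loss on learnable data and is seed-reproducible", {
  fx <- small_training_fixture()
  cfg <- train_config(max_epochs = 4L, patience = 4L, batch_size = 64L,
                      seed = 31L)
  sp <- make_split(fx$n, seed = 31)
  tr <- sort(unlist(sp$folds[1:4])); va <- sp$folds[[5]]
  m1 <- build_model(fx$cfg)
  t1 <- train_model(m1, fx$feats, tr, va, cfg)
  expect_lt(t1$history$train_mse[4], t1$history$train_mse[1])
  expect_true(all(is.finite(t1$history$val_mse)))

  t2 <- train_model(build_model(fx$cfg), fx$feats, tr, va, cfg)
  expect_identical(t1$history, t2$history)

  expect_error(train_model(m1, fx$feats, integer(0), va, cfg), "empty training")
  expect_error(train_model(m1, fx$feats, tr, tr[1], cfg), "overlap")
})

test_that("early stopping with patience 0 stops one epoch after the best", {
  fx <- small_training_fixture()
  sp <- make_split(fx$n, seed = 13)
  tr <- sort(unlist(sp$folds[1:4])); va <- sp$folds[[5]]
  cfg <- train_config(max_epochs = 8L, patience = 0L, batch_size = 64L,
                      seed = 13L, learning_rate = 5e-3)
  t1 <- train_model(build_model(fx$cfg), fx$feats, tr, va, cfg)
  expect_equal(nrow(t1$history), min(8L, t1$best_epoch + 1L))
})

test_that("training writes a complete run directory when asked", {
  fx <- small_training_fixture()
  sp <- make_split(fx$n, seed = 3)
  tr <- sort(unlist(sp$folds[1:4])); va <- sp$folds[[5]]
  rd <- withr::local_tempdir()
  t1 <- train_model(build_model(fx$cfg), fx$feats, tr, va,
                    train_config(max_epochs = 2L, patience = 2L,
                                 batch_size = 64L, seed = 3L),
                    run_dir = rd)
  expect_setequal(list.files(rd), c("history.csv", "best_model.rds",
                                    "model_config.txt", "train_config.txt",
                                    "metrics.json"))
  reloaded <- load_model(file.path(rd, "best_model.rds"))
  expect_identical(predict(reloaded, cpifuse:::subset_features(fx$feats, 1:4)),
                   predict(t1, cpifuse:::subset_features(fx$feats, 1:4)))
})

test_that("fine-tuning at learning rate zero is a no-op on predictions", {
  fx <- small_training_fixture()
  sp <- make_split(fx$n, seed = 41)
  tr <- sort(unlist(sp$folds[1:4])); va <- sp$folds[[5]]
  # fit the featurizer on the same rows fine-tuning will refit on, so the
  # only possible change is in the weights
  base <- train_cpi(fx$ds, tr, va,
                    train_config(max_epochs = 2L, patience = 2L,
                                 batch_size = 64L, seed = 41L))
  ft <- finetune(base, fx$ds, tr, va,
                 train_config(max_epochs = 2L, patience = 2L, seed = 42L,
                              fine_tune_learning_rate = 0))
  p_base <- predict_affinity(base, fx$ds)$predicted_affinity[va]
  p_ft <- predict_affinity(ft, fx$ds)$predicted_affinity[va]
  expect_equal(p_ft, p_base, tolerance = 1e-8)
})

test_that("fine-tuning on the pretraining task does not degrade validation MSE", {
  fx <- small_training_fixture()
  sp <- make_split(fx$n, seed = 51)
  tr <- sort(unlist(sp$folds[1:4])); va <- sp$folds[[5]]
  base <- train_model(build_model(fx$cfg), fx$feats, tr, va,
                      train_config(max_epochs = 4L, patience = 4L,
                                   batch_size = 64L, seed = 51L))
  base$featurizer <- fx$fz
  ft <- finetune(base, fx$ds, tr, va,
                 train_config(max_epochs = 3L, patience = 3L, seed = 52L))
  expect_lte(ft$best_val_mse, base$best_val_mse * 1.2)
})

test_that("cross-validation reports five folds with sample-sd aggregates", {
  ds <- generate_cpi_dataset(25, 5, 0.8, signal_spec(noise_sd = 0.1),
                             seed = 61)
  cv <- cross_validate(ds, train_config(max_epochs = 2L, patience = 2L,
                                        batch_size = 50L, seed = 61L))
  expect_equal(nrow(cv$per_fold), 5L)
  expect_identical(cv$per_fold$fold, 1:5)
  for (mcol in c("mse", "ci", "r2", "pcc")) {
    expect_equal(unname(cv$mean[[mcol]]), mean(cv$per_fold[[mcol]]))
    expect_equal(unname(cv$sd[[mcol]]), sd(cv$per_fold[[mcol]]))
  }
  expect_true(all(cv$per_fold$mse >= 0))
  expect_true(all(cv$per_fold$ci >= 0 & cv$per_fold$ci <= 1))
})
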