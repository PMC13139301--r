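#' Configure the training loop
#'
#' @param learning_rate Adam learning rate for training from scratch.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience on validation MSE: training stops
#'   once the validation MSE has failed to improve for `patience + 1`
#'   consecutive epochs; the best-validation weights are returned.
#' @param fine_tune_learning_rate reduced Adam rate used by [finetune()].
#' @param seed seed for shuffling, dropout and weight initialization.
#' @param freeze `"none"` (default: fine-tuning updates all layers) or
#'   `"local"` (freeze embeddings and convolutional heads during
#'   fine-tuning).
#' @return A `cpi_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256L,
                         max_epochs = 30L, patience = 5L,
                         fine_tune_learning_rate = 1e-4, seed = 1L,
                         freeze = c("none", "local")) {
  freeze <- match.arg(freeze)
  if (learning_rate < 0 || fine_tune_learning_rate < 0)
    stopf("learning rates must be non-negative")
  if (!is_count(batch_size) || !is_count(max_epochs))
    stopf("batch_size and max_epochs must be positive integers")
  if (patience < 0 || patience > max_epochs)
    stopf("patience must be in [0, max_epochs]")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 fine_tune_learning_rate = fine_tune_learning_rate,
                 seed = as.integer(seed), freeze = freeze),
            class = "cpi_train_config")
}

#' Partition interactions into a held-out sixth and five CV folds
#'
#' A seeded uniform shuffle assigns `floor(n/6)` interactions to the test
#' set; the remainder is split into five mutually disjoint folds whose sizes
#' differ by at most one. Test and fold indices are disjoint and together
#' exhaustive.
#'
#' @param dataset a [cpi_dataset()], or an integer interaction count.
#' @param seed shuffle seed.
#' @return A `cpi_split` with `test_indices` and `folds` (list of 5).
#' @export
make_split <- function(dataset, seed = 1L) {
  n <- if (inherits(dataset, "cpi_dataset")) n_interactions(dataset)
       else as.integer(dataset)
  if (!is_count(n) || n < 6L) stopf("need at least 6 interactions to split")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(n / 6)
  test <- sort(perm[seq_len(n_test)])
  rest <- perm[(n_test + 1L):n]
  r <- length(rest)
  sizes <- rep(r %/% 5L, 5L) + c(rep(1L, r %% 5L), rep(0L, 5L - r %% 5L))
  folds <- vector("list", 5L)
  at <- 0L
  for (k in 1:5) {
    folds[[k]] <- sort(rest[at + seq_len(sizes[k])])
    at <- at + sizes[k]
  }
  structure(list(n = n, seed = as.integer(seed), test_indices = test,
                 folds = folds), class = "cpi_split")
}

#' @export
print.cpi_split <- function(x, ...) {
  cat(sprintf("<cpi_split> n = %d: test %d + folds {%s} (seed %d)\n", x$n,
              length(x$test_indices),
              paste(lengths(x$folds), collapse = ", "), x$seed))
  invisible(x)
}

batch_mse_grad <- function(yhat, y) 2 * (yhat - y) / length(y)

freeze_local_grads <- function(grads) {
  grads$emb_c[] <- 0
  grads$emb_p[] <- 0
  for (i in 1:3) {
    grads$conv_c[[i]]$dW[] <- 0; grads$conv_c[[i]]$db[] <- 0
    grads$conv_p[[i]]$dW[] <- 0; grads$conv_p[[i]]$db[] <- 0
  }
  grads
}

#' Train a fusion model with Adam on the MSE loss
#'
#' Minibatch gradient descent with Adam, per-epoch validation MSE, and
#' early stopping: the returned model carries the weights of the epoch with
#' the best validation MSE. Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param model an untrained or pretrained `cpi_model`.
#' @param features a [prepare_features()] result for the full dataset.
#' @param train_idx,val_idx disjoint interaction row indices.
#' @param config a [train_config()].
#' @param learning_rate overrides `config$learning_rate` (used by
#'   [finetune()]).
#' @param freeze overrides `config$freeze`.
#' @param run_dir optional directory; when given, the training run writes a
#'   config snapshot, the per-epoch loss log (CSV), the best checkpoint and
#'   a final metrics JSON there.
#' @return The best-validation `cpi_model`, with a `history` element: a
#'   tibble of per-epoch train/validation MSE.
#' @export
train_model <- function(model, features, train_idx, val_idx, config,
                        learning_rate = NULL, freeze = NULL, run_dir = NULL) {
  stopifnot(inherits(model, "cpi_model"), inherits(config, "cpi_train_config"))
  if (!length(train_idx)) stopf("empty training set")
  if (!length(val_idx)) stopf("empty validation set")
  if (length(intersect(train_idx, val_idx)))
    stopf("train and validation indices overlap")
  lr <- learning_rate %||% config$learning_rate
  freeze <- freeze %||% config$freeze
  train_feats <- subset_features(features, train_idx)
  val_feats <- subset_features(features, val_idx)
  check_batch(model, train_feats)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)

  params <- model$params
  state <- adam_init(params)
  nt <- length(train_idx)
  bs <- min(config$batch_size, nt)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(nt)
    losses <- numeric(0)
    for (s in seq(1L, nt, by = bs)) {
      idx <- perm[s:min(s + bs - 1L, nt)]
      bat <- subset_features(train_feats, idx)
      fw <- nn_forward(params, bat, dropout = model$config$dropout,
                       train = TRUE, keep_cache = TRUE)
      resid <- fw$yhat - bat$y
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stopf("training aborted: non-finite loss at epoch %d (learning rate too high?)",
              epoch)
      losses <- c(losses, loss)
      grads <- nn_backward(params, bat, fw$cache, batch_mse_grad(fw$yhat, bat$y))
      if (freeze == "local") grads <- freeze_local_grads(grads)
      stepped <- adam_step(params, grads, state, lr)
      params <- stepped$params
      state <- stepped$state
    }
    tmp_model <- model; tmp_model$params <- params
    val_pred <- predict(tmp_model, val_feats)
    val_mse <- mean((val_pred - val_feats$y)^2)
    hist[[epoch]] <- c(epoch = epoch, train_mse = mean(losses),
                       val_mse = val_mse)
    if (val_mse < best$val) {
      best <- list(params = params, val = val_mse, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > config$patience) break
    }
  }

  model$params <- best$params
  model$history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
  model$best_val_mse <- best$val
  model$best_epoch <- best$epoch
  if (!is.null(run_dir)) write_run_dir(model, config, lr, run_dir)
  model
}

write_run_dir <- function(model, config, lr, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(model$history, file.path(run_dir, "history.csv"),
                   row.names = FALSE)
  save_model(model, file.path(run_dir, "best_model.rds"))
  write_model_config(model$config, file.path(run_dir, "model_config.txt"))
  tc <- unclass(config); tc$effective_learning_rate <- lr
  writeLines(sprintf("%s=%s", names(tc),
                     vapply(tc, function(v) paste(v, collapse = ","),
                            character(1))),
             file.path(run_dir, "train_config.txt"))
  jsonlite::write_json(list(best_epoch = model$best_epoch,
                            best_val_mse = model$best_val_mse),
                       file.path(run_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}

#' Fit the full pipeline on a CPI dataset
#'
#' Convenience wrapper: fits a featurizer on the training rows, builds a
#' model (default architecture unless a config is given), trains it, and
#' stores the featurizer in the returned model so [predict_affinity()] works
#' on raw datasets.
#'
#' @param dataset a [cpi_dataset()].
#' @param train_idx,val_idx disjoint interaction row indices.
#' @param train_cfg a [train_config()].
#' @param model_cfg optional [model_config()]; widths must match the fitted
#'   featurizer. By default the standard architecture is configured from the
#'   featurizer's widths with `random_seed = train_cfg$seed`.
#' @param featurizer optional pre-fitted [fit_featurizer()].
#' @param compound_provider,protein_provider forwarded to [fit_featurizer()].
#' @return A trained `cpi_model` (with `history` and `featurizer`).
#' @export
train_cpi <- function(dataset, train_idx, val_idx,
                      train_cfg = train_config(), model_cfg = NULL,
                      featurizer = NULL,
                      compound_provider = minimal_descriptor_provider(),
                      protein_provider = NULL) {
  featurizer <- featurizer %||%
    fit_featurizer(dataset, train_idx, compound_provider, protein_provider)
  feats <- prepare_features(featurizer, dataset)
  if (is.null(model_cfg)) {
    w <- featurizer_widths(featurizer)
    model_cfg <- model_config(compound_vocab_size = w$compound_vocab_size,
                              protein_vocab_size = w$protein_vocab_size,
                              compound_global_in = w$compound_global_in,
                              protein_global_in = w$protein_global_in,
                              random_seed = train_cfg$seed)
  }
  model <- build_model(model_cfg)
  model$featurizer <- featurizer
  train_model(model, feats, train_idx, val_idx, train_cfg)
}

#' Predict affinities for every interaction of a dataset
#'
#' @param model a trained `cpi_model` carrying a featurizer.
#' @param dataset a [cpi_dataset()]; its affinity column is ignored (use a
#'   placeholder, e.g. 0, for screening libraries).
#' @return Tibble with `compound_id`, `protein_id`, `predicted_affinity`.
#' @export
predict_affinity <- function(model, dataset) {
  stopifnot(inherits(model, "cpi_model"))
  if (is.null(model$featurizer))
    stopf("model has no featurizer; train it with train_cpi() or attach one")
  feats <- prepare_features(model$featurizer, dataset)
  tibble::tibble(compound_id = feats$compound_id,
                 protein_id = feats$protein_id,
                 predicted_affinity = predict(model, feats))
}

#' Fine-tune a pretrained model on a small target dataset
#'
#' Transfer-learning step: the pretrained weights (including the output
#' head) are kept and all layers are updated end-to-end at the reduced
#' `fine_tune_learning_rate` (set `config$freeze = "local"` to freeze the
#' convolutional heads). Descriptor postprocessor statistics are refitted on
#' the target training rows through the stored column identities, so feature
#' widths stay compatible with the pretrained heads.
#'
#' @param pretrained a trained `cpi_model` with featurizer.
#' @param target_dataset the small target [cpi_dataset()].
#' @param train_idx,val_idx disjoint row indices into the target
#'   interactions.
#' @param config a [train_config()].
#' @return The fine-tuned best-validation `cpi_model`.
#' @export
finetune <- function(pretrained, target_dataset, train_idx, val_idx, config) {
  stopifnot(inherits(pretrained, "cpi_model"))
  if (is.null(pretrained$featurizer))
    stopf("pretrained model has no featurizer")
  featurizer <- refit_featurizer(pretrained$featurizer, target_dataset,
                                 train_idx)
  feats <- prepare_features(featurizer, target_dataset)
  model <- pretrained
  model$featurizer <- featurizer
  check_batch(model, feats)
  train_model(model, feats, train_idx, val_idx, config,
              learning_rate = config$fine_tune_learning_rate,
              freeze = config$freeze)
}

#' 5-fold cross-validation over a shared held-out test sixth
#'
#' For each fold, a model is trained on the remaining four folds, validated
#' (for early stopping) on the held-out fold, and evaluated on the shared
#' test sixth. The featurizer is refitted per fold on that fold's training
#' rows. Aggregates report the per-fold mean and sample (n-1) standard
#' deviation of each metric.
#'
#' @param dataset a [cpi_dataset()].
#' @param train_cfg a [train_config()].
#' @param model_cfg optional [model_config()] shared by all folds.
#' @param split optional [make_split()] result (default: seeded from
#'   `train_cfg$seed`).
#' @param compound_provider,protein_provider forwarded to
#'   [fit_featurizer()].
#' @return A `cpi_cv`: tibble `per_fold` plus named vectors `mean` and `sd`.
#' @export
cross_validate <- function(dataset, train_cfg = train_config(),
                           model_cfg = NULL, split = NULL,
                           compound_provider = minimal_descriptor_provider(),
                           protein_provider = NULL) {
  stopifnot(inherits(dataset, "cpi_dataset"))
  split <- split %||% make_split(dataset, train_cfg$seed)
  rows <- vector("list", 5L)
  for (k in 1:5) {
    train_idx <- sort(unlist(split$folds[-k]))
    val_idx <- split$folds[[k]]
    cfg_k <- train_cfg
    cfg_k$seed <- derive_seed(train_cfg$seed, k)
    model <- tryCatch(
      train_cpi(dataset, train_idx, val_idx, cfg_k, model_cfg,
                compound_provider = compound_provider,
                protein_provider = protein_provider),
      error = function(e) stopf("fold %d failed: %s", k, conditionMessage(e)))
    feats <- prepare_features(model$featurizer, dataset)
    test_feats <- subset_features(feats, split$test_indices)
    met <- evaluate_predictions(test_feats$y, predict(model, test_feats))
    rows[[k]] <- tibble::tibble(fold = k, mse = met$mse, ci = met$ci,
                                r2 = met$r2, pcc = met$pcc)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("mse", "ci", "r2", "pcc")
  structure(list(per_fold = per_fold,
                 mean = vapply(per_fold[metric_cols], mean, numeric(1)),
                 sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
                 split = split),
            class = "cpi_cv")
}

#' @export
print.cpi_cv <- function(x, ...) {
  cat("5-fold cross-validation (shared held-out test sixth):\n")
  for (m in names(x$mean))
    cat(sprintf("  %-4s %.4f (%.4f)\n", toupper(m), x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
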