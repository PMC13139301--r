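test_that("the default architecture concatenates the four heads to width 1,216", {
  cfg <- model_config(compound_vocab_size = 40L, compound_global_in = 1041L,
                      protein_global_in = 567L)
  expect_equal(cpifuse:::concat_width(cfg), 1216L)
  # 96 + 512 + 96 + 512 with the default split
  expect_equal(cfg$compound_local_out + cfg$compound_global_out +
                 cfg$protein_local_out + cfg$protein_global_out, 1216L)
})

test_that("non-compliant head widths are rejected unless explicitly overridden", {
  expect_error(
    model_config(compound_vocab_size = 40L, compound_global_in = 100L,
                 protein_global_in = 100L,
                 conv_filters = c(32L, 64L, 100L),
                 compound_local_out = 100L, protein_local_out = 100L,
                 compound_global_out = 500L, protein_global_out = 500L),
    "config error")
  cfg <- model_config(compound_vocab_size = 40L, compound_global_in = 100L,
                      protein_global_in = 100L,
                      conv_filters = c(32L, 64L, 100L),
                      compound_local_out = 100L, protein_local_out = 100L,
                      compound_global_out = 500L, protein_global_out = 500L,
                      nonstandard = TRUE)
  expect_equal(cpifuse:::concat_width(cfg), 1200L)
  expect_error(model_config(compound_vocab_size = 40L,
                            compound_global_in = 10L,
                            protein_global_in = 10L, dropout = 1),
               "dropout")
})

test_that("weight initialization is seed-deterministic", {
  cfg <- tiny_model_config(seed = 17L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_model_config(seed = 18L))
  expect_false(identical(m1$params, m3$params))
})

test_that("forward pass yields finite, order-equivariant, batch-size invariant outputs", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  batch <- tiny_feature_batch(9, cfg, seed = 2)
  p <- predict(m, batch)
  expect_length(p, 9L)
  expect_true(all(is.finite(p)))

  perm <- c(4, 1, 9, 2, 7, 3, 6, 5, 8)
  p_perm <- predict(m, cpifuse:::subset_features(batch, perm))
  expect_equal(p_perm, p[perm], tolerance = 1e-10)

  p_single <- vapply(1:9, function(i)
    predict(m, cpifuse:::subset_features(batch, i)), numeric(1))
  expect_equal(p_single, p, tolerance = 1e-5)

  # repeated inference is bitwise stable (dropout off at inference)
  expect_identical(predict(m, batch), p)
})

test_that("local head output is invariant to pure zero-padding context", {
  # the same token row evaluated alone and next to a much longer row (which
  # widens the cropped conv window) must give identical predictions
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  batch <- tiny_feature_batch(2, cfg, seed = 3)
  batch$prot_tokens[2, ] <- 0L
  batch$prot_tokens[2, 1:900] <- rep(c(1L, 5L), 450)  # long companion row
  alone <- predict(m, cpifuse:::subset_features(batch, 1))
  paired <- predict(m, batch)[1]
  expect_equal(alone, paired, tolerance = 1e-12)
})

test_that("model checkpoints round-trip exactly and reject corrupt files", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  batch <- tiny_feature_batch(5, cfg, seed = 4)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(predict(m2, batch), predict(m, batch))

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_model(bad), "load error")
  saveRDS(list(format = "something_else"), bad)
  expect_error(load_model(bad), "load error")
})

test_that("feature-width mismatches raise shape errors naming the head", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  batch <- tiny_feature_batch(3, cfg, seed = 5)
  batch$prot_global <- batch$prot_global[, -1, drop = FALSE]
  expect_error(predict(m, batch), "protein global head")
  batch2 <- tiny_feature_batch(3, cfg, seed = 5)
  batch2$comp_global <- cbind(batch2$comp_global, 0)
  expect_error(predict(m, batch2), "compound global head")
})

test_that("model config round-trips through its plain-text file format", {
  cfg <- tiny_model_config(seed = 23L)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_model_config(cfg, tf)
  cfg2 <- read_model_config(tf)
  expect_identical(unclass(cfg2), unclass(cfg))
})
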