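FUSION_CONCAT_WIDTH <- 1216L

concat_width <- function(config) {
  config$compound_local_out + config$compound_global_out +
    config$protein_local_out + config$protein_global_out
}

#' Configure the four-head fusion network
#'
#' The architecture has two local convolutional heads (character-level over
#' SMILES, residue-level over protein sequence: embedding, three stacked 1-D
#' convolutions, max-over-time pooling) and two global dense heads (compound
#' fingerprint+descriptor vector; protein descriptor vector). The four head
#' outputs are concatenated — their widths must sum to 1,216 — and passed
#' through a fully connected stack with dropout to a single affinity output.
#'
#' @param compound_vocab_size number of SMILES character indices
#'   (vocabulary size including UNKNOWN; padding 0 is extra).
#' @param protein_vocab_size number of residue indices (default 21:
#'   20 amino acids + UNKNOWN).
#' @param compound_global_in,protein_global_in input widths of the two
#'   global heads (fingerprint bits + kept descriptor columns; kept protein
#'   descriptor columns).
#' @param embedding_dim embedding width shared by both local heads.
#' @param conv_filters filter counts of the three stacked convolutions.
#' @param compound_kernels,protein_kernels kernel sizes of the three
#'   convolutions in each local head.
#' @param compound_local_out,protein_local_out local head output widths;
#'   must equal the last conv filter count (max-over-time pooling).
#' @param compound_global_out,protein_global_out global head output widths.
#' @param fusion_hidden widths of the fully connected fusion stack.
#' @param dropout dropout rate applied after each fusion layer in training.
#' @param random_seed seed for weight initialization.
#' @param nonstandard set TRUE to allow head widths that do not sum to
#'   1,216.
#' @return A `cpi_model_config`.
#' @export
model_config <- function(compound_vocab_size,
                         protein_vocab_size = 21L,
                         compound_global_in,
                         protein_global_in,
                         embedding_dim = 128L,
                         conv_filters = c(32L, 64L, 96L),
                         compound_kernels = c(4L, 6L, 8L),
                         protein_kernels = c(4L, 8L, 12L),
                         compound_local_out = 96L,
                         protein_local_out = 96L,
                         compound_global_out = 512L,
                         protein_global_out = 512L,
                         fusion_hidden = c(1024L, 512L),
                         dropout = 0.1,
                         random_seed = 42L,
                         nonstandard = FALSE) {
  cf <- list(compound_vocab_size = as.integer(compound_vocab_size),
             protein_vocab_size = as.integer(protein_vocab_size),
             compound_global_in = as.integer(compound_global_in),
             protein_global_in = as.integer(protein_global_in),
             embedding_dim = as.integer(embedding_dim),
             conv_filters = as.integer(conv_filters),
             compound_kernels = as.integer(compound_kernels),
             protein_kernels = as.integer(protein_kernels),
             compound_local_out = as.integer(compound_local_out),
             protein_local_out = as.integer(protein_local_out),
             compound_global_out = as.integer(compound_global_out),
             protein_global_out = as.integer(protein_global_out),
             fusion_hidden = as.integer(fusion_hidden),
             dropout = as.numeric(dropout),
             random_seed = as.integer(random_seed),
             nonstandard = isTRUE(nonstandard))
  with(cf, {
    if (length(conv_filters) != 3L || length(compound_kernels) != 3L ||
        length(protein_kernels) != 3L)
      stopf("conv_filters and kernel vectors must have length 3")
    if (any(c(compound_vocab_size, protein_vocab_size, compound_global_in,
              protein_global_in, embedding_dim, conv_filters,
              compound_kernels, protein_kernels, compound_local_out,
              protein_local_out, compound_global_out, protein_global_out,
              fusion_hidden) <= 0L))
      stopf("all architecture widths must be positive")
    if (compound_local_out != conv_filters[3] ||
        protein_local_out != conv_filters[3])
      stopf("local head output widths must equal the last conv filter count (%d)",
            conv_filters[3])
    if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  })
  if (!cf$nonstandard && concat_width(cf) != FUSION_CONCAT_WIDTH)
    stopf(paste("config error: head output widths sum to %d, not the standard",
                "concatenation width %d (set nonstandard = TRUE to override)"),
          concat_width(cf), FUSION_CONCAT_WIDTH)
  structure(cf, class = "cpi_model_config")
}

#' @export
print.cpi_model_config <- function(x, ...) {
  cat(sprintf("<cpi_model_config> heads %d+%d+%d+%d = %d -> fusion [%s] -> 1\n",
              x$compound_local_out, x$compound_global_out,
              x$protein_local_out, x$protein_global_out, concat_width(x),
              paste(x$fusion_hidden, collapse = ", ")))
  invisible(x)
}

#' Build an untrained fusion model from a configuration
#'
#' Initializes all learnable weights from the configuration's random seed
#' (two builds with the same seed give identical weights). The concatenated
#' multi-head width is asserted at build time.
#'
#' @param config a [model_config()].
#' @return A `cpi_model` holding the config and weights; its `featurizer`
#'   slot is filled by the training pipeline.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cpi_model_config"))
  if (!config$nonstandard && concat_width(config) != FUSION_CONCAT_WIDTH)
    stopf("config error: concatenated head width %d != %d",
          concat_width(config), FUSION_CONCAT_WIDTH)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$random_seed)
  params <- init_params(config)
  structure(list(config = config, params = params, featurizer = NULL),
            class = "cpi_model")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.cpi_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<cpi_model> %s parameters, concat width %d%s\n",
              format(np, big.mark = ","), concat_width(x$config),
              if (is.null(x$featurizer)) " (untrained)" else ""))
  invisible(x)
}

check_batch <- function(model, batch) {
  need <- c("comp_tokens", "comp_global", "prot_tokens", "prot_global")
  miss <- setdiff(need, names(batch))
  if (length(miss)) stopf("batch missing component(s): %s",
                          paste(miss, collapse = ", "))
  cf <- model$config
  if (ncol(batch$comp_tokens) != SMILES_ENCODING_LENGTH)
    stopf("shape error in compound local head: token length %d != %d",
          ncol(batch$comp_tokens), SMILES_ENCODING_LENGTH)
  if (ncol(batch$prot_tokens) != PROTEIN_ENCODING_LENGTH)
    stopf("shape error in protein local head: token length %d != %d",
          ncol(batch$prot_tokens), PROTEIN_ENCODING_LENGTH)
  if (ncol(batch$comp_global) != cf$compound_global_in)
    stopf("shape error in compound global head: feature width %d != %d",
          ncol(batch$comp_global), cf$compound_global_in)
  if (ncol(batch$prot_global) != cf$protein_global_in)
    stopf("shape error in protein global head: feature width %d != %d",
          ncol(batch$prot_global), cf$protein_global_in)
  if (max(batch$comp_tokens) > cf$compound_vocab_size)
    stopf("shape error in compound local head: token id exceeds vocabulary")
  invisible(TRUE)
}

#' Predict affinities for a feature batch
#'
#' Deterministic inference pass (dropout disabled). Predictions are
#' batch-order equivariant and batch-size invariant: predicting rows singly
#' equals predicting them jointly.
#'
#' @param object a `cpi_model`.
#' @param batch list with `comp_tokens` (n x 100 integer),
#'   `comp_global` (n x compound_global_in), `prot_tokens` (n x 1000
#'   integer), `prot_global` (n x protein_global_in).
#' @param chunk_size internal forward-pass chunking (memory bound).
#' @param ... unused.
#' @return Numeric vector of n predicted affinities.
#' @export
predict.cpi_model <- function(object, batch, chunk_size = 512L, ...) {
  check_batch(object, batch)
  n <- nrow(batch$comp_tokens)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    sub <- list(comp_tokens = batch$comp_tokens[idx, , drop = FALSE],
                comp_global = batch$comp_global[idx, , drop = FALSE],
                prot_tokens = batch$prot_tokens[idx, , drop = FALSE],
                prot_global = batch$prot_global[idx, , drop = FALSE])
    out[idx] <- nn_forward(object$params, sub)$yhat
  }
  out
}

#' Write / read a model configuration as a plain-text key-value file
#'
#' The file fully determines the architecture: one `key=value` line per
#' field, vectors comma-separated.
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `write_model_config`: the path, invisibly; `read_model_config`:
#'   the `cpi_model_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "cpi_model_config"))
  vals <- unclass(config)
  writeLines(sprintf("%s=%s", names(vals),
                     vapply(vals, function(v) paste(v, collapse = ","),
                            character(1))),
             path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stopf("malformed config file: %s", path)
  vals <- lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  num <- function(x) as.numeric(x)
  do.call(model_config, list(
    compound_vocab_size = num(vals$compound_vocab_size),
    protein_vocab_size = num(vals$protein_vocab_size),
    compound_global_in = num(vals$compound_global_in),
    protein_global_in = num(vals$protein_global_in),
    embedding_dim = num(vals$embedding_dim),
    conv_filters = num(vals$conv_filters),
    compound_kernels = num(vals$compound_kernels),
    protein_kernels = num(vals$protein_kernels),
    compound_local_out = num(vals$compound_local_out),
    protein_local_out = num(vals$protein_local_out),
    compound_global_out = num(vals$compound_global_out),
    protein_global_out = num(vals$protein_global_out),
    fusion_hidden = num(vals$fusion_hidden),
    dropout = num(vals$dropout),
    random_seed = num(vals$random_seed),
    nonstandard = identical(tolower(vals$nonstandard), "true")))
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint contains the configuration, all weights and the fitted
#' featurizer (vocabulary + descriptor postprocessors), so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `cpi_model`.
#' @param path checkpoint file path.
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cpi_model"))
  saveRDS(list(format = "cpifuse_model", version = MODEL_FORMAT_VERSION,
               config = model$config, params = model$params,
               featurizer = model$featurizer), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stopf("model load error: %s is not a readable checkpoint (%s)",
                                            path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "cpifuse_model"))
    stopf("model load error: %s is not a cpifuse checkpoint", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stopf("model load error: checkpoint version %s, expected %d",
          obj$version, MODEL_FORMAT_VERSION)
  cf <- obj$config
  if (nrow(obj$params$dense_gc$W) != cf$compound_global_in)
    stopf("model load error: compound global head width mismatch")
  if (nrow(obj$params$dense_gp$W) != cf$protein_global_in)
    stopf("model load error: protein global head width mismatch")
  structure(list(config = cf, params = obj$params,
                 featurizer = obj$featurizer), class = "cpi_model")
}
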