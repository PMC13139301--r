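# Turns a cpi_dataset into the four model input blocks. Raw per-entity
# features (encodings, fingerprints, raw descriptors) depend only on the
# molecules, so they are computed once per unique compound/protein and
# cached inside the featurizer; only the descriptor postprocessors carry
# fitted (training-set) statistics.

compute_entity_features <- function(dataset, vocab, compound_provider,
                                    protein_provider) {
  comp <- dataset$compounds
  prot <- dataset$proteins
  ct <- t(vapply(comp$smiles,
                 function(s) encode_smiles(s, vocab, warn_unknown = FALSE),
                 integer(SMILES_ENCODING_LENGTH)))
  rownames(ct) <- comp$compound_id
  fp <- compute_ecfp4(comp$smiles, ids = comp$compound_id)
  cd <- compute_compound_descriptors(comp$smiles, compound_provider,
                                     ids = comp$compound_id)
  pt <- t(vapply(prot$sequence, encode_sequence,
                 integer(PROTEIN_ENCODING_LENGTH)))
  rownames(pt) <- prot$protein_id
  pd <- suppressWarnings(
    compute_protein_descriptors(prot$sequence, provider = protein_provider,
                                ids = prot$protein_id))
  list(comp_ids = comp$compound_id, comp_tokens = ct, comp_fp = fp,
       comp_desc = cd, prot_ids = prot$protein_id, prot_tokens = pt,
       prot_desc = pd)
}

#' Fit a featurizer on a CPI dataset
#'
#' Builds the SMILES character vocabulary from the training compounds and
#' fits the descriptor postprocessors (null/zero-variance column exclusion +
#' z-scoring) on the descriptor rows of the training interactions only, so
#' no test-set statistics leak into the features.
#'
#' @param dataset a [cpi_dataset()].
#' @param train_idx interaction row indices regarded as training data
#'   (default: all rows).
#' @param compound_provider descriptor provider for compounds
#'   (default [minimal_descriptor_provider()]).
#' @param protein_provider optional external protein descriptor provider
#'   (default: built-in 567-wide AAC/DPC/CTD set).
#' @return A `cpi_featurizer` carrying the vocabulary, providers, fitted
#'   postprocessors and a per-entity feature cache for `dataset`.
#' @export
fit_featurizer <- function(dataset, train_idx = NULL,
                           compound_provider = minimal_descriptor_provider(),
                           protein_provider = NULL) {
  stopifnot(inherits(dataset, "cpi_dataset"))
  n <- n_interactions(dataset)
  if (n == 0L) stopf("cannot fit a featurizer on a dataset with no interactions")
  train_idx <- train_idx %||% seq_len(n)
  inter <- dataset$interactions[train_idx, , drop = FALSE]
  train_comp <- unique(inter$compound_id)

  vocab <- build_vocabulary(
    dataset$compounds$smiles[dataset$compounds$compound_id %in% train_comp])
  store <- compute_entity_features(dataset, vocab, compound_provider,
                                   protein_provider)
  ci <- match(inter$compound_id, store$comp_ids)
  pi <- match(inter$protein_id, store$prot_ids)
  pp_comp <- fit_postprocessor(store$comp_desc[ci, , drop = FALSE])
  pp_prot <- fit_postprocessor(store$prot_desc[pi, , drop = FALSE])

  structure(list(vocab = vocab, compound_provider = compound_provider,
                 protein_provider = protein_provider,
                 pp_comp = pp_comp, pp_prot = pp_prot,
                 cache = store),
            class = "cpi_featurizer")
}

#' @export
print.cpi_featurizer <- function(x, ...) {
  cat(sprintf("<cpi_featurizer> vocab %d chars; compound global %d + %d cols; protein global %d cols\n",
              length(unclass(x$vocab)), ECFP_BITS, length(x$pp_comp$kept),
              length(x$pp_prot$kept)))
  invisible(x)
}

featurizer_widths <- function(featurizer) {
  list(compound_vocab_size = attr(featurizer$vocab, "size"),
       protein_vocab_size = AA_UNKNOWN_INDEX,
       compound_global_in = ECFP_BITS + length(featurizer$pp_comp$kept),
       protein_global_in = length(featurizer$pp_prot$kept))
}

#' Prepare model input features for a dataset
#'
#' Assembles the four model input blocks (and the affinity vector) for every
#' interaction of `dataset`, using the featurizer's vocabulary and fitted
#' postprocessors. Per-entity features are taken from the featurizer's cache
#' when `dataset` matches the one it was fitted on, and recomputed otherwise
#' (e.g. for a screening library or a transfer target set).
#'
#' @param featurizer a [fit_featurizer()] result.
#' @param dataset a [cpi_dataset()].
#' @return A feature list: `comp_tokens`, `comp_global`, `prot_tokens`,
#'   `prot_global`, `y`, `compound_id`, `protein_id`.
#' @export
prepare_features <- function(featurizer, dataset) {
  stopifnot(inherits(featurizer, "cpi_featurizer"),
            inherits(dataset, "cpi_dataset"))
  store <- featurizer$cache
  if (is.null(store) ||
      !identical(store$comp_ids, dataset$compounds$compound_id) ||
      !identical(store$prot_ids, dataset$proteins$protein_id)) {
    store <- compute_entity_features(dataset, featurizer$vocab,
                                     featurizer$compound_provider,
                                     featurizer$protein_provider)
  }
  inter <- dataset$interactions
  ci <- match(inter$compound_id, store$comp_ids)
  pi <- match(inter$protein_id, store$prot_ids)
  comp_desc <- apply_postprocessor(featurizer$pp_comp, store$comp_desc)
  prot_desc <- apply_postprocessor(featurizer$pp_prot, store$prot_desc)
  list(comp_tokens = store$comp_tokens[ci, , drop = FALSE],
       comp_global = cbind(store$comp_fp, comp_desc)[ci, , drop = FALSE],
       prot_tokens = store$prot_tokens[pi, , drop = FALSE],
       prot_global = prot_desc[pi, , drop = FALSE],
       y = inter$affinity,
       compound_id = inter$compound_id,
       protein_id = inter$protein_id)
}

subset_features <- function(features, idx) {
  list(comp_tokens = features$comp_tokens[idx, , drop = FALSE],
       comp_global = features$comp_global[idx, , drop = FALSE],
       prot_tokens = features$prot_tokens[idx, , drop = FALSE],
       prot_global = features$prot_global[idx, , drop = FALSE],
       y = features$y[idx],
       compound_id = features$compound_id[idx],
       protein_id = features$protein_id[idx])
}

# refit the postprocessor statistics of a featurizer on a transfer target's
# training rows, keeping the stored column identities so head widths match
refit_featurizer <- function(featurizer, dataset, train_idx) {
  store <- compute_entity_features(dataset, featurizer$vocab,
                                   featurizer$compound_provider,
                                   featurizer$protein_provider)
  inter <- dataset$interactions[train_idx, , drop = FALSE]
  ci <- match(inter$compound_id, store$comp_ids)
  pi <- match(inter$protein_id, store$prot_ids)
  featurizer$pp_comp <- refit_postprocessor(featurizer$pp_comp,
                                            store$comp_desc[ci, , drop = FALSE])
  featurizer$pp_prot <- refit_postprocessor(featurizer$pp_prot,
                                            store$prot_desc[pi, , drop = FALSE])
  featurizer$cache <- store
  featurizer
}
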