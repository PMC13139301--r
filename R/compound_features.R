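SMILES_ENCODING_LENGTH <- 100L
ECFP_BITS <- 1024L

#' Build a character vocabulary from a SMILES corpus
#'
#' Every character occurring in the corpus gets an integer index, assigned in
#' sorted character order starting at 1. Index 0 is reserved for padding and
#' the index after the last character is reserved for UNKNOWN characters met
#' at encoding time.
#'
#' @param smiles_corpus character vector of SMILES strings.
#' @return A `smiles_vocabulary`: named integer vector (names are characters)
#'   with attributes `unknown_index` and `size` (= number of characters + 1
#'   for UNKNOWN).
#' @examples
#' build_vocabulary(c("CCO", "c1ccccc1"))
#' @export
build_vocabulary <- function(smiles_corpus) {
  smiles_corpus <- smiles_corpus[!is.na(smiles_corpus) & nzchar(smiles_corpus)]
  if (!length(smiles_corpus)) stopf("empty SMILES corpus")
  chars <- sort(unique(unlist(strsplit(smiles_corpus, "", fixed = TRUE),
                              use.names = FALSE)), method = "radix")
  vocab <- stats::setNames(seq_along(chars), chars)
  structure(vocab, unknown_index = length(chars) + 1L,
            size = length(chars) + 1L, class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("<smiles_vocabulary> %d characters + UNKNOWN (index %d), 0 = padding\n",
              length(unclass(x)), attr(x, "unknown_index")))
  invisible(x)
}

#' Save / load a SMILES vocabulary as a plain-text key-value file
#' @param vocab a `smiles_vocabulary`.
#' @param path file path (tab-separated `character<TAB>index` lines).
#' @return `save_vocabulary`: the path, invisibly. `load_vocabulary`: the
#'   vocabulary.
#' @export
save_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  writeLines(sprintf("%s\t%d", names(vocab), as.integer(vocab)), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) stopf("malformed vocabulary file: %s", path)
  chars <- vapply(parts, `[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[`, character(1), 2L))
  if (anyNA(idx) || anyDuplicated(idx) || anyDuplicated(chars))
    stopf("malformed vocabulary file: %s", path)
  ord <- order(idx)
  vocab <- stats::setNames(idx[ord], chars[ord])
  structure(vocab, unknown_index = max(idx) + 1L, size = max(idx) + 1L,
            class = "smiles_vocabulary")
}

#' Label-encode a SMILES string to fixed length 100
#'
#' Characters map through the vocabulary; strings longer than 100 characters
#' are truncated, shorter ones zero-padded. Characters absent from the
#' vocabulary map to the UNKNOWN index with a warning.
#'
#' @param smiles single SMILES string (non-empty).
#' @param vocab a [build_vocabulary()] result.
#' @param warn_unknown warn when unknown characters are met (default TRUE).
#' @return Integer vector of length 100.
#' @export
encode_smiles <- function(smiles, vocab, warn_unknown = TRUE) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stopf("smiles must be a single non-empty string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(chars) > SMILES_ENCODING_LENGTH)
    chars <- chars[seq_len(SMILES_ENCODING_LENGTH)]
  ids <- unname(unclass(vocab)[chars])
  unk <- is.na(ids)
  if (any(unk)) {
    if (warn_unknown)
      warnf("%d character(s) not in vocabulary mapped to UNKNOWN: %s",
            sum(unk), paste(unique(chars[unk]), collapse = ""))
    ids[unk] <- attr(vocab, "unknown_index")
  }
  out <- integer(SMILES_ENCODING_LENGTH)
  out[seq_along(ids)] <- as.integer(ids)
  out
}

smiles_to_sdf <- function(smiles, ids = NULL) {
  ids <- ids %||% sprintf("cmpd_%d", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) stopf("unparseable SMILES among compound(s) %s (%s)",
                              paste(utils::head(ids, 5), collapse = ", "),
                              conditionMessage(e)))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok))
    stopf("unparseable SMILES for compound(s): %s",
          paste(utils::head(ids[!ok], 5), collapse = ", "))
  sdf
}

#' Compute 1,024-bit ECFP4 circular fingerprints
#'
#' Extended-connectivity (Morgan, radius 2) fingerprints computed on the
#' canonicalized molecule and folded to 1,024 bits, so the bit vector depends
#' only on the structure, not on the SMILES spelling.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers used in error messages.
#' @return Binary 0/1 matrix, one row per compound, 1,024 columns.
#' @examples
#' fp <- compute_ecfp4(c("c1ccccc1", "CCO"))
#' dim(fp)
#' @export
compute_ecfp4 <- function(smiles, ids = NULL) {
  ids <- ids %||% sprintf("cmpd_%d", seq_along(smiles))
  if (!length(smiles)) stopf("no SMILES supplied")
  sdf <- smiles_to_sdf(smiles, ids)
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  wide <- fp@fpma
  # fold to 1,024 bits by OR over the 4 aligned blocks
  nb <- ncol(wide)
  if (nb %% ECFP_BITS != 0L)
    stopf("unexpected fingerprint width %d", nb)
  folded <- matrix(0L, nrow(wide), ECFP_BITS)
  for (blk in seq_len(nb / ECFP_BITS)) {
    cols <- ((blk - 1L) * ECFP_BITS + 1L):(blk * ECFP_BITS)
    folded <- folded | wide[, cols, drop = FALSE]
  }
  folded <- matrix(as.integer(folded), nrow(wide), ECFP_BITS)
  rownames(folded) <- ids
  folded
}

#' Built-in minimal compound descriptor provider
#'
#' A small, dependency-light descriptor set: atom counts by element, ring and
#' bond counts, aromatic fraction, and OpenBabel-computed molecular weight,
#' logP, TPSA, molar refractivity and hydrogen-bond donor/acceptor counts.
#' The first column is the heavy-atom count. Entries that cannot be computed
#' are emitted as `NA` for [fit_postprocessor()] to handle.
#'
#' @return A provider object for [compute_compound_descriptors()].
#' @export
minimal_descriptor_provider <- function() {
  cols <- c("n_heavy", "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur",
            "n_halogen", "n_hetero", "n_rings", "n_aromatic_atoms",
            "frac_aromatic", "n_bonds", "n_double_bonds", "mw", "logp",
            "tpsa", "mr", "hbd", "hba")
  compute <- function(smiles, ids) {
    sdf <- smiles_to_sdf(smiles, ids)
    props <- ChemmineR::propOB(sdf)
    n <- length(smiles)
    out <- matrix(NA_real_, n, length(cols), dimnames = list(ids, cols))
    for (i in seq_len(n)) {
      mol <- sdf[[i]]
      ab <- ChemmineR::atomblock(mol)
      elements <- gsub("_.*$", "", rownames(ab))
      n_heavy <- sum(elements != "H")
      cnt <- function(e) sum(elements %in% e)
      ring_info <- tryCatch(
        ChemmineR::rings(mol, type = "all", arom = TRUE, inner = TRUE),
        error = function(e) list(RINGS = list(), AROMATIC = logical()))
      n_rings <- length(ring_info$RINGS)
      arom_atoms <- unique(unlist(ring_info$RINGS[ring_info$AROMATIC],
                                  use.names = FALSE))
      bb <- ChemmineR::bondblock(mol)
      out[i, ] <- c(n_heavy, cnt("C"), cnt("N"), cnt("O"), cnt("S"),
                    cnt(c("F", "Cl", "Br", "I")),
                    n_heavy - cnt("C"),
                    n_rings, length(arom_atoms),
                    if (n_heavy > 0) length(arom_atoms) / n_heavy else NA_real_,
                    nrow(bb), sum(bb[, 3] == 2),
                    props$MW[i], props$logP[i], props$TPSA[i], props$MR[i],
                    props$HBD[i], props$HBA1[i])
    }
    out
  }
  structure(list(name = "minimal", columns = cols, compute = compute),
            class = "descriptor_provider")
}

#' Compute compound descriptors through a provider
#'
#' Providers are a contract: a fixed, run-constant column set and a
#' `compute(smiles, ids)` function returning a numeric matrix with `NA`
#' markers for non-computable entries. The built-in
#' [minimal_descriptor_provider()] always works; wider external descriptor
#' sets can be bound by supplying another provider object.
#'
#' @param smiles character vector of SMILES strings.
#' @param provider a `descriptor_provider`
#'   (default [minimal_descriptor_provider()]).
#' @param ids optional identifiers for error messages and row names.
#' @return Numeric matrix, one row per compound, `length(provider$columns)`
#'   columns.
#' @export
compute_compound_descriptors <- function(smiles,
                                         provider = minimal_descriptor_provider(),
                                         ids = NULL) {
  if (!inherits(provider, "descriptor_provider"))
    stopf("provider must be a descriptor_provider object")
  ids <- ids %||% sprintf("cmpd_%d", seq_along(smiles))
  out <- provider$compute(smiles, ids)
  if (!is.matrix(out) || ncol(out) != length(provider$columns))
    stopf("provider '%s' violated its width contract", provider$name)
  out
}
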