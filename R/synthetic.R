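# Synthetic CPI benchmark with a planted local+global signal.
#
# The planted affinity is
#   y = b + w1 * 1[compound motif] * 1[protein motif]
#         + w2 * z(MW_compound) * z(hydrophobic fraction_protein) + eps
# so the interaction term is only visible to representations that resolve
# substructure/sequence matches (the local heads), while the property term
# is only visible to global physicochemical descriptors.

#' Specify the planted synthetic signal
#'
#' @param compound_motif SMILES substructure fragment appended to about half
#'   the generated compounds (default carboxyl, `"C(=O)O"`).
#' @param protein_motif amino-acid k-mer inserted into about half the
#'   generated proteins (default 5-mer `"WKRHW"`).
#' @param w_local weight of the motif-pair interaction term.
#' @param w_global weight of the MW x hydrophobicity property term.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param base baseline affinity level (pEC50-like scale).
#' @return A `signal_spec`.
#' @export
signal_spec <- function(compound_motif = "C(=O)O", protein_motif = "WKRHW",
                        w_local = 2, w_global = 1, noise_sd = 0.25,
                        base = 5) {
  if (!nzchar(compound_motif) || !nzchar(protein_motif))
    stopf("motifs must be non-empty")
  if (!is.finite(w_local) || !is.finite(w_global) || !is.finite(base))
    stopf("weights and base must be finite")
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(compound_motif = compound_motif,
                 protein_motif = protein_motif, w_local = w_local,
                 w_global = w_global, noise_sd = noise_sd, base = base),
            class = "signal_spec")
}

# fragment alphabet: every fragment starts at an atom and closes all its
# branches/rings, so any concatenation is a valid SMILES; none of them can
# spell the carboxyl motif across a boundary
SMILES_FRAGMENTS <- c("C", "CC", "CCC", "CCCC", "CO", "CCO", "CN", "CCN",
                      "c1ccccc1", "C(C)C", "CC(C)C", "CCOC", "CCS")

HEAVY_MASSES <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)

heavy_atom_mw <- function(smiles) {
  chars <- strsplit(toupper(smiles), "", fixed = TRUE)[[1]]
  sum(HEAVY_MASSES[chars], na.rm = TRUE)
}

#' Generate valid synthetic compounds from a fragment grammar
#'
#' SMILES are assembled by seeded concatenation of 2-5 fragments from a
#' fixed alphabet (alkyl chains, ether/amine/thioether links, benzene,
#' branched alkyls), guaranteeing chemical validity; about half the
#' compounds additionally receive the signal motif as a terminal cap and are
#' flagged in the metadata.
#'
#' @param n number of compounds (>= 1).
#' @param seed RNG seed.
#' @param motif terminal cap fragment marking "active" compounds.
#' @return Tibble with `compound_id`, `smiles`, `has_motif`, `mw`
#'   (heavy-atom molecular weight).
#' @export
generate_compounds <- function(n, seed = 1L, motif = "C(=O)O") {
  if (!is_count(n)) stopf("n must be a positive integer")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n_frag <- sample(2:5, n, replace = TRUE)
  has_motif <- stats::runif(n) < 0.5
  smiles <- vapply(seq_len(n), function(i) {
    body <- paste(sample(SMILES_FRAGMENTS, n_frag[i], replace = TRUE),
                  collapse = "")
    if (has_motif[i]) paste0(body, motif) else body
  }, character(1))
  tibble::tibble(compound_id = sprintf("CMP%05d", seq_len(n)),
                 smiles = smiles,
                 has_motif = has_motif,
                 mw = vapply(smiles, heavy_atom_mw, numeric(1),
                             USE.NAMES = FALSE))
}

HYDROPHOBIC_AA <- c("C", "L", "V", "I", "M", "F", "W")

#' Generate random synthetic proteins
#'
#' Uniform random sequences over the 20 standard amino acids; about half
#' receive the signal motif inserted (overwritten) at a random position and
#' the flag records actual substring presence.
#'
#' @param n number of proteins (>= 1).
#' @param length_range integer range of sequence lengths, within
#'   \[10, 2000\].
#' @param seed RNG seed.
#' @param motif the k-mer to plant (default length 5).
#' @return Tibble with `protein_id`, `sequence`, `has_motif`, `hydro_frac`
#'   (fraction of hydrophobic residues).
#' @export
generate_proteins <- function(n, length_range = c(30L, 100L), seed = 1L,
                              motif = "WKRHW") {
  if (!is_count(n)) stopf("n must be a positive integer")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 10L || length_range[2] > 2000L)
    stopf("length_range must be within [10, 2000]")
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(mchars %in% AA_ALPHABET))
    stopf("motif must use the 20 standard amino acids")
  if (length(mchars) > length_range[1])
    stopf("motif longer than the shortest allowed sequence")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
  plant <- stats::runif(n) < 0.5
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(AA_ALPHABET, lens[i], replace = TRUE)
    if (plant[i]) {
      at <- sample.int(lens[i] - length(mchars) + 1L, 1L)
      chars[at:(at + length(mchars) - 1L)] <- mchars
    }
    paste(chars, collapse = "")
  }, character(1))
  tibble::tibble(protein_id = sprintf("PRT%05d", seq_len(n)),
                 sequence = seqs,
                 has_motif = grepl(motif, seqs, fixed = TRUE),
                 hydro_frac = vapply(seqs, function(s) {
                   ch <- strsplit(s, "", fixed = TRUE)[[1]]
                   mean(ch %in% HYDROPHOBIC_AA)
                 }, numeric(1), USE.NAMES = FALSE))
}

#' Generate a synthetic CPI dataset with a planted local+global signal
#'
#' Samples `floor(density * n_compounds * n_proteins)` compound-protein
#' pairs and assigns each the affinity
#' `y = base + w_local * 1[both motifs present] +
#' w_global * z(MW) * z(hydrophobic fraction) + Normal(0, noise_sd^2)`,
#' where the z-scores are taken over the generated compound and protein
#' populations. The ground-truth signal components are stored in the
#' returned dataset's `truth` tibble for oracle tests.
#'
#' @param n_compounds,n_proteins population sizes.
#' @param density fraction of the compound x protein grid to sample, in
#'   (0, 1].
#' @param spec a [signal_spec()].
#' @param seed RNG seed (compounds, proteins, pair sampling and noise use
#'   derived sub-seeds).
#' @param length_range protein length range, as in [generate_proteins()].
#' @return A [cpi_dataset()] (`scale_tag = "pEC50"`) with an extra `truth`
#'   element.
#' @examples
#' ds <- generate_cpi_dataset(20, 5, 0.5, signal_spec(noise_sd = 0), seed = 7)
#' ds
#' @export
generate_cpi_dataset <- function(n_compounds, n_proteins, density,
                                 spec = signal_spec(), seed = 1L,
                                 length_range = c(30L, 100L)) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.numeric(density) || density <= 0 || density > 1)
    stopf("density must be in (0, 1]")
  comp <- generate_compounds(n_compounds, derive_seed(seed, 1L),
                             spec$compound_motif)
  prot <- generate_proteins(n_proteins, length_range, derive_seed(seed, 2L),
                            spec$protein_motif)
  m <- floor(density * n_compounds * n_proteins)
  if (m < 1L) stopf("density %.3g yields no interaction pairs", density)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 3L))
  sel <- sample.int(n_compounds * n_proteins, m)
  ci <- ((sel - 1L) %% n_compounds) + 1L
  pj <- ((sel - 1L) %/% n_compounds) + 1L

  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  z_mw <- zscore(comp$mw)
  z_hyd <- zscore(prot$hydro_frac)
  local_active <- comp$has_motif[ci] & prot$has_motif[pj]
  eps <- stats::rnorm(m, 0, spec$noise_sd)
  y <- spec$base + spec$w_local * as.numeric(local_active) +
    spec$w_global * z_mw[ci] * z_hyd[pj] + eps

  ds <- cpi_dataset(comp[, c("compound_id", "smiles")],
                    prot[, c("protein_id", "sequence")],
                    tibble::tibble(compound_id = comp$compound_id[ci],
                                   protein_id = prot$protein_id[pj],
                                   affinity = y),
                    scale_tag = "pEC50")
  ds$truth <- tibble::tibble(compound_id = comp$compound_id[ci],
                             protein_id = prot$protein_id[pj],
                             local_active = local_active,
                             z_mw = z_mw[ci], z_hyd = z_hyd[pj],
                             epsilon = eps, y = y)
  ds$signal <- spec
  ds$compound_meta <- comp
  ds$protein_meta <- prot
  ds
}

#' Build the desk-scale transfer-learning benchmark
#'
#' A large source task and a small (default 245-interaction) target task
#' drawn from fresh compound/protein populations with shifted base level and
#' signal weights, mirroring a pretrain-on-benchmark / fine-tune-on-assay
#' workflow.
#'
#' @param seed RNG seed.
#' @param source_spec,target_spec [signal_spec()]s for the two tasks.
#' @param n_source_compounds,n_source_proteins,source_density source task
#'   size (defaults give ~2,000 pairs).
#' @param n_target_compounds,n_target_proteins target task size (defaults
#'   give 49 x 5 = 245 pairs at density 1).
#' @return List with `source` and `target` datasets.
#' @export
transfer_benchmark <- function(seed = 1L,
                               source_spec = signal_spec(),
                               target_spec = signal_spec(w_local = 1.5,
                                                         w_global = 0.8,
                                                         base = 6.5),
                               n_source_compounds = 200L,
                               n_source_proteins = 20L,
                               source_density = 0.5,
                               n_target_compounds = 49L,
                               n_target_proteins = 5L) {
  list(source = generate_cpi_dataset(n_source_compounds, n_source_proteins,
                                     source_density, source_spec,
                                     seed = derive_seed(seed, 11L)),
       target = generate_cpi_dataset(n_target_compounds, n_target_proteins,
                                     1, target_spec,
                                     seed = derive_seed(seed, 13L)))
}
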