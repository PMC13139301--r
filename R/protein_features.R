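PROTEIN_ENCODING_LENGTH <- 1000L

# the 20 standard amino acids, alphabetical; indices 1..20, UNKNOWN = 21
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_UNKNOWN_INDEX <- 21L

# Standard 3-class groupings of the 20 amino acids under 7 physicochemical
# attributes, used by the composition/transition/distribution descriptors.
CTD_GROUPS <- list(
  hydrophobicity = list(g1 = c("R", "K", "E", "D", "Q", "N"),
                        g2 = c("G", "A", "S", "T", "P", "H", "Y"),
                        g3 = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(g1 = c("G", "A", "S", "T", "P", "D", "C"),
                    g2 = c("N", "V", "E", "Q", "I", "L"),
                    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
                  g2 = c("P", "A", "T", "G", "S"),
                  g3 = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(g1 = c("G", "A", "S", "D", "T"),
                        g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
                        g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(g1 = c("K", "R"),
                g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
                       "P", "S", "T", "W", "Y", "V"),
                g3 = c("D", "E")),
  secondary_structure = list(g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
                             g2 = c("V", "I", "Y", "C", "W", "F", "T"),
                             g3 = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
                               g2 = c("R", "K", "Q", "E", "N", "D"),
                               g3 = c("M", "S", "P", "T", "H", "Y")))

#' Label-encode a protein sequence to fixed length 1,000
#'
#' Uses the fixed alphabetical map A=1 ... Y=20; any other letter maps to the
#' UNKNOWN index 21. Sequences longer than 1,000 residues keep their first
#' 1,000; shorter ones are zero-padded.
#'
#' @param sequence single amino-acid string (one-letter codes, non-empty).
#' @return Integer vector of length 1,000 with entries in 0..21.
#' @examples
#' enc <- encode_sequence("ACDY")
#' enc[1:5]
#' @export
encode_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stopf("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) > PROTEIN_ENCODING_LENGTH)
    chars <- chars[seq_len(PROTEIN_ENCODING_LENGTH)]
  ids <- match(chars, AA_ALPHABET)
  ids[is.na(ids)] <- AA_UNKNOWN_INDEX
  out <- integer(PROTEIN_ENCODING_LENGTH)
  out[seq_along(ids)] <- ids
  out
}

aac_names <- function() paste0("AAC_", AA_ALPHABET)
dpc_names <- function() {
  paste0("DPC_", as.vector(outer(AA_ALPHABET, AA_ALPHABET,
                                 function(a, b) paste0(a, b))))
}
ctd_names <- function() {
  out <- character(0)
  for (attr_name in names(CTD_GROUPS)) {
    out <- c(out, paste0("CTDC_", attr_name, "_g", 1:3))
    out <- c(out, paste0("CTDT_", attr_name, "_", c("g1g2", "g1g3", "g2g3")))
    for (g in 1:3)
      out <- c(out, paste0("CTDD_", attr_name, "_g", g, "_",
                           c("first", "p25", "p50", "p75", "last")))
  }
  out
}

protein_descriptor_names <- function() c(aac_names(), dpc_names(), ctd_names())

compute_ctd_one <- function(chars) {
  n <- length(chars)
  out <- numeric(0)
  for (attr_name in names(CTD_GROUPS)) {
    groups <- CTD_GROUPS[[attr_name]]
    cls <- integer(n)
    for (g in 1:3) cls[chars %in% groups[[g]]] <- g
    comp <- tabulate(cls, 3) / n
    if (n >= 2) {
      a <- cls[-n]; b <- cls[-1]
      lo <- pmin(a, b); hi <- pmax(a, b)
      trans <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
                 sum(lo == 2 & hi == 3)) / (n - 1)
    } else trans <- c(0, 0, 0)
    dist <- numeric(15)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos)) {
        k <- length(pos)
        picks <- pos[pmax(1L, ceiling(k * c(0, 0.25, 0.5, 0.75, 1)))]
        picks[1] <- pos[1L]
        dist[(g - 1L) * 5L + 1:5] <- picks / n * 100
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Compute global protein descriptors
#'
#' The built-in provider emits, in fixed order: amino-acid composition (20),
#' overlapping dipeptide composition (400) and composition/transition/
#' distribution descriptors over 7 physicochemical attributes with 3 classes
#' each (21 + 21 + 105 = 147), for a total width of 567. Non-standard
#' residues are skipped with a warning; wider external descriptor sets can be
#' plugged in through the `provider` argument.
#'
#' @param sequences character vector of amino-acid sequences (each of length
#'   >= 2 after removing non-standard residues).
#' @param provider optional external provider: a list with `columns` and
#'   `compute(sequences, ids)`; default is the built-in 567-wide set.
#' @param ids optional identifiers for row names and error messages.
#' @return Numeric matrix, one row per sequence.
#' @examples
#' d <- compute_protein_descriptors("ACACAC")
#' d[1, "DPC_AC"]
#' @export
compute_protein_descriptors <- function(sequences, provider = NULL, ids = NULL) {
  ids <- ids %||% sprintf("prot_%d", seq_along(sequences))
  if (!length(sequences)) stopf("no sequences supplied")
  if (!is.null(provider)) {
    out <- provider$compute(sequences, ids)
    if (!is.matrix(out) || ncol(out) != length(provider$columns))
      stopf("protein descriptor provider violated its width contract")
    return(out)
  }
  cols <- protein_descriptor_names()
  out <- matrix(0, length(sequences), length(cols),
                dimnames = list(ids, cols))
  aa2 <- dpc_names()
  for (i in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[i]), "", fixed = TRUE)[[1]]
    keep <- chars %in% AA_ALPHABET
    if (any(!keep))
      warnf("protein %s: skipped %d non-standard residue(s) in descriptor computation",
            ids[i], sum(!keep))
    chars <- chars[keep]
    if (length(chars) < 2L)
      stopf("protein %s: fewer than 2 standard residues; descriptors undefined",
            ids[i])
    n <- length(chars)
    aac <- tabulate(match(chars, AA_ALPHABET), 20) / n
    dip <- paste0("DPC_", chars[-n], chars[-1])
    dpc <- tabulate(match(dip, aa2), 400) / (n - 1)
    out[i, ] <- c(aac, dpc, compute_ctd_one(chars))
  }
  out
}
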