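#' Construct a CPI dataset
#'
#' Bundles compound records, protein records and affinity-labelled interaction
#' records into a validated container. All interactions must share one affinity
#' scale (`"kiba"` or `"pEC50"`), every interaction must reference an existing
#' compound and protein, and duplicate (compound, protein) pairs are collapsed
#' by keeping the first occurrence.
#'
#' @param compounds data frame with columns `compound_id`, `smiles`.
#' @param proteins data frame with columns `protein_id`, `sequence`
#'   (amino-acid one-letter codes; non-standard letters are treated as
#'   UNKNOWN downstream).
#' @param interactions data frame with columns `compound_id`, `protein_id`,
#'   `affinity`.
#' @param scale_tag `"kiba"` or `"pEC50"`; the scale all affinities live on.
#' @return A `cpi_dataset`: a list with tibbles `compounds`, `proteins`,
#'   `interactions` and the `scale_tag`.
#' @export
cpi_dataset <- function(compounds, proteins, interactions,
                        scale_tag = c("kiba", "pEC50")) {
  scale_tag <- match.arg(scale_tag)
  compounds <- tibble::as_tibble(compounds)
  proteins <- tibble::as_tibble(proteins)
  interactions <- tibble::as_tibble(interactions)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stopf("%s is missing column(s): %s", what,
                            paste(miss, collapse = ", "))
  }
  need(compounds, c("compound_id", "smiles"), "compounds")
  need(proteins, c("protein_id", "sequence"), "proteins")
  need(interactions, c("compound_id", "protein_id", "affinity"),
       "interactions")

  compounds$compound_id <- as.character(compounds$compound_id)
  proteins$protein_id <- as.character(proteins$protein_id)
  interactions$compound_id <- as.character(interactions$compound_id)
  interactions$protein_id <- as.character(interactions$protein_id)
  interactions$affinity <- as.numeric(interactions$affinity)

  if (anyDuplicated(compounds$compound_id))
    stopf("duplicate compound_id values in compounds table")
  if (anyDuplicated(proteins$protein_id))
    stopf("duplicate protein_id values in proteins table")
  if (any(!nzchar(compounds$compound_id)) || any(!nzchar(compounds$smiles)))
    stopf("compound_id and smiles must be non-empty")
  if (any(!nzchar(proteins$protein_id)) || any(!nzchar(proteins$sequence)))
    stopf("protein_id and sequence must be non-empty")
  bad_seq <- grepl("[^A-Za-z]", proteins$sequence)
  if (any(bad_seq))
    stopf("protein sequence(s) contain non-letter characters: %s",
          paste(utils::head(proteins$protein_id[bad_seq], 3), collapse = ", "))

  if (nrow(interactions)) {
    if (any(!is.finite(interactions$affinity)))
      stopf("non-finite affinity in interaction row(s): %s",
            paste(utils::head(which(!is.finite(interactions$affinity)), 5),
                  collapse = ", "))
    dup <- duplicated(interactions[, c("compound_id", "protein_id")])
    if (any(dup)) {
      msgf("collapsed %d duplicate (compound, protein) pair(s), keeping first occurrence",
           sum(dup))
      interactions <- interactions[!dup, , drop = FALSE]
    }
    miss_c <- setdiff(interactions$compound_id, compounds$compound_id)
    miss_p <- setdiff(interactions$protein_id, proteins$protein_id)
    if (length(miss_c)) stopf("interaction references unknown compound_id: %s",
                              paste(utils::head(miss_c, 3), collapse = ", "))
    if (length(miss_p)) stopf("interaction references unknown protein_id: %s",
                              paste(utils::head(miss_p, 3), collapse = ", "))
  }

  structure(list(compounds = compounds, proteins = proteins,
                 interactions = interactions, scale_tag = scale_tag),
            class = "cpi_dataset")
}

#' @export
print.cpi_dataset <- function(x, ...) {
  cat(sprintf("<cpi_dataset> %d interactions between %d compounds and %d proteins (scale: %s)\n",
              nrow(x$interactions), nrow(x$compounds), nrow(x$proteins),
              x$scale_tag))
  invisible(x)
}

#' Number of interactions in a CPI dataset
#' @param dataset a `cpi_dataset`.
#' @return Integer interaction count.
#' @export
n_interactions <- function(dataset) nrow(dataset$interactions)

default_cpi_schema <- function() {
  list(compound_id = "compound_id", smiles = "smiles",
       protein_id = "protein_id", sequence = "sequence",
       affinity = "affinity")
}

read_delim_table <- function(path, sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, fileEncoding = "UTF-8")
}

#' Load a CPI affinity table
#'
#' Reads a delimited text file with one interaction per row (compound id and
#' SMILES, protein id and sequence, affinity value) into a validated
#' [cpi_dataset()]. Duplicate (compound, protein) pairs are collapsed to the
#' first occurrence with a message. Affinities that fail to parse to a finite
#' number are reported with their file line number.
#'
#' @param path path to a CSV (or TSV, see `sep`) file with a header row.
#' @param schema named list mapping the canonical roles `compound_id`,
#'   `smiles`, `protein_id`, `sequence`, `affinity` to the file's column
#'   names; defaults to identically named columns.
#' @param scale_tag affinity scale of the file, `"kiba"` (default) or
#'   `"pEC50"`.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return A `cpi_dataset`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(compound_id = "c1", smiles = "CCO",
#'                      protein_id = "p1", sequence = "MKV", affinity = 11.2),
#'           tf, row.names = FALSE)
#' load_cpi_table(tf)
#' @export
load_cpi_table <- function(path, schema = default_cpi_schema(),
                           scale_tag = c("kiba", "pEC50"), sep = ",") {
  scale_tag <- match.arg(scale_tag)
  schema <- utils::modifyList(default_cpi_schema(), as.list(schema))
  raw <- read_delim_table(path, sep = sep)
  miss <- setdiff(unlist(schema), names(raw))
  if (length(miss))
    stopf("schema error: column(s) %s not present in %s",
          paste(miss, collapse = ", "), path)

  if (nrow(raw) == 0L) {
    empty_c <- tibble::tibble(compound_id = character(), smiles = character())
    empty_p <- tibble::tibble(protein_id = character(), sequence = character())
    empty_i <- tibble::tibble(compound_id = character(),
                              protein_id = character(), affinity = numeric())
    return(cpi_dataset(empty_c, empty_p, empty_i, scale_tag))
  }

  aff <- suppressWarnings(as.numeric(raw[[schema$affinity]]))
  bad <- which(!is.finite(aff))
  if (length(bad))
    stopf("unparseable affinity at file line(s): %s",
          paste(utils::head(bad + 1L, 5), collapse = ", "))  # +1 for header

  inter <- tibble::tibble(compound_id = as.character(raw[[schema$compound_id]]),
                          protein_id = as.character(raw[[schema$protein_id]]),
                          affinity = aff)
  comp <- tibble::tibble(compound_id = as.character(raw[[schema$compound_id]]),
                         smiles = as.character(raw[[schema$smiles]]))
  comp <- comp[!duplicated(comp$compound_id), , drop = FALSE]
  prot <- tibble::tibble(protein_id = as.character(raw[[schema$protein_id]]),
                         sequence = toupper(as.character(raw[[schema$sequence]])))
  prot <- prot[!duplicated(prot$protein_id), , drop = FALSE]
  cpi_dataset(comp, prot, inter, scale_tag)
}

#' Load a concentration-response activity table as pEC50
#'
#' Reads an activity file (e.g. a ChEMBL EC50 export) and stores the affinity
#' as pEC50 = -log10(EC50 in molar). Concentration values must be strictly
#' positive; values already on the pEC50 scale are taken as-is.
#'
#' @param path path to the delimited file.
#' @param value_column name of the activity-value column.
#' @param value_units units of that column: `"nM"`, `"uM"`, `"M"` or
#'   `"pEC50"`.
#' @param schema as in [load_cpi_table()]; the `affinity` role is ignored in
#'   favour of `value_column`.
#' @param sep field separator.
#' @return A `cpi_dataset` with `scale_tag = "pEC50"`.
#' @export
load_activity_csv <- function(path, value_column, value_units,
                              schema = default_cpi_schema(), sep = ",") {
  units_tab <- c(nM = 1e-9, uM = 1e-6, M = 1)
  if (!value_units %in% c(names(units_tab), "pEC50"))
    stopf("config error: unknown value_units '%s' (use nM, uM, M or pEC50)",
          value_units)
  schema <- utils::modifyList(default_cpi_schema(), as.list(schema))
  schema$affinity <- value_column
  raw <- read_delim_table(path, sep = sep)
  if (!value_column %in% names(raw))
    stopf("schema error: value column '%s' not present in %s",
          value_column, path)

  vals <- suppressWarnings(as.numeric(raw[[value_column]]))
  if (value_units %in% names(units_tab)) {
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad))
      stopf("non-positive or unparseable concentration at file line(s): %s",
            paste(utils::head(bad + 1L, 5), collapse = ", "))
    raw[[value_column]] <- -log10(vals * units_tab[[value_units]])
  } else {
    raw[[value_column]] <- vals
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(raw, tmp, row.names = FALSE)
  load_cpi_table(tmp, schema = schema, scale_tag = "pEC50")
}

#' Write model predictions to a CSV file
#'
#' @param records data frame with columns `compound_id`, `protein_id`,
#'   `predicted_affinity`; must have at least one row.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(records, path) {
  records <- as.data.frame(records)
  need <- c("compound_id", "protein_id", "predicted_affinity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stopf("refusing to write an empty prediction table")
  out <- records[, need]
  out$predicted_affinity <- sprintf("%.17g", out$predicted_affinity)
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stopf("cannot write predictions to %s: %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' Read model predictions written by [write_predictions()]
#' @param path the CSV file.
#' @return Tibble with `compound_id`, `protein_id`, `predicted_affinity`.
#' @export
read_predictions <- function(path) {
  raw <- read_delim_table(path)
  tibble::tibble(compound_id = as.character(raw$compound_id),
                 protein_id = as.character(raw$protein_id),
                 predicted_affinity = as.numeric(raw$predicted_affinity))
}

#' Read a SMI compound list
#'
#' One compound per line: a SMILES string optionally followed by whitespace
#' and an identifier. Missing identifiers become `cmpd_<line>`.
#'
#' @param path SMI file path.
#' @return Tibble with `compound_id`, `smiles`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(compound_id = character(), smiles = character()))
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("cmpd_%d", i)
  }, character(1))
  tibble::tibble(compound_id = ids, smiles = smiles)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file path.
#' @return Tibble with `protein_id` (first word of the header) and `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
  tibble::tibble(protein_id = ids, sequence = unname(as.character(seqs)))
}
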