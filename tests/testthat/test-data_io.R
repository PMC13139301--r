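cpi_rows <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c3", "c1", "c2"),
    smiles = c("CCO", "c1ccccc1", "CCN", "CCO", "c1ccccc1"),
    protein_id = c("p1", "p1", "p2", "p1", "p2"),
    sequence = c("MKVA", "MKVA", "ACDEF", "MKVA", "ACDEF"),
    affinity = c(11.2, 10.1, 12.9, 99, 8.4),
    stringsAsFactors = FALSE)
}

test_that("load_cpi_table builds a valid dataset and collapses duplicates first-wins", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, cpi_rows())
  expect_message(ds <- load_cpi_table(tf), "1 duplicate")
  expect_s3_class(ds, "cpi_dataset")
  # 5 rows with one duplicated (c1,p1) pair -> 4 interactions retained
  expect_equal(n_interactions(ds), 4L)
  expect_equal(nrow(ds$compounds), 3L)
  expect_equal(nrow(ds$proteins), 2L)
  # first-occurrence affinity kept, not the later 99
  kept <- ds$interactions$affinity[ds$interactions$compound_id == "c1" &
                                     ds$interactions$protein_id == "p1"]
  expect_equal(kept, 11.2)
})

test_that("load_cpi_table handles empty files, schema errors, and bad affinities", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, cpi_rows()[0, ])
  ds <- load_cpi_table(tf)
  expect_equal(n_interactions(ds), 0L)

  rows <- cpi_rows(); names(rows)[5] <- "kiba_score"
  write_cpi_fixture_csv(tf, rows)
  expect_error(load_cpi_table(tf), "schema error")
  expect_equal(n_interactions(load_cpi_table(tf, schema = list(affinity = "kiba_score"))),
               4L)

  rows <- cpi_rows(); rows$affinity <- as.character(rows$affinity)
  rows$affinity[3] <- "not-a-number"
  write_cpi_fixture_csv(tf, rows)
  expect_error(load_cpi_table(tf), "line.*4")  # header + 3

  expect_error(load_cpi_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("load_cpi_table accepts tab-separated input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cpi_rows()[1:3, ], tf, sep = "\t", row.names = FALSE)
  expect_equal(n_interactions(load_cpi_table(tf, sep = "\t")), 3L)
})

test_that("load_activity_csv converts concentrations to pEC50 = -log10(molar)", {
  rows <- data.frame(compound_id = c("a", "b", "c"),
                     smiles = c("CCO", "CCN", "CCC"),
                     protein_id = "p1", sequence = "MKVAW",
                     ec50 = c(1000, 1e9, 42))  # nM
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, rows)
  ds <- load_activity_csv(tf, value_column = "ec50", value_units = "nM")
  expect_equal(ds$scale_tag, "pEC50")
  expect_equal(ds$interactions$affinity[1], 6.0)  # 1000 nM = 1e-6 M
  expect_equal(ds$interactions$affinity[2], 0.0)  # 1e9 nM = 1 M
  rows$ec50 <- c(37, 1, 2)  # uM
  write_cpi_fixture_csv(tf, rows)
  ds <- load_activity_csv(tf, value_column = "ec50", value_units = "uM")
  expect_equal(ds$interactions$affinity[1], 4.4318, tolerance = 1e-4)
})

test_that("load_activity_csv rejects non-positive concentrations and unknown units", {
  rows <- data.frame(compound_id = "a", smiles = "CCO", protein_id = "p1",
                     sequence = "MKVAW", ec50 = -5)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, rows)
  expect_error(load_activity_csv(tf, "ec50", "nM"), "non-positive")
  expect_error(load_activity_csv(tf, "ec50", "furlongs"), "config error")
})

test_that("pEC50 transform is strictly decreasing in EC50", {
  ec50 <- sort(10^stats::runif(25, -3, 9))  # nM span
  rows <- data.frame(compound_id = sprintf("c%02d", 1:25), smiles = "CCO",
                     protein_id = "p1", sequence = "MKVAW", ec50 = ec50)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, rows)
  ds <- load_activity_csv(tf, "ec50", "nM")
  expect_true(all(diff(ds$interactions$affinity) < 0))
})

test_that("predictions round-trip through write/read at full precision", {
  preds <- tibble::tibble(compound_id = c("c1", "c2", "c3"),
                          protein_id = c("p1", "p2", "p1"),
                          predicted_affinity = c(pi, exp(1), 1 / 3))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_predictions(preds, tf)
  expect_length(readLines(tf), 4L)  # header + 3 rows
  back <- read_predictions(tf)
  expect_identical(back$compound_id, preds$compound_id)
  expect_true(max(abs(back$predicted_affinity - preds$predicted_affinity)) < 1e-12)
  expect_error(write_predictions(preds[0, ], tf), "empty")
})

test_that("load -> write -> load is idempotent on retained records", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cpi_fixture_csv(tf, cpi_rows())
  suppressMessages(ds1 <- load_cpi_table(tf))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  out <- ds1$interactions
  merged <- merge(merge(out, ds1$compounds, by = "compound_id"),
                  ds1$proteins, by = "protein_id")
  write_cpi_fixture_csv(tf2, merged)
  ds2 <- load_cpi_table(tf2)
  key <- function(d) {
    i <- d$interactions[order(d$interactions$compound_id,
                              d$interactions$protein_id), ]
    paste(i$compound_id, i$protein_id, i$affinity)
  }
  expect_identical(key(ds2), key(ds1))
})

test_that("SMI and FASTA readers parse ids and bodies", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1"), smi)
  tab <- read_smi(smi)
  expect_identical(tab$compound_id, c("ethanol", "cmpd_2"))
  expect_identical(tab$smiles, c("CCO", "c1ccccc1"))

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">protA kinase domain", "MKVAW", "ACDEF", ">protB", "GGGG"), fa)
  prot <- read_fasta_proteins(fa)
  expect_identical(prot$protein_id, c("protA", "protB"))
  expect_identical(prot$sequence, c("MKVAWACDEF", "GGGG"))
})

test_that("cpi_dataset enforces referential integrity and a single scale", {
  comp <- tibble::tibble(compound_id = "c1", smiles = "CCO")
  prot <- tibble::tibble(protein_id = "p1", sequence = "MKVA")
  bad <- tibble::tibble(compound_id = "cX", protein_id = "p1", affinity = 1)
  expect_error(cpi_dataset(comp, prot, bad), "unknown compound_id")
  bad2 <- tibble::tibble(compound_id = "c1", protein_id = "p1", affinity = NaN)
  expect_error(cpi_dataset(comp, prot, bad2), "non-finite")
  expect_error(cpi_dataset(comp[c(1, 1), ], prot,
                           tibble::tibble(compound_id = character(),
                                          protein_id = character(),
                                          affinity = numeric())),
               "duplicate compound_id")
})
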