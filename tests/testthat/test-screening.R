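random_screen_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    compound_id = sprintf("CMP%06d", sample.int(10 * n, n)),
    predicted_affinity = round(rnorm(n, 6, 1), 3),
    docking_score = round(runif(n, -10, -4), 2),
    qikprop_stars = sample(0:8, n, replace = TRUE)))
}

test_that("top-fraction selection takes floor(fraction * n) rows, highest first", {
  tab <- random_screen_table(1000, 1)
  top <- select_top_fraction(tab, 0.10)
  expect_equal(nrow(top), 100L)
  expect_gte(min(top$predicted_affinity),
             max(tab$predicted_affinity[!tab$compound_id %in% top$compound_id]))

  expect_equal(nrow(select_top_fraction(tab[1:10, ], 1.0)), 10L)
  expect_warning(zero <- select_top_fraction(tab[1:7, ], 0.10), "0 compounds")
  expect_equal(nrow(zero), 0L)
  expect_error(select_top_fraction(tab[0, ], 0.10), "empty")
  expect_error(select_top_fraction(tab, 1.5), "fraction")
})

test_that("ties at the selection boundary break by compound_id deterministically", {
  tab <- tibble::tibble(compound_id = c("z9", "a1", "m5", "b2", "x7",
                                        "c3", "d4", "e5", "f6", "g7"),
                        predicted_affinity = c(rep(7, 5), rep(5, 5)))
  top <- select_top_fraction(tab, 0.3)
  # all candidates tie at 7; the 3 lexicographically smallest ids win
  expect_identical(top$compound_id, c("a1", "b2", "m5"))
  expect_identical(select_top_fraction(tab, 0.3)$compound_id,
                   top$compound_id)
})

test_that("candidate filters use strict thresholds at the -7 / 5-star boundaries", {
  tab <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
                        predicted_affinity = 6,
                        docking_score = c(-7.0, -7.3, -8.1, -7.5),
                        qikprop_stars = c(4, 4, 5, 0))
  kept <- apply_candidate_filters(tab)
  # -7.0 exactly fails the strict docking rule; 5 stars fails the star rule
  expect_identical(kept$compound_id, c("b", "d"))
  inclusive <- apply_candidate_filters(tab, strict = FALSE)
  expect_identical(inclusive$compound_id, c("a", "b", "c", "d"))
  expect_error(apply_candidate_filters(tab, docking_threshold = "low"),
               "config error")
})

test_that("a constructed fixture keeps exactly its designed survivors", {
  withr::with_seed(8, {
    good <- tibble::tibble(compound_id = sprintf("good%02d", 1:6),
                           predicted_affinity = rnorm(6, 7),
                           docking_score = runif(6, -9, -7.01),
                           qikprop_stars = sample(0:4, 6, replace = TRUE))
    bad <- tibble::tibble(compound_id = sprintf("bad%02d", 1:14),
                          predicted_affinity = rnorm(14, 7),
                          docking_score = c(runif(7, -6.9, -4), runif(7, -9, -7.1)),
                          qikprop_stars = c(sample(0:4, 7, TRUE), sample(5:8, 7, TRUE)))
  })
  kept <- apply_candidate_filters(rbind(good, bad))
  expect_setequal(kept$compound_id, good$compound_id)
})

test_that("rows with missing filter values are dropped and counted", {
  tab <- random_screen_table(10, 3)
  tab$docking_score[c(2, 5)] <- NA
  expect_message(kept <- apply_candidate_filters(tab), "2 row")
  expect_false(any(kept$compound_id %in% tab$compound_id[c(2, 5)]))
})

test_that("filters are idempotent and compose with ranking as a set intersection", {
  tab <- random_screen_table(400, 21)
  once <- apply_candidate_filters(tab)
  twice <- apply_candidate_filters(once)
  expect_identical(twice, once)

  cascade <- screen_candidates(tab, fraction = 0.25)
  top <- select_top_fraction(tab, 0.25)
  direct <- tab[tab$compound_id %in% top$compound_id &
                  tab$docking_score < -7 & tab$qikprop_stars < 5, ]
  expect_setequal(cascade$compound_id, direct$compound_id)
})

test_that("top-fraction size law holds over random tables", {
  withr::with_seed(31, {
    for (case in 1:15) {
      n <- sample(1:500, 1)
      fr <- runif(1, 0.01, 1)
      tab <- random_screen_table(n, case + 100)
      got <- suppressWarnings(nrow(select_top_fraction(tab, fr)))
      expect_equal(got, floor(fr * n))
    }
  })
})

test_that("Lipinski violation counts follow the boundary-inclusive rule of five", {
  expect_equal(lipinski_violations(500, 5, 5, 10), 0L)
  expect_equal(lipinski_violations(600, 5, 5, 10), 1L)
  expect_equal(lipinski_violations(600, 6, 7, 12), 4L)
  expect_equal(lipinski_violations(MW = c(400, 501), logP = c(1, 6),
                                   HBD = c(0, 6), HBA = c(2, 11)),
               c(0L, 4L))
  expect_error(lipinski_violations(400, NA, 1, 2), "logP")
})
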