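#' Select the top fraction of a screening table by predicted affinity
#'
#' Returns the `floor(fraction * n)` rows with the highest
#' `predicted_affinity`. Ties at the cut are broken deterministically by
#' lexicographic `compound_id`, so every selected score is greater than or
#' equal to every unselected score.
#'
#' @param table data frame with at least `compound_id` (unique) and
#'   `predicted_affinity` (finite).
#' @param fraction fraction to keep, in (0, 1]; default 0.10.
#' @return The selected rows, ordered by decreasing predicted affinity.
#' @examples
#' tab <- data.frame(compound_id = sprintf("c%02d", 1:20),
#'                   predicted_affinity = 21 - (1:20))
#' nrow(select_top_fraction(tab, 0.10))
#' @export
select_top_fraction <- function(table, fraction = 0.10) {
  table <- tibble::as_tibble(table)
  if (!nrow(table)) stopf("empty screening table")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stopf("fraction must be a single number in (0, 1]")
  check_screening_table(table)
  k <- floor(fraction * nrow(table))
  if (k == 0L) {
    warnf("top fraction %.3g of %d rows selects 0 compounds", fraction,
          nrow(table))
    return(table[0, , drop = FALSE])
  }
  ord <- order(-table$predicted_affinity, table$compound_id, method = "radix")
  table[ord[seq_len(k)], , drop = FALSE]
}

check_screening_table <- function(table) {
  miss <- setdiff(c("compound_id", "predicted_affinity"), names(table))
  if (length(miss)) stopf("screening table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(table$compound_id))
    stopf("duplicate compound_id in screening table")
  if (any(!is.finite(table$predicted_affinity)))
    stopf("non-finite predicted_affinity in screening table")
  invisible(TRUE)
}

#' Filter screening candidates by docking score and QikProp stars
#'
#' Keeps rows with `docking_score` strictly below `docking_threshold` AND
#' `qikprop_stars` strictly below `stars_threshold` (both thresholds read as
#' strict inequalities; boundary rows are excluded). Rows with a missing
#' value in either column are dropped and counted in a message. Set
#' `strict = FALSE` for inclusive boundaries if parity with another tool is
#' needed.
#'
#' @param table data frame with `docking_score` (lower is better) and
#'   `qikprop_stars` (non-negative integer) columns.
#' @param docking_threshold docking-score cut, default -7.
#' @param stars_threshold star-count cut, default 5.
#' @param strict use strict inequalities (default TRUE).
#' @return The retained rows.
#' @export
apply_candidate_filters <- function(table, docking_threshold = -7,
                                    stars_threshold = 5, strict = TRUE) {
  table <- tibble::as_tibble(table)
  if (!is.numeric(docking_threshold) || !is.numeric(stars_threshold))
    stopf("config error: thresholds must be numeric")
  miss <- setdiff(c("docking_score", "qikprop_stars"), names(table))
  if (length(miss)) stopf("screening table missing column(s): %s",
                          paste(miss, collapse = ", "))
  ds <- as.numeric(table$docking_score)
  st <- as.numeric(table$qikprop_stars)
  incomplete <- !is.finite(ds) | !is.finite(st)
  if (any(incomplete))
    msgf("dropped %d row(s) with missing docking score or star count",
         sum(incomplete))
  keep <- if (strict) ds < docking_threshold & st < stars_threshold
          else ds <= docking_threshold & st <= stars_threshold
  table[which(!incomplete & keep), , drop = FALSE]
}

#' Count Lipinski rule-of-five violations
#'
#' Counts how many of the four oral drug-likeness rules are violated:
#' MW > 500, logP > 5, H-bond donors > 5, H-bond acceptors > 10. Boundary
#' values violate nothing.
#'
#' @param MW molecular weight (Da).
#' @param logP octanol-water partition coefficient.
#' @param HBD hydrogen-bond donor count.
#' @param HBA hydrogen-bond acceptor count.
#' @return Integer vector of violation counts (0-4); vectorized over the
#'   inputs.
#' @examples
#' lipinski_violations(500, 5, 5, 10)  # 0
#' lipinski_violations(600, 6, 7, 12)  # 4
#' @export
lipinski_violations <- function(MW, logP, HBD, HBA) {
  args <- list(MW = MW, logP = logP, HBD = HBD, HBA = HBA)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || !length(args[[nm]]) || anyNA(args[[nm]]))
      stopf("missing property: %s", nm)
  }
  as.integer((MW > 500) + (logP > 5) + (HBD > 5) + (HBA > 10))
}

#' Run the screening cascade: rank, take the top fraction, filter
#'
#' Composition of [select_top_fraction()] and [apply_candidate_filters()]
#' in the standard virtual-screening order.
#'
#' @param table screening table with `compound_id`, `predicted_affinity`,
#'   `docking_score` and `qikprop_stars`.
#' @inheritParams select_top_fraction
#' @inheritParams apply_candidate_filters
#' @return The candidate rows.
#' @export
screen_candidates <- function(table, fraction = 0.10, docking_threshold = -7,
                              stars_threshold = 5, strict = TRUE) {
  top <- select_top_fraction(table, fraction)
  if (!nrow(top)) return(top)
  apply_candidate_filters(top, docking_threshold, stars_threshold, strict)
}
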