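#' Fit a descriptor postprocessor on training rows
#'
#' Drops every column with any null/non-finite entry or zero variance on the
#' training matrix, and records per-column training means and standard
#' deviations for z-scoring. Apply-time nulls are imputed with the training
#' mean (0 after scaling), so downstream features are always finite.
#'
#' @param training_matrix numeric matrix (rows = training compounds/proteins).
#' @return A `feature_postprocessor` with `kept`, `mean`, `sd` and the
#'   original column count.
#' @export
fit_postprocessor <- function(training_matrix) {
  training_matrix <- as.matrix(training_matrix)
  if (!nrow(training_matrix)) stopf("cannot fit postprocessor on 0 rows")
  has_na <- apply(training_matrix, 2, function(x) any(!is.finite(x)))
  sds <- apply(training_matrix, 2, function(x)
    if (any(!is.finite(x))) NA_real_ else stats::sd(x))
  # single-row training sets have undefined sample sd; treat as zero variance
  zero_var <- !is.finite(sds) | sds == 0
  kept <- which(!has_na & !zero_var)
  if (!length(kept))
    stopf("postprocessor kept no columns: all have nulls or zero variance")
  mu <- colMeans(training_matrix[, kept, drop = FALSE])
  sdv <- sds[kept]
  structure(list(kept = kept, mean = mu, sd = sdv,
                 n_input = ncol(training_matrix),
                 colnames = colnames(training_matrix)),
            class = "feature_postprocessor")
}

#' Apply a fitted postprocessor
#'
#' @param pp a [fit_postprocessor()] result.
#' @param matrix numeric matrix with the same column count the postprocessor
#'   was fitted on.
#' @return Matrix restricted to the kept columns, z-scored with the stored
#'   training statistics; never contains non-finite values.
#' @export
apply_postprocessor <- function(pp, matrix) {
  if (!inherits(pp, "feature_postprocessor"))
    stopf("apply_postprocessor called before fit: pp is not a feature_postprocessor")
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != pp$n_input)
    stopf("width mismatch: postprocessor fitted on %d columns, got %d",
          pp$n_input, ncol(matrix))
  x <- matrix[, pp$kept, drop = FALSE]
  x <- sweep(x, 2, pp$mean, "-")
  x <- sweep(x, 2, pp$sd, "/")
  x[!is.finite(x)] <- 0  # impute apply-time nulls with the training mean
  x
}

# refit mean/sd on new training rows while keeping the stored column
# identities (used by transfer learning so head widths stay compatible);
# columns degenerate on the new rows are centred only
refit_postprocessor <- function(pp, training_matrix) {
  training_matrix <- as.matrix(training_matrix)
  if (ncol(training_matrix) != pp$n_input)
    stopf("width mismatch: postprocessor fitted on %d columns, got %d",
          pp$n_input, ncol(training_matrix))
  x <- training_matrix[, pp$kept, drop = FALSE]
  mu <- apply(x, 2, function(v) mean(v[is.finite(v)]))
  mu[!is.finite(mu)] <- 0
  sdv <- apply(x, 2, function(v) stats::sd(v[is.finite(v)]))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  pp$mean <- mu
  pp$sd <- sdv
  pp
}
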