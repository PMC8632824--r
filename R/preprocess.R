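#' Filter low-expressed genes
#'
#' Keeps genes whose mean raw count across all samples reaches
#' \code{min_mean}; gene order is preserved. With \code{min_mean = 0} this is
#' the identity.
#'
#' @param experiment A \code{\link{counts_experiment}}.
#' @param min_mean Minimum mean count (default 1).
#' @return A filtered \code{counts_experiment}; warns (does not error) when
#'   no gene survives.
#' @export
filter_low_expressed <- function(experiment, min_mean = 1) {
  stopifnot(inherits(experiment, "counts_experiment"))
  if (min_mean < 0) stopf("min_mean must be nonnegative")
  keep <- rowMeans(experiment$counts) >= min_mean
  if (!any(keep)) warnf("no genes pass the mean-count filter (min_mean = %g)",
                        min_mean)
  counts_experiment(experiment$counts[keep, , drop = FALSE], experiment$design)
}

## per-sample upper-quartile factor: 75th percentile (linear interpolation)
## of the sample's nonzero counts
uq_factors <- function(mat) {
  raw <- apply(mat, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  })
  bad <- is.na(raw)
  if (any(bad)) {
    stopf("sample(s) with all-zero counts cannot be normalized: %s",
          paste(colnames(mat)[bad], collapse = ", "))
  }
  raw / exp(mean(log(raw)))  # rescale to geometric mean 1
}

#' Upper-quartile normalization
#'
#' Scales each sample by the 75th percentile of its nonzero counts, with the
#' factors rescaled to geometric mean 1 so normalized values stay on the
#' counts scale. Also returns log2(normalized + 1), the modeling scale used
#' by the time-course fits.
#'
#' @param x A \code{\link{counts_experiment}}, or a bare nonnegative matrix.
#' @return An object of class \code{normalized_matrix}: list with
#'   \code{values}, \code{size_factors}, \code{log2} and (when available)
#'   \code{design}.
#' @export
upper_quartile_normalize <- function(x) {
  if (inherits(x, "counts_experiment")) {
    mat <- x$counts
    design <- x$design
  } else {
    mat <- as.matrix(x)
    design <- NULL
  }
  if (any(mat < 0)) stopf("negative values cannot be normalized")
  f <- uq_factors(mat)
  values <- sweep(mat, 2, f, "/")
  structure(list(values = values,
                 size_factors = f,
                 log2 = log2(values + 1),
                 design = design),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (upper-quartile, geometric-mean-1 factors)\n")
  cat("  size factor range:",
      paste(signif(range(x$size_factors), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Write a normalized matrix and its size factors
#'
#' @param norm A \code{normalized_matrix}.
#' @param values_path TSV path for the normalized values.
#' @param factors_path TSV path for the per-sample size factors.
#' @return Invisibly, the written paths.
#' @export
write_normalized_matrix <- function(norm, values_path, factors_path) {
  utils::write.table(
    data.frame(gene_id = rownames(norm$values), norm$values, check.names = FALSE),
    values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(norm$values),
               size_factor = norm$size_factors),
    factors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(values = values_path, factors = factors_path))
}
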