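#' Construct a counts experiment
#'
#' Bundle a gene-by-sample matrix of raw RNA-seq counts with its per-sample
#' design metadata (genotype, tissue, irrigation condition, week, replicate
#' plot). This is the container every transcriptome stage consumes.
#'
#' @param counts Integer matrix, genes as rows, samples as columns. Row and
#'   column names are required and must be unique.
#' @param design Data frame with one row per sample and columns
#'   \code{sample_id}, \code{genotype}, \code{tissue}, \code{condition},
#'   \code{week} (numeric, weeks after emergence), \code{replicate}.
#' @return An object of class \code{counts_experiment}: a list with elements
#'   \code{counts} and \code{design}.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' sim <- simulate_experiment(cfg)
#' ce <- sim$experiment
#' dim(ce$counts)
#' @export
counts_experiment <- function(counts, design) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stopf("counts must have gene row names and sample column names")
  }
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids in counts")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (any(counts != floor(counts))) stopf("counts must be integers")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "tissue", "condition", "week", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stopf("design is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (!all(colnames(counts) %in% design$sample_id)) {
    stopf("every sample id in counts must appear in the design table")
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "counts_experiment")
}

#' @export
print.counts_experiment <- function(x, ...) {
  d <- x$design
  cat("counts_experiment:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  genotypes: ", paste(unique(d$genotype), collapse = ", "), "\n", sep = "")
  cat("  conditions:", paste(unique(d$condition), collapse = ", "), "\n")
  cat("  weeks:     ", paste(range(d$week), collapse = "-"),
      " (", length(unique(d$week)), " time points)\n", sep = "")
  invisible(x)
}

#' @export
dim.counts_experiment <- function(x) dim(x$counts)

#' Read / write a counts experiment as TSV
#'
#' Counts are written genes-as-rows with a \code{gene_id} first column and
#' sample ids as the header; the design is a sibling TSV with one row per
#' sample.
#'
#' @param experiment A \code{counts_experiment}.
#' @param counts_path,design_path File paths for the two tables.
#' @return \code{read_counts_experiment} returns a \code{counts_experiment};
#'   \code{write_counts_experiment} returns the paths, invisibly.
#' @export
write_counts_experiment <- function(experiment, counts_path, design_path) {
  counts_df <- data.frame(gene_id = rownames(experiment$counts),
                          experiment$counts, check.names = FALSE)
  utils::write.table(counts_df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(experiment$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, design = design_path))
}

#' @rdname write_counts_experiment
#' @export
read_counts_experiment <- function(counts_path, design_path) {
  counts_df <- utils::read.delim(counts_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  counts_experiment(counts, design)
}
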