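#' Fisher's method for combining p-values
#'
#' Combines independent p-values (here: one per genotype) via
#' \eqn{X^2 = -2 \sum \ln p}, referred to a chi-square distribution with
#' \eqn{2k} degrees of freedom.
#'
#' @param p Numeric vector of p-values in (0, 1]; exact zeros are clamped to
#'   the smallest positive double with a warning.
#' @return List with \code{statistic} (X-squared) and \code{p} (combined
#'   p-value).
#' @examples
#' fisher_combine(c(0.05, 0.05))$p  # ~0.00999
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stopf("at least one p-value is required")
  if (any(is.na(p))) return(list(statistic = NA_real_, p = NA_real_))
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warnf("p-value of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(p))
  list(statistic = x2,
       p = stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE))
}

## row-wise Fisher combination over a genes x genotypes matrix of p-values
fisher_combine_rows <- function(pmat) {
  pmat <- as.matrix(pmat)
  if (any(pmat == 0, na.rm = TRUE)) {
    warnf("p-value of 0 clamped to the smallest positive double")
    pmat[pmat == 0] <- .Machine$double.xmin
  }
  k <- rowSums(!is.na(pmat))
  x2 <- -2 * rowSums(log(pmat), na.rm = TRUE)
  x2[k == 0] <- NA_real_
  data.frame(statistic = x2,
             p = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved and non-finite entries
#' (NA/NaN) are propagated unchanged and excluded from the family size.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, elementwise at least as large as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  out <- p
  ok <- is.finite(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Overall log-fold change across a time course
#'
#' Collapses the per-week trajectory L to a single ranking statistic. The
#' default \code{signed_mean} is the time average \eqn{(1/T)\sum_t L_t},
#' which carries sign and therefore supports a top (most increased) and a
#' bottom (most decreased) tail. The \code{as_printed} mode evaluates
#' \eqn{sign(mean) \times (mean)}, i.e. the absolute mean.
#'
#' @param L Numeric vector of per-week log2 fold changes, or a genes x weeks
#'   matrix (row-wise result).
#' @param mode \code{"signed_mean"} (default) or \code{"as_printed"}.
#' @return Numeric scalar or per-gene vector.
#' @export
overall_lfc <- function(L, mode = c("signed_mean", "as_printed")) {
  mode <- match.arg(mode)
  if (is.matrix(L)) {
    if (!ncol(L)) stopf("L must be non-empty")
    m <- rowMeans(L)
  } else {
    if (!length(L)) stopf("L must be non-empty")
    m <- mean(L)
  }
  if (mode == "as_printed") sign(m) * m else m
}

#' Select highly variable genes from one ranked list
#'
#' Eligibility requires BH-adjusted combined p below the threshold; eligible
#' genes are ranked by the genotype-specific overall log-fold change in
#' descending order, and the first and last \code{ceiling(fraction * n)}
#' genes are labeled top and bottom. Ties are broken by smaller adjusted p,
#' then lexical gene id. If the two tails would overlap the bottom tail is
#' truncated so no gene is in both.
#'
#' @param gene_id Gene identifiers.
#' @param adjusted_p BH-adjusted combined p-values, aligned with
#'   \code{gene_id}.
#' @param lfc Per-genotype overall log-fold changes, aligned likewise.
#' @param combined_p Optional raw combined p-values carried into the output.
#' @param fraction Tail fraction (default 0.05).
#' @param alpha Eligibility threshold on adjusted p (default 0.05).
#' @param label List label.
#' @return Object of class \code{hvg_list}: list with \code{label},
#'   \code{top}, \code{bottom} (ordered gene ids) and \code{table} (the
#'   ranked eligible genes).
#' @export
select_hvgs <- function(gene_id, adjusted_p, lfc, combined_p = NULL,
                        fraction = 0.05, alpha = 0.05, label = "hvg") {
  stopifnot(length(gene_id) == length(adjusted_p),
            length(gene_id) == length(lfc))
  eligible <- !is.na(adjusted_p) & adjusted_p < alpha & !is.na(lfc)
  n <- sum(eligible)
  if (n == 0) {
    message("no eligible genes (adjusted p < ", alpha, ") for list ", label)
    return(structure(list(label = label, top = character(),
                          bottom = character(),
                          table = data.frame(gene_id = character(),
                                             lfc = numeric(),
                                             combined_p = numeric(),
                                             adjusted_p = numeric(),
                                             tail = character(),
                                             stringsAsFactors = FALSE)),
                     class = "hvg_list"))
  }
  idx <- which(eligible)
  ord <- idx[order(-lfc[idx], adjusted_p[idx], gene_id[idx])]
  k <- ceiling(fraction * n)
  top <- gene_id[ord[seq_len(k)]]
  bottom_idx <- ord[seq(n, by = -1L, length.out = min(k, n - k))]
  bottom <- gene_id[bottom_idx]  # most-decreased first
  tab <- data.frame(gene_id = gene_id[ord],
                    lfc = lfc[ord],
                    combined_p = if (is.null(combined_p)) NA_real_ else combined_p[ord],
                    adjusted_p = adjusted_p[ord],
                    tail = "none",
                    stringsAsFactors = FALSE)
  tab$tail[tab$gene_id %in% top] <- "top"
  tab$tail[tab$gene_id %in% bottom] <- "bottom"
  structure(list(label = label, top = top, bottom = bottom, table = tab),
            class = "hvg_list")
}

#' @export
print.hvg_list <- function(x, ...) {
  cat("hvg_list '", x$label, "': ", nrow(x$table), " eligible, ",
      length(x$top), " top + ", length(x$bottom), " bottom\n", sep = "")
  invisible(x)
}

## internal: one condition/period -> two genotype-labeled hvg_lists
hvg_lists_for_contrast <- function(norm, condition, genotypes, df, weeks,
                                   period, fraction, alpha, lfc_mode) {
  des <- lapply(genotypes, function(g) {
    compute_de_stats(fit_gene_models(norm, g, condition, df = df, weeks = weeks))
  })
  names(des) <- genotypes
  pmat <- do.call(cbind, lapply(des, function(d) d$p))
  comb <- fisher_combine_rows(pmat)
  adj <- bh_adjust(comb$p)
  gene_id <- des[[1]]$gene_id
  out <- list()
  for (g in genotypes) {
    lfc <- overall_lfc(trajectory_matrix(des[[g]]), mode = lfc_mode)
    label <- paste(g, condition, period, sep = "_")
    out[[label]] <- select_hvgs(gene_id, adj, lfc, combined_p = comb$p,
                                fraction = fraction, alpha = alpha,
                                label = label)
  }
  attr(out, "de") <- des
  attr(out, "combined") <- data.frame(gene_id = gene_id,
                                      condition = condition, period = period,
                                      statistic = comb$statistic,
                                      combined_p = comb$p, adjusted_p = adj,
                                      stringsAsFactors = FALSE)
  out
}

#' Build the eight highly-variable-gene lists and merge them
#'
#' Runs the drought-vs-control time-course contrasts for both genotypes on
#' the full course for each drought condition (four lists), then again on
#' the pre-flowering drought-only weeks and recovery-only weeks (four more),
#' and merges the eight top/bottom selections into one set per tissue, each
#' gene tagged with every source list.
#'
#' @param norm A \code{normalized_matrix} with design.
#' @param conditions Drought conditions (default pre- and post-flowering).
#' @param genotypes Genotypes (default: those in the design).
#' @param windows Named list of pre-flowering sub-period week windows
#'   (defaults: drought = weeks 3-8, recovery = weeks 9-17).
#' @param df Spline df.
#' @param fraction Tail fraction for each list (default 0.05).
#' @param alpha Adjusted-p eligibility threshold.
#' @param lfc_mode Ranking statistic mode, see [overall_lfc()].
#' @return Object of class \code{hvg_set}: \code{lists} (named
#'   \code{hvg_list}s), \code{merged} (data frame gene_id, sources,
#'   n_sources), \code{de} (the underlying \code{tcde_result}s) and
#'   \code{combined} (per-contrast combined/adjusted p tables).
#' @export
build_and_merge_lists <- function(norm,
                                  conditions = c("preflowering", "postflowering"),
                                  genotypes = NULL,
                                  windows = list(drought = 3:8, recovery = 9:17),
                                  df = 4, fraction = 0.05, alpha = 0.05,
                                  lfc_mode = "signed_mean") {
  design <- norm$design
  if (is.null(design)) stopf("normalized matrix carries no design metadata")
  if (is.null(genotypes)) genotypes <- sort(unique(design$genotype))
  lists <- list()
  de_all <- list()
  combined_all <- list()
  for (cond in conditions) {
    res <- hvg_lists_for_contrast(norm, cond, genotypes, df, weeks = NULL,
                                  period = "full", fraction = fraction,
                                  alpha = alpha, lfc_mode = lfc_mode)
    lists <- c(lists, res)
    de_all[[paste(cond, "full", sep = "_")]] <- attr(res, "de")
    combined_all[[paste(cond, "full", sep = "_")]] <- attr(res, "combined")
  }
  for (w in names(windows)) {
    wk <- windows[[w]]
    present <- any(design$condition == "preflowering" & design$week %in% wk)
    if (!present) {
      message("no pre-flowering samples in the '", w, "' window; lists empty")
      for (g in genotypes) {
        label <- paste(g, "preflowering", w, sep = "_")
        lists[[label]] <- structure(list(label = label, top = character(),
                                         bottom = character(),
                                         table = data.frame()),
                                    class = "hvg_list")
      }
      next
    }
    res <- hvg_lists_for_contrast(norm, "preflowering", genotypes, df,
                                  weeks = wk, period = w,
                                  fraction = fraction, alpha = alpha,
                                  lfc_mode = lfc_mode)
    lists <- c(lists, res)
    de_all[[paste("preflowering", w, sep = "_")]] <- attr(res, "de")
    combined_all[[paste("preflowering", w, sep = "_")]] <- attr(res, "combined")
  }

  membership <- lapply(lists, function(l) union(l$top, l$bottom))
  all_genes <- sort(unique(unlist(membership)))
  sources <- vapply(all_genes, function(g) {
    paste(names(lists)[vapply(membership, function(m) g %in% m, logical(1))],
          collapse = ";")
  }, character(1))
  merged <- data.frame(gene_id = all_genes,
                       sources = unname(sources),
                       n_sources = lengths(regmatches(sources,
                                                      gregexpr(";", sources))) + 1L,
                       stringsAsFactors = FALSE)
  if (!nrow(merged)) merged$n_sources <- integer()
  tissue <- unique(design$tissue)
  structure(list(lists = lists, merged = merged, tissue = tissue,
                 de = de_all, combined = combined_all,
                 params = list(fraction = fraction, alpha = alpha,
                               df = df, windows = windows,
                               lfc_mode = lfc_mode)),
            class = "hvg_set")
}

#' @export
print.hvg_set <- function(x, ...) {
  cat("hvg_set (", paste(x$tissue, collapse = ","), "): ",
      length(x$lists), " lists, merged union of ", nrow(x$merged),
      " genes\n", sep = "")
  for (l in x$lists) {
    cat("  ", l$label, ": ", length(l$top), " top + ", length(l$bottom),
        " bottom\n", sep = "")
  }
  invisible(x)
}

#' Write the HVG lists and merged set as TSV
#'
#' @param hvgs An \code{hvg_set}.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_hvg_set <- function(hvgs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (l in hvgs$lists) {
    p <- file.path(dir, paste0("hvg_", l$label, ".tsv"))
    tab <- l$table
    if (nrow(tab)) tab <- cbind(list_label = l$label, tab)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "hvg_merged.tsv")
  utils::write.table(hvgs$merged, p, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(hvgs$merged$gene_id, file.path(dir, "hvg_merged_genes.txt"))
  invisible(c(paths, p))
}
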