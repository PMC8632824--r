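#' Natural cubic spline basis over assay weeks
#'
#' Builds the smooth-in-time basis used by the per-gene models. With
#' \code{df = 1} the basis degenerates to a single centered linear term.
#'
#' @param times Numeric vector of week values (need not be unique or sorted).
#' @param df Degrees of freedom; must be smaller than the number of distinct
#'   times.
#' @return Object of class \code{spline_basis}: list with \code{times}
#'   (sorted unique weeks), \code{df}, \code{basis} (matrix, one row per
#'   unique time), and \code{boundary} knots. Use [eval_basis()] to evaluate
#'   at arbitrary times.
#' @export
build_spline_basis <- function(times, df) {
  ut <- sort(unique(times))
  if (df < 1 || df != floor(df)) stopf("df must be a positive integer")
  if (df >= length(ut)) {
    stopf("df (%d) must be smaller than the number of distinct times (%d)",
          df, length(ut))
  }
  bknots <- range(ut)
  if (df == 1) {
    B <- matrix(ut - mean(ut), ncol = 1,
                dimnames = list(NULL, "linear"))
    ns_obj <- NULL
  } else {
    B <- splines::ns(ut, df = df, Boundary.knots = bknots)
    ns_obj <- B
    B <- matrix(as.numeric(B), nrow = length(ut),
                dimnames = list(NULL, paste0("s", seq_len(df))))
  }
  structure(list(times = ut, df = df, basis = B, boundary = bknots,
                 ns = ns_obj, center = mean(ut)),
            class = "spline_basis")
}

#' Evaluate a spline basis at given times
#' @param basis A [build_spline_basis()] object.
#' @param times Times at which to evaluate (must lie within data support for
#'   sensible extrapolation-free use; natural splines are linear beyond the
#'   boundary knots).
#' @return Matrix with one row per element of \code{times}.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "spline_basis"))
  if (basis$df == 1) {
    matrix(times - basis$center, ncol = 1, dimnames = list(NULL, "linear"))
  } else {
    m <- stats::predict(basis$ns, times)
    matrix(as.numeric(m), nrow = length(times),
           dimnames = list(NULL, colnames(basis$basis)))
  }
}

#' Fit per-gene smooth time-course models for a drought-vs-control contrast
#'
#' For one genotype and one drought condition, fits to each gene's log2
#' normalized expression the least-squares model
#' \code{intercept + spline(week) + condition + condition:spline(week)}
#' (a different smooth functional form per condition), and the null model
#' without any condition term. The per-week log2 fold-change trajectory L is
#' the fitted drought curve minus the fitted control curve evaluated at each
#' shared assayed week.
#'
#' @param norm A \code{normalized_matrix} carrying a design.
#' @param genotype Genotype to fit.
#' @param condition Drought condition contrasted against \code{control}.
#' @param control Name of the control condition.
#' @param df Spline degrees of freedom (default 4); reduced automatically
#'   when a week window leaves fewer distinct weeks than \code{df + 1}.
#' @param weeks Optional week window (e.g. drought-only weeks) to restrict
#'   the fit to a sub-period.
#' @param basis Optional pre-built [build_spline_basis()]; by default built
#'   on the shared assayed weeks.
#' @return Object of class \code{gene_fits}: per-gene RSS for full and null
#'   models, residual df, residual variances \code{s2}, the L matrix
#'   (genes x shared weeks), and fit metadata. A rank-deficient design (for
#'   example a condition observed in a single week) yields NA fits with the
#'   reason recorded in \code{$failure}.
#' @export
fit_gene_models <- function(norm, genotype, condition, control = "control",
                            df = 4, weeks = NULL, basis = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  design <- norm$design
  if (is.null(design)) stopf("normalized matrix carries no design metadata")
  sel <- design$genotype == genotype & design$condition %in% c(control, condition)
  if (!is.null(weeks)) sel <- sel & design$week %in% weeks
  d <- design[sel, , drop = FALSE]
  if (!all(c(control, condition) %in% d$condition)) {
    stopf("both conditions must be present for genotype %s", genotype)
  }
  shared <- sort(intersect(d$week[d$condition == control],
                           d$week[d$condition == condition]))
  keep <- sel
  keep[sel] <- d$week %in% shared
  d <- design[keep, , drop = FALSE]
  Y <- norm$log2[, keep, drop = FALSE]

  n_distinct <- length(shared)
  use_df <- min(df, n_distinct - 1L)
  if (use_df < 1) {
    return(structure(list(genes = rownames(Y), failure = "fewer than 2 shared weeks"),
                     class = "gene_fits"))
  }
  if (is.null(basis)) basis <- build_spline_basis(shared, use_df)

  B <- eval_basis(basis, d$week)
  trt <- as.numeric(d$condition == condition)
  X1 <- cbind(`(Intercept)` = 1, B, condition = trt, trt * B)
  colnames(X1)[(ncol(B) + 3):ncol(X1)] <- paste0("condition:", colnames(B))
  X0 <- cbind(`(Intercept)` = 1, B)

  qr1 <- qr(X1)
  qr0 <- qr(X0)
  n <- nrow(X1)
  p1 <- ncol(X1)
  if (qr1$rank < p1 || n - p1 < 1) {
    return(structure(list(genes = rownames(Y),
                          failure = sprintf(
                            "singular or saturated design (rank %d of %d, n = %d)",
                            qr1$rank, p1, n)),
                     class = "gene_fits"))
  }

  Yt <- t(Y)
  R1 <- qr.resid(qr1, Yt)
  R0 <- qr.resid(qr0, Yt)
  rss1 <- colSums(R1^2)
  rss0 <- colSums(R0^2)
  beta <- qr.coef(qr1, Yt)  # p1 x genes

  ## L(t) = condition main effect + B(t) %*% interaction coefficients
  Bg <- eval_basis(basis, basis$times)
  cond_idx <- ncol(B) + 2L
  int_idx <- (ncol(B) + 3L):p1
  L <- t(matrix(beta[cond_idx, ], nrow = 1)[rep(1, length(basis$times)), , drop = FALSE] +
           Bg %*% beta[int_idx, , drop = FALSE])
  dimnames(L) <- list(rownames(Y), paste0("w", basis$times))

  d_resid <- n - p1
  structure(list(genes = rownames(Y),
                 rss0 = rss0, rss1 = rss1,
                 df_resid = d_resid,
                 q = p1 - ncol(X0),
                 s2 = rss1 / d_resid,
                 L = L,
                 weeks = basis$times,
                 genotype = genotype, condition = condition,
                 n = n, failure = NULL),
            class = "gene_fits")
}

#' @export
print.gene_fits <- function(x, ...) {
  if (!is.null(x$failure)) {
    cat("gene_fits: FAILED -", x$failure, "\n")
    return(invisible(x))
  }
  cat("gene_fits:", length(x$genes), "genes,", x$genotype, x$condition,
      "vs control over weeks", paste(range(x$weeks), collapse = "-"), "\n")
  cat("  residual df", x$df_resid, "| condition parameters q =", x$q, "\n")
  invisible(x)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-gene residual variances toward a common prior value:
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d s^2_g) / (d_0 + d)}. The prior degrees
#' of freedom \eqn{d_0} and prior variance \eqn{s_0^2} are estimated by
#' moment matching on \eqn{\log s^2}: the excess of \eqn{var(\log s^2)} over
#' \eqn{trigamma(d/2)} is matched to \eqn{trigamma(d_0/2)} (trigamma inverted
#' numerically). When the empirical variance does not exceed
#' \eqn{trigamma(d/2)} the prior df is capped at \eqn{10^6}, so every
#' moderated variance collapses to \eqn{s_0^2}.
#'
#' @param s2 Per-gene residual variances.
#' @param d Residual degrees of freedom of each fit (scalar).
#' @param d0 Optional fixed prior df (bypasses estimation); \code{d0 = 0}
#'   disables moderation, \code{Inf} is treated as the cap.
#' @return Object of class \code{moderation_params}: list with \code{d0},
#'   \code{s0_sq} and the per-gene moderated variances \code{s_tilde_sq}.
#' @export
moderate_variances <- function(s2, d, d0 = NULL) {
  if (any(s2 < 0, na.rm = TRUE)) stopf("residual variances must be nonnegative")
  if (d < 1) stopf("residual df must be at least 1")
  cap <- 1e6
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (is.null(d0)) {
    if (sum(ok) < 10) {
      warnf("fewer than 10 genes with positive variance; moderation skipped")
      d0 <- 0
    } else {
      excess <- stats::var(z) - trigamma(d / 2)
      d0 <- if (excess <= 0) cap else 2 * trigamma_inverse(excess)
      if (d0 > cap) d0 <- cap
    }
  } else if (is.infinite(d0)) {
    d0 <- cap
  }
  s0_sq <- if (sum(ok)) {
    exp(mean(z) - digamma(d / 2) + log(d / 2) +
          (if (d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0))
  } else {
    NA_real_
  }
  s_tilde <- if (d0 > 0) (d0 * s0_sq + d * s2) / (d0 + d) else s2
  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde, d = d),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat("moderation_params: prior df d0 =", format(x$d0),
      "| prior variance s0^2 =", format(x$s0_sq),
      "| residual df d =", x$d, "\n")
  invisible(x)
}

#' Moderated-F statistics for a fitted contrast
#'
#' Computes per-gene moderated F statistics,
#' \eqn{F = ((RSS_0 - RSS_1)/q) / \tilde s^2}, with p-values from the F
#' distribution on \eqn{(q, d_0 + d)} degrees of freedom (the chi-square
#' limit \eqn{\chi^2_q / q} when the prior df hits the cap).
#'
#' @param fits A [fit_gene_models()] result.
#' @param moderation A [moderate_variances()] result on the same genes; if
#'   omitted it is estimated from the fits.
#' @return Object of class \code{tcde_result}: data frame with columns
#'   \code{gene_id}, \code{genotype}, \code{condition}, \code{F}, \code{p},
#'   and the per-week trajectory columns \code{L_w<week>}.
#' @export
compute_de_stats <- function(fits, moderation = NULL) {
  stopifnot(inherits(fits, "gene_fits"))
  if (!is.null(fits$failure)) {
    out <- data.frame(gene_id = fits$genes, genotype = NA_character_,
                      condition = NA_character_, F = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "failure") <- fits$failure
    class(out) <- c("tcde_result", "data.frame")
    return(out)
  }
  if (is.null(moderation)) moderation <- moderate_variances(fits$s2, fits$df_resid)
  stopifnot(inherits(moderation, "moderation_params"))
  if (length(moderation$s_tilde_sq) != length(fits$genes)) {
    stopf("fits and moderation cover different gene sets")
  }
  q <- fits$q
  d0 <- moderation$d0
  d <- fits$df_resid
  Fstat <- ((fits$rss0 - fits$rss1) / q) / moderation$s_tilde_sq
  ## a gene fit exactly by the null model (both RSS at rounding noise) is a
  ## clean null: F = 0, p = 1, rather than a 0/0 artifact
  exact_null <- fits$rss0 < 1e-10 & fits$rss1 < 1e-10
  Fstat[exact_null] <- 0
  p <- if (d0 >= 1e6) {
    stats::pchisq(q * Fstat, df = q, lower.tail = FALSE)
  } else {
    stats::pf(Fstat, q, d0 + d, lower.tail = FALSE)
  }
  n_na <- sum(is.na(p))
  if (n_na > 0) message(n_na, " gene(s) with NA statistics excluded downstream")
  out <- data.frame(gene_id = fits$genes,
                    genotype = fits$genotype,
                    condition = fits$condition,
                    F = Fstat, p = p,
                    stringsAsFactors = FALSE)
  Lcols <- as.data.frame(fits$L)
  names(Lcols) <- paste0("L_", colnames(fits$L))
  out <- cbind(out, Lcols)
  attr(out, "weeks") <- fits$weeks
  attr(out, "q") <- q
  attr(out, "d0") <- d0
  attr(out, "d") <- d
  class(out) <- c("tcde_result", "data.frame")
  out
}

#' @export
print.tcde_result <- function(x, ...) {
  cat("tcde_result:", nrow(x), "genes |", x$genotype[1], x$condition[1],
      "vs control | weeks", paste(range(attr(x, "weeks")), collapse = "-"), "\n")
  cat("  moderated F on (", attr(x, "q"), ", ",
      format(attr(x, "d0") + attr(x, "d")), ") df; ",
      sum(x$p < 0.05, na.rm = TRUE), " genes at raw p < 0.05\n", sep = "")
  invisible(x)
}

#' @export
summary.tcde_result <- function(object, ...) {
  cat("Time-course differential expression,", object$genotype[1],
      object$condition[1], "vs control\n")
  cat("  genes:", nrow(object), "\n")
  cat("  raw p < 0.05:", sum(object$p < 0.05, na.rm = TRUE), "\n")
  L <- trajectory_matrix(object)
  cat("  mean |L| quartiles:",
      paste(signif(stats::quantile(rowMeans(abs(L))), 3), collapse = " "), "\n")
  invisible(object)
}

#' Extract the L trajectory matrix from a tcde_result
#' @param de A \code{tcde_result}.
#' @return Numeric matrix genes x weeks of per-week log2 fold changes.
#' @export
trajectory_matrix <- function(de) {
  cols <- grep("^L_w", names(de), value = TRUE)
  m <- as.matrix(de[, cols, drop = FALSE])
  rownames(m) <- de$gene_id
  m
}

#' Genotype-contrast time-course fit
#'
#' The same spline machinery with genotype replacing condition: within one
#' irrigation condition, tests whether the two genotypes follow different
#' expression curves over time.
#'
#' @param norm A \code{normalized_matrix} with design.
#' @param condition Condition within which genotypes are compared.
#' @param genotypes Length-2 character vector; the second is contrasted
#'   against the first.
#' @inheritParams fit_gene_models
#' @return A \code{tcde_result} (L is the second-genotype curve minus the
#'   first).
#' @export
fit_genotype_contrast <- function(norm, condition, genotypes = NULL,
                                  df = 4, weeks = NULL) {
  design <- norm$design
  if (is.null(design)) stopf("normalized matrix carries no design metadata")
  if (is.null(genotypes)) genotypes <- unique(design$genotype)
  if (length(genotypes) != 2) stopf("exactly two genotypes are required")
  ## reuse the condition machinery by relabeling
  norm2 <- norm
  sel <- design$condition == condition & design$genotype %in% genotypes
  norm2$log2 <- norm$log2[, sel, drop = FALSE]
  norm2$values <- norm$values[, sel, drop = FALSE]
  d2 <- design[sel, , drop = FALSE]
  d2$condition <- ifelse(d2$genotype == genotypes[2], "g2", "g1")
  d2$genotype <- "pooled"
  norm2$design <- d2
  fits <- fit_gene_models(norm2, genotype = "pooled", condition = "g2",
                          control = "g1", df = df, weeks = weeks)
  de <- compute_de_stats(fits)
  de$genotype <- paste(genotypes[2], "vs", genotypes[1])
  de$condition <- condition
  de
}
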