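#' Pooled-variance two-sample t-test
#'
#' Classical Student's t-test (equal variances pooled, df = n1 + n2 - 2)
#' comparing a droughted treatment's replicates to its watered control.
#' Degenerate zero-pooled-variance inputs follow a fixed contract: equal
#' means give t = 0, p = 1; unequal means give p = 0 with flag
#' \code{"degenerate"}.
#'
#' @param treatment,control Numeric replicate vectors (>= 2 values each).
#' @return List with \code{t}, \code{p}, \code{df}, \code{flag}.
#' @export
contrast_ttest <- function(treatment, control) {
  if (length(treatment) < 2 || length(control) < 2) {
    stopf("at least 2 replicates per group are required")
  }
  df <- length(treatment) + length(control) - 2L
  pooled_ss <- sum((treatment - mean(treatment))^2) +
    sum((control - mean(control))^2)
  if (pooled_ss == 0) {
    if (mean(treatment) == mean(control)) {
      return(list(t = 0, p = 1, df = df, flag = ""))
    }
    return(list(t = sign(mean(treatment) - mean(control)) * Inf,
                p = 0, df = df, flag = "degenerate"))
  }
  ht <- stats::t.test(treatment, control, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), flag = "")
}

#' Attach BH adjustment and significance decisions to contrasts
#'
#' Adjusts raw p-values within each family (default: all analytes of a
#' tissue x genotype x week report) by Benjamini-Hochberg and flags
#' significance where the raw p is below \code{alpha} and the BH-adjusted p
#' survives the configured FDR (default 0.25, the conservative assumption).
#'
#' @param contrasts Data frame with at least a \code{p} column and the
#'   family columns.
#' @param fdr FDR threshold for the BH decision (default 0.25).
#' @param alpha Raw significance threshold (default 0.05).
#' @param family Column names defining each BH family.
#' @return The input with \code{p_adj} and \code{significant} columns added.
#' @export
adjust_and_flag <- function(contrasts, fdr = 0.25, alpha = 0.05,
                            family = c("tissue", "genotype", "week")) {
  if (!nrow(contrasts)) stopf("empty contrast table")
  fam_cols <- intersect(family, names(contrasts))
  key <- if (length(fam_cols)) {
    do.call(paste, c(contrasts[fam_cols], sep = "\r"))
  } else {
    rep("all", nrow(contrasts))
  }
  p_adj <- rep(NA_real_, nrow(contrasts))
  for (k in unique(key)) {
    idx <- which(key == k)
    p_adj[idx] <- bh_adjust(contrasts$p[idx])
  }
  contrasts$p_adj <- p_adj
  contrasts$significant <- !is.na(contrasts$p) & contrasts$p < alpha &
    !is.na(p_adj) & p_adj <= fdr
  contrasts
}

#' Flag extreme replicate outliers
#'
#' Leave-one-out rule: a replicate is a candidate for removal when its
#' absolute deviation from the mean of the other replicates exceeds
#' \code{k} times their standard deviation. At most one replicate (the most
#' extreme candidate) is removed, and never below 2 survivors.
#'
#' @param x Replicate values.
#' @param k Deviation multiplier (default 4).
#' @return Logical keep mask, same length as \code{x}.
#' @export
flag_outliers <- function(x, k = 4) {
  n <- length(x)
  keep <- rep(TRUE, n)
  if (n < 3) return(keep)
  dev <- vapply(seq_len(n), function(i) {
    others <- x[-i]
    s <- stats::sd(others)
    if (is.na(s) || s == 0) {
      if (x[i] == mean(others)) 0 else Inf
    } else {
      abs(x[i] - mean(others)) / s
    }
  }, numeric(1))
  cand <- which(dev > k)
  if (length(cand)) {
    worst <- cand[which.max(dev[cand])]
    keep[worst] <- FALSE
  }
  keep
}

#' Treatment-vs-control contrasts over an analyte table
#'
#' For every analyte x tissue x genotype x week cell of each non-control
#' condition with a matching control cell, runs the pooled t-test, computes
#' the percent change \code{100 * (treatment - control) / control}, and
#' attaches BH-adjusted decisions per tissue x genotype x week family.
#' Cells lacking a control are skipped with a message.
#'
#' @param table Analyte table (see [read_analyte_table()]).
#' @param weeks Weeks to analyze (default 7 and 14); \code{NULL} for all.
#' @param control Control condition label.
#' @param fdr,alpha Thresholds passed to [adjust_and_flag()].
#' @param remove_outliers Apply [flag_outliers()] to each replicate cell
#'   before testing (default FALSE).
#' @param k Outlier multiplier.
#' @return Data frame of contrast results (one row per analyte x genotype x
#'   week x condition) with means, SDs, percent change, t, p, p_adj,
#'   significant, and the number of replicates used.
#' @export
chem_contrasts <- function(table, weeks = c(7, 14), control = "control",
                           fdr = 0.25, alpha = 0.05,
                           remove_outliers = FALSE, k = 4) {
  if (!is.null(weeks)) {
    found <- intersect(weeks, unique(table$week))
    if (length(found) < length(weeks)) {
      warnf("week(s) %s absent from the analyte table; report covers %s",
            paste(setdiff(weeks, found), collapse = ", "),
            paste(found, collapse = ", "))
    }
    table <- table[table$week %in% found, , drop = FALSE]
  }
  cells <- unique(table[, c("analyte", "tissue", "genotype", "week")])
  trt_conditions <- setdiff(unique(table$condition), control)
  rows <- list()
  removed <- 0L
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    sub <- table[table$analyte == ci$analyte & table$tissue == ci$tissue &
                   table$genotype == ci$genotype & table$week == ci$week, ]
    ctrl <- sub$quantity[sub$condition == control]
    if (length(ctrl) < 2) {
      message("no control cell for ", ci$analyte, " ", ci$genotype,
              " week ", ci$week, "; contrasts skipped")
      next
    }
    if (remove_outliers) {
      m <- flag_outliers(ctrl, k)
      removed <- removed + sum(!m)
      ctrl <- ctrl[m]
    }
    for (cond in trt_conditions) {
      trt <- sub$quantity[sub$condition == cond]
      if (length(trt) < 2) next
      if (remove_outliers) {
        m <- flag_outliers(trt, k)
        removed <- removed + sum(!m)
        trt <- trt[m]
      }
      tt <- contrast_ttest(trt, ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = ci$analyte, tissue = ci$tissue, genotype = ci$genotype,
        week = ci$week, condition = cond,
        control_mean = mean(ctrl), control_sd = stats::sd(ctrl),
        treatment_mean = mean(trt), treatment_sd = stats::sd(trt),
        percent_change = 100 * (mean(trt) - mean(ctrl)) / mean(ctrl),
        n_treatment = length(trt), n_control = length(ctrl),
        t = tt$t, p = tt$p, flag = tt$flag,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  if (removed > 0) message(removed, " replicate(s) removed as extreme outliers")
  adjust_and_flag(out, fdr = fdr, alpha = alpha)
}
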