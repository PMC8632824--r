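test_that("spline basis has the requested rank and degenerates cleanly", {
  b1 <- build_spline_basis(1:10, df = 1)
  expect_equal(ncol(b1$basis), 1)
  expect_true(all(diff(b1$basis[, 1]) > 0))
  b4 <- build_spline_basis(1:17, df = 4)
  expect_equal(dim(b4$basis), c(17, 4))
  expect_equal(qr(b4$basis)$rank, 4)
  expect_identical(build_spline_basis(1:17, df = 4)$basis, b4$basis)
  expect_error(build_spline_basis(1:4, df = 4), "distinct times")
  ## evaluation at the construction grid reproduces the stored basis
  expect_equal(eval_basis(b4, b4$times), b4$basis, ignore_attr = TRUE)
})

test_that("identical conditions give a zero contrast and equal RSS", {
  design <- two_condition_design(weeks = 1:8, reps = 1:2)
  set.seed(1)
  y <- matrix(rnorm(5 * nrow(design), mean = 6), 5,
              dimnames = list(paste0("g", 1:5), design$sample_id))
  ## same values in both conditions at every (week, replicate)
  ctl <- design$condition == "control"
  y[, !ctl] <- y[, ctl][, order(design$week[ctl], design$replicate[ctl])][
    , order(order(design$week[!ctl], design$replicate[!ctl]))]
  norm <- norm_from_log2(y, design)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 3)
  expect_equal(fits$rss0, fits$rss1, tolerance = 1e-8)
  expect_true(all(abs(fits$L) < 1e-8))
})

test_that("a constant condition offset is recovered exactly in L", {
  design <- two_condition_design(weeks = 1:10, reps = 1:2)
  base <- sin(design$week / 3) + 5
  delta <- 1.25
  y <- rbind(g1 = base + delta * (design$condition == "preflowering"),
             g2 = base)
  colnames(y) <- design$sample_id
  norm <- norm_from_log2(y, design)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 4)
  expect_equal(unname(fits$L["g1", ]), rep(delta, 10), tolerance = 1e-8)
  expect_equal(unname(fits$L["g2", ]), rep(0, 10), tolerance = 1e-8)
})

test_that("a planted trajectory in the spline space is recovered exactly", {
  design <- two_condition_design(weeks = 1:17, reps = 1:3)
  basis <- build_spline_basis(1:17, df = 4)
  coefs <- c(0.8, -1.2, 0.5, 0.3)
  traj <- as.numeric(basis$basis %*% coefs) + 0.4
  y <- matrix(6 + cos(design$week / 4), 1, nrow(design),
              dimnames = list("g1", design$sample_id))
  drought <- design$condition == "preflowering"
  y[1, drought] <- y[1, drought] + traj[design$week[drought]]
  norm <- norm_from_log2(y, design)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 4, basis = basis)
  expect_equal(unname(fits$L["g1", ]), traj, tolerance = 1e-8)
})

test_that("degenerate designs yield flagged NA fits, not crashes", {
  ## drought condition observed at a single week: saturated/singular
  design <- two_condition_design(weeks = 1:8, reps = 1:2)
  keep <- design$condition == "control" | design$week == 4
  design2 <- design[keep, ]
  y <- matrix(rnorm(2 * nrow(design2), 6), 2,
              dimnames = list(c("g1", "g2"), design2$sample_id))
  norm <- norm_from_log2(y, design2)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 3)
  expect_false(is.null(fits$failure))
  de <- compute_de_stats(fits)
  expect_true(all(is.na(de$p)))
})

test_that("moderation limits and simulation recovery behave as specified", {
  set.seed(7)
  s2 <- rchisq(500, df = 8) / 8
  m0 <- moderate_variances(s2, d = 8, d0 = 0)
  expect_equal(m0$s_tilde_sq, s2)
  mInf <- moderate_variances(s2, d = 8, d0 = Inf)
  expect_equal(unname(mInf$s_tilde_sq / mInf$s0_sq), rep(1, 500),
               tolerance = 1e-3)
  ## homogeneous truth: s2 ~ s0^2 chi^2_d / d at d = 4 -> huge prior df,
  ## prior variance within 5% of the true value
  set.seed(12)
  s0_true <- 2.5
  s2h <- s0_true * rchisq(10000, df = 4) / 4
  mh <- moderate_variances(s2h, d = 4)
  expect_gte(mh$d0, 100)
  expect_equal(mh$s0_sq, s0_true, tolerance = 0.05)
  expect_warning(moderate_variances(s2[1:5], d = 4), "fewer than 10")
})

test_that("moderated variances interpolate between gene and prior", {
  set.seed(3)
  s2 <- exp(rnorm(200))
  m <- moderate_variances(s2, d = 6)
  between <- (m$s_tilde_sq >= pmin(s2, m$s0_sq) - 1e-12) &
    (m$s_tilde_sq <= pmax(s2, m$s0_sq) + 1e-12)
  expect_true(all(between))
})

test_that("moderation agrees with an independent empirical-Bayes estimator", {
  skip_if_not_installed("limma")
  set.seed(19)
  d <- 6; d0_true <- 10; s0_true <- 1.5
  sigma2 <- d0_true * s0_true / rchisq(3000, df = d0_true)
  s2 <- sigma2 * rchisq(3000, df = d) / d
  ours <- moderate_variances(s2, d = d)
  ref <- limma::squeezeVar(s2, df = d)
  expect_equal(ours$s_tilde_sq, ref$var.post, tolerance = 0.1)
  expect_equal(ours$s0_sq, ref$var.prior, tolerance = 0.2)
})

test_that("unmoderated F matches the classical partial F from lm/anova", {
  design <- two_condition_design(weeks = 1:9, reps = 1:2)
  set.seed(5)
  y <- matrix(rnorm(3 * nrow(design), 6), 3,
              dimnames = list(paste0("g", 1:3), design$sample_id))
  y[1, design$condition == "preflowering"] <-
    y[1, design$condition == "preflowering"] + 0.8
  norm <- norm_from_log2(y, design)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 3)
  de <- compute_de_stats(fits, moderate_variances(fits$s2, fits$df_resid, d0 = 0))
  basis <- build_spline_basis(sort(unique(design$week)), 3)
  B <- eval_basis(basis, design$week)
  trt <- as.numeric(design$condition == "preflowering")
  for (g in rownames(y)) {
    full <- lm(y[g, ] ~ B + trt + trt:B)
    null <- lm(y[g, ] ~ B)
    a <- anova(null, full)
    expect_equal(de$F[de$gene_id == g], a$F[2], tolerance = 1e-8)
    expect_equal(de$p[de$gene_id == g], a$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("F is zero for an exact null gene and grows with the offset", {
  design <- two_condition_design(weeks = 1:10, reps = 1:2)
  base <- 5 + design$week / 10
  offsets <- c(0, 0.2, 0.5, 1, 2)
  set.seed(13)
  noise <- rnorm(nrow(design), sd = 0.1)
  y <- do.call(rbind, lapply(offsets, function(d) {
    base + noise + d * (design$condition == "preflowering")
  }))
  rownames(y) <- paste0("g", seq_along(offsets))
  colnames(y) <- design$sample_id
  norm <- norm_from_log2(y, design)
  fits <- fit_gene_models(norm, "RTx430", "preflowering", df = 4)
  expect_true(all(fits$rss0 - fits$rss1 >= -1e-10))
  de <- compute_de_stats(fits, moderate_variances(fits$s2, fits$df_resid, d0 = 0))
  expect_true(all(de$F >= 0))
  expect_true(all(diff(de$F) > 0))  # strictly increasing in the offset
  ## exact null gene with no noise: F = 0, p = 1
  y0 <- rbind(g0 = base, gref = base + rnorm(nrow(design), sd = 0.05))
  colnames(y0) <- design$sample_id
  f0 <- fit_gene_models(norm_from_log2(y0, design), "RTx430", "preflowering")
  de0 <- compute_de_stats(f0, moderate_variances(f0$s2, f0$df_resid, d0 = 0))
  expect_equal(de0$F[1], 0, tolerance = 1e-8)
  expect_equal(de0$p[1], 1, tolerance = 1e-6)
})

test_that("the genotype contrast recovers a planted between-line offset", {
  d1 <- two_condition_design(weeks = 1:8, reps = 1:2,
                             conditions = c("control", "control2"))
  d1 <- d1[d1$condition == "control", ]
  d2 <- d1
  d2$genotype <- "BTx642"
  d2$sample_id <- sub("RTx430", "BTx642", d2$sample_id)
  design <- rbind(d1, d2)
  y <- matrix(5 + design$week / 5 + 0.9 * (design$genotype == "BTx642"),
              1, nrow(design), dimnames = list("g1", design$sample_id))
  norm <- norm_from_log2(y, design)
  de <- suppressWarnings(
    fit_genotype_contrast(norm, "control", c("RTx430", "BTx642"), df = 3))
  L <- trajectory_matrix(de)
  expect_equal(unname(L["g1", ]), rep(0.9, 8), tolerance = 1e-8)
})
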