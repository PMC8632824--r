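test_that("Fisher combination matches its closed forms", {
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p, 1)
  ## k = 1: chi-square with 2 df survival of -2 log p returns p itself
  for (p in c(0.5, 0.01, 0.9)) expect_equal(fisher_combine(p)$p, p)
  ## k = 2 closed form: exp(-x/2) (1 + x/2)
  res <- fisher_combine(c(0.05, 0.05))
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(res$statistic, x, tolerance = 1e-12)
  expect_equal(res$p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(out$p > 0)
  expect_error(fisher_combine(numeric()), "at least one")
})

test_that("Fisher combination is monotone in each input", {
  base <- fisher_combine(c(0.2, 0.3))$p
  for (p1 in c(0.15, 0.1, 0.01)) {
    expect_lt(fisher_combine(c(p1, 0.3))$p, base)
  }
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(1:1000, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  ## dominance and NaN propagation with exclusion from the family size
  p <- c(0.01, NaN, 0.5)
  out <- bh_adjust(p)
  expect_true(is.nan(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(p[c(1, 3)]))
  set.seed(100)
  q <- runif(50)
  expect_true(all(bh_adjust(q) >= q))
})

test_that("overall lfc modes follow the displayed formula and its signed fix", {
  expect_equal(overall_lfc(c(2, 2, 2)), 2)
  expect_equal(overall_lfc(c(2, 2, 2), "as_printed"), 2)
  expect_equal(overall_lfc(c(-2, -2, -2)), -2)
  expect_equal(overall_lfc(c(-2, -2, -2), "as_printed"), 2)
  expect_equal(overall_lfc(c(3, -1, 1)), 1)
  m <- rbind(a = c(1, 2, 3), b = c(-1, -2, -3))
  expect_equal(overall_lfc(m), c(a = 2, b = -2))
  expect_equal(overall_lfc(m, "as_printed"), c(a = 2, b = 2))
  expect_error(overall_lfc(numeric()), "non-empty")
})

test_that("HVG selection takes ceiling(5%) from each tail without overlap", {
  set.seed(4)
  n <- 400
  ids <- sprintf("g%03d", 1:n)
  adj <- c(runif(200, 0, 0.049), runif(200, 0.06, 1))  # 200 eligible
  lfc <- rnorm(n)
  sel <- select_hvgs(ids, adj, lfc, fraction = 0.05)
  expect_length(sel$top, 10)
  expect_length(sel$bottom, 10)
  expect_length(intersect(sel$top, sel$bottom), 0)
  chosen <- c(sel$top, sel$bottom)
  expect_true(all(adj[match(chosen, ids)] < 0.05))
  ## top genes have the largest eligible lfc, bottom the smallest
  elig <- adj < 0.05
  expect_setequal(sel$top, ids[elig][rank(-lfc[elig]) <= 10])
  expect_setequal(sel$bottom, ids[elig][rank(lfc[elig]) <= 10])
  ## 10 eligible -> ceil(0.5) = 1 per tail
  sel2 <- select_hvgs(ids[1:10], rep(0.01, 10), lfc[1:10])
  expect_length(sel2$top, 1)
  expect_length(sel2$bottom, 1)
  ## 0 eligible -> empty with a message
  expect_message(sel0 <- select_hvgs(ids[1:5], rep(0.9, 5), lfc[1:5]),
                 "no eligible")
  expect_length(sel0$top, 0)
})

test_that("selection bound holds and tiny lists truncate the bottom tail", {
  ## 3 eligible at fraction 0.5 -> k = 2, bottom truncated to 1
  sel <- select_hvgs(c("a", "b", "c"), c(0.01, 0.01, 0.01), c(3, 2, 1),
                     fraction = 0.5)
  expect_length(sel$top, 2)
  expect_length(sel$bottom, 1)
  expect_length(intersect(sel$top, sel$bottom), 0)
  expect_lte(length(union(sel$top, sel$bottom)), 2 * ceiling(0.5 * 3))
})

test_that("eight lists are built and merged as a tagged union", {
  norm <- small_norm()
  hv <- build_and_merge_lists(norm)
  expect_length(hv$lists, 8)
  labels <- names(hv$lists)
  expect_setequal(
    labels,
    c(t(outer(c("RTx430", "BTx642"),
              c("preflowering_full", "postflowering_full",
                "preflowering_drought", "preflowering_recovery"),
              paste, sep = "_"))))
  ## merged is exactly the union of the per-list top/bottom selections
  manual <- sort(unique(unlist(lapply(hv$lists, function(l) c(l$top, l$bottom)))))
  expect_identical(hv$merged$gene_id, manual)
  ## sources tags point back to real lists containing the gene
  for (i in seq_len(min(10, nrow(hv$merged)))) {
    g <- hv$merged$gene_id[i]
    for (lbl in strsplit(hv$merged$sources[i], ";")[[1]]) {
      expect_true(g %in% c(hv$lists[[lbl]]$top, hv$lists[[lbl]]$bottom))
    }
  }
  ## every merged gene is eligible in at least one source contrast
  comb <- do.call(rbind, hv$combined)
  expect_true(all(hv$merged$gene_id %in%
                    comb$gene_id[comb$adjusted_p < 0.05 & !is.na(comb$adjusted_p)]))
})

test_that("a null experiment yields an empty or near-empty merged set", {
  sim <- simulate_experiment(sim_config(n_genes = 800, frac_responsive = 0,
                                        seed = 31))
  norm <- upper_quartile_normalize(filter_low_expressed(sim$experiment))
  hv <- suppressMessages(build_and_merge_lists(norm))
  expect_lte(nrow(hv$merged), 5)
})

test_that("missing sub-period samples give empty lists, not errors", {
  sim <- simulate_experiment(sim_config(n_genes = 60, n_weeks = 6, seed = 2))
  norm <- upper_quartile_normalize(filter_low_expressed(sim$experiment))
  expect_message(
    hv <- build_and_merge_lists(norm, windows = list(drought = 3:6,
                                                     recovery = 20:25)),
    "recovery")
  expect_length(hv$lists, 8)
  expect_length(hv$lists[["RTx430_preflowering_recovery"]]$top, 0)
})
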