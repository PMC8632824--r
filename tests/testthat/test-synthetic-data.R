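test_that("simulated experiment has the full factorial design shape", {
  sim <- simulate_experiment(sim_config(n_genes = 100, seed = 3))
  expect_equal(dim(sim$experiment$counts), c(100, 2 * 3 * 17 * 3))
  d <- sim$experiment$design
  expect_equal(nrow(unique(d[, c("genotype", "condition", "week", "replicate")])),
               nrow(d))
  ## a smaller design obeys the same dimension law
  sim2 <- simulate_experiment(sim_config(n_genes = 20, n_weeks = 6,
                                         n_replicates = 2, seed = 3))
  expect_equal(ncol(sim2$experiment$counts), 2 * 3 * 6 * 2)
})

test_that("null configuration plants nothing", {
  sim <- simulate_experiment(sim_config(n_genes = 80, frac_responsive = 0,
                                        seed = 9))
  expect_false(any(sim$truth$genes$responsive))
  for (m in sim$truth$trajectories) expect_true(all(m == 0))
})

test_that("planted trajectories peak exactly at the configured effect size", {
  sim <- simulate_experiment(sim_config(n_genes = 200, effect_size_log2 = 1.5,
                                        seed = 21))
  g <- sim$truth$genes
  for (cond in names(sim$truth$trajectories)) {
    m <- sim$truth$trajectories[[cond]]
    flag_cols <- grep(paste0("responsive_", cond), names(g), value = TRUE)
    flagged <- g$gene_id[Reduce(`|`, g[flag_cols])]
    if (length(flagged)) {
      peaks <- apply(abs(m[flagged, , drop = FALSE]), 1, max)
      expect_equal(unname(peaks), rep(1.5, length(flagged)))
    }
    unflagged <- setdiff(g$gene_id, flagged)
    expect_true(all(m[unflagged, ] == 0))
  }
})

test_that("seeding is a contract: same seed identical, new seed different", {
  a <- simulate_experiment(sim_config(n_genes = 50, seed = 1))
  b <- simulate_experiment(sim_config(n_genes = 50, seed = 1))
  c <- simulate_experiment(sim_config(n_genes = 50, seed = 2))
  expect_identical(a$experiment$counts, b$experiment$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(c$experiment$counts), dim(a$experiment$counts))
  expect_false(identical(a$experiment$counts, c$experiment$counts))
})

test_that("invalid configurations are rejected with a message", {
  expect_error(sim_config(n_genes = 10, n_replicates = 2.5), "integer")
  expect_error(sim_config(n_genes = 10, frac_responsive = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 10, conditions = c("wet", "dry")),
               "control")
  expect_error(sim_config(n_genes = 10, n_replicates = 1), "at least 2")
})

test_that("GO annotation counts are deterministic and overlap-controlled", {
  ids <- sprintf("g%04d", 1:1000)
  ann0 <- simulate_go_annotations(ids, frac = 0, seed = 4)
  expect_equal(nrow(ann0$terms), 0)
  ann <- simulate_go_annotations(ids, frac = 0.1, seed = 4)
  expect_equal(length(unique(ann$terms$gene_id)), 100)
  expect_true(all(ann$terms$go_id %in% cell_wall_go_terms))
  ## curated list is disjoint from the GO-annotated set
  expect_length(intersect(ann$curated, unique(ann$terms$gene_id)), 0)
  ## overlap parameter fixes the annotated-by-responsive count
  resp <- ids[1:200]
  ann2 <- simulate_go_annotations(ids, frac = 0.1, responsive_ids = resp,
                                  overlap = 0.5, seed = 4)
  expect_equal(length(intersect(unique(ann2$terms$gene_id), resp)), 50)
  expect_error(simulate_go_annotations(c("a", "a")), "unique")
})

test_that("chemistry simulator plants effects on the mean and respects CV", {
  null_sim <- simulate_chem_dataset(effects = data.frame(
    analyte = character(), genotype = character(), condition = character(),
    week = numeric(), percent = numeric()), cv = 0, seed = 2)
  tab <- null_sim$table
  ## zero planted effect and zero CV: drought equals control exactly
  for (a in unique(tab$analyte)) {
    sub <- tab[tab$analyte == a, ]
    expect_equal(length(unique(sub$quantity)), 1)
  }
  ## default effects include the 62/33/62/37 percent leaf increases
  eff <- default_chem_effects()
  expect_setequal(eff$percent, c(62, 33, 62, 37))
  eff_sim <- simulate_chem_dataset(cv = 0, seed = 2)
  t7 <- eff_sim$table
  rha_trt <- t7$quantity[t7$analyte == "rhamnose" & t7$condition == "preflowering" &
                           t7$week == 7 & t7$genotype == "RTx430"][1]
  rha_ctl <- t7$quantity[t7$analyte == "rhamnose" & t7$condition == "control" &
                           t7$week == 7 & t7$genotype == "RTx430"][1]
  expect_equal(rha_trt / rha_ctl, 1.62)
  expect_error(simulate_chem_dataset(cv = -0.1), "nonnegative")
})

test_that("simulation tables round-trip through the TSV writers", {
  sim <- simulate_experiment(sim_config(n_genes = 30, n_weeks = 5, seed = 8))
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 30, n_weeks = 5, seed = 8)
  ann <- simulate_go_annotations(rownames(sim$experiment$counts), cfg,
                                 responsive_ids = sim$truth$responsive_ids)
  write_simulation(sim, annotations = ann, config = cfg, dir = dir)
  back <- read_counts_experiment(file.path(dir, "counts.tsv"),
                                 file.path(dir, "design.tsv"))
  expect_identical(back$counts, sim$experiment$counts)
  expect_identical(back$design, sim$experiment$design)
  ann_back <- read_go_annotations(file.path(dir, "annotations.tsv"),
                                  curated_path = file.path(dir, "curated_genes.txt"))
  expect_setequal(unique(ann_back$terms$gene_id), unique(ann$terms$gene_id))
  expect_identical(ann_back$curated, ann$curated)
})
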