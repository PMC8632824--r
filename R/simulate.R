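#' Simulation configuration for the drought field design
#'
#' Describes a synthetic bulk RNA-seq time course mirroring a field drought
#' trial: two genotypes, three irrigation regimes (well-watered control,
#' pre-flowering drought with recovery, post-flowering drought), weekly
#' sampling and replicated plots. A configurable fraction of genes carries a
#' planted smooth drought-response trajectory whose peak absolute log2 fold
#' change equals \code{effect_size_log2}; the remainder are null.
#'
#' @param n_genes Number of genes.
#' @param n_weeks Number of weekly time points (default 17).
#' @param genotypes Genotype labels (default the two cultivars RTx430 and
#'   BTx642, an early-senescing pre-flowering-tolerant and a stay-green
#'   post-flowering-tolerant line).
#' @param conditions Irrigation condition labels; must contain
#'   \code{"control"}.
#' @param n_replicates Replicate plots per genotype x condition (default 3,
#'   must be at least 2).
#' @param tissue Tissue label for the generated samples.
#' @param frac_responsive Fraction of genes that are drought-responsive.
#' @param effect_size_log2 Peak absolute log2 fold change of planted
#'   trajectories (default 2).
#' @param dispersion Negative-binomial dispersion (scalar, or one value per
#'   gene); variance is \code{mu + dispersion * mu^2}.
#' @param baseline_log2_range Range of per-gene baseline log2 mean counts.
#' @param size_factor_range Per-sample library size factors are drawn
#'   log-uniformly within this range, so upper-quartile normalization has
#'   real work to do.
#' @param prob_cell_response Given a responsive gene, the probability that a
#'   particular genotype x drought-condition cell actually responds; values
#'   below 1 make part of the response genotype-specific, as expected when
#'   the two cultivars follow different drought-tolerance strategies.
#' @param recovery_response_prob Probability that a pre-flowering-responsive
#'   gene also shows a (possibly opposite-signed) response during the
#'   re-watering recovery period.
#' @param drought_weeks,recovery_weeks,post_weeks Week windows (1-based) in
#'   which the pre-flowering drought, recovery, and post-flowering drought
#'   responses are active. Defaults follow withheld irrigation in weeks 3-8,
#'   recovery afterwards, and post-flowering drought from week 10 on.
#' @param frac_cellwall_annotated Fraction of genes receiving cell-wall GO
#'   annotation in [simulate_go_annotations()].
#' @param overlap_responsive Fraction of cell-wall-annotated genes drawn from
#'   the responsive set (controls the annotated-by-responsive overlap).
#' @param n_curated Size of the simulated curated cell-wall gene list.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   simulated tables bit for bit.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes,
                       n_weeks = 17,
                       genotypes = c("RTx430", "BTx642"),
                       conditions = c("control", "preflowering", "postflowering"),
                       n_replicates = 3,
                       tissue = "leaf",
                       frac_responsive = 0.10,
                       effect_size_log2 = 2,
                       dispersion = 0.1,
                       baseline_log2_range = c(2, 10),
                       size_factor_range = c(0.5, 2),
                       prob_cell_response = 0.7,
                       recovery_response_prob = 0.5,
                       drought_weeks = 3:8,
                       recovery_weeks = 9:17,
                       post_weeks = 10:17,
                       frac_cellwall_annotated = 0.10,
                       overlap_responsive = 0.5,
                       n_curated = 10,
                       seed = 1) {
  if (n_genes < 1) stopf("n_genes must be positive")
  if (n_weeks < 1) stopf("n_weeks must be positive")
  if (n_replicates != floor(n_replicates)) {
    stopf("n_replicates must be an integer, got %s", format(n_replicates))
  }
  if (n_replicates < 2) stopf("n_replicates must be at least 2")
  for (nm in c("frac_responsive", "frac_cellwall_annotated",
               "overlap_responsive", "prob_cell_response",
               "recovery_response_prob")) {
    v <- get(nm)
    if (v < 0 || v > 1) stopf("%s must lie in [0, 1], got %s", nm, format(v))
  }
  if (!"control" %in% conditions) stopf("conditions must contain \"control\"")
  if (any(dispersion <= 0)) stopf("dispersion must be positive")
  if (effect_size_log2 < 0) stopf("effect_size_log2 must be nonnegative")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_weeks, "weeks,",
      length(x$genotypes), "genotypes x", length(x$conditions),
      "conditions x", x$n_replicates, "replicates\n")
  cat("  responsive fraction", x$frac_responsive,
      "| peak |log2FC|", x$effect_size_log2,
      "| NB dispersion", x$dispersion[1], "\n")
  invisible(x)
}

## Smooth bump supported on a week window: half-sine raised to a random
## power so planted responses vary in width, rescaled to unit peak.
bump_shape <- function(weeks, window, sharpness = 1) {
  out <- numeric(length(weeks))
  idx <- weeks %in% window
  if (!any(idx)) return(out)
  a <- min(window) - 1
  b <- max(window) + 1
  u <- (weeks[idx] - a) / (b - a)
  s <- sin(pi * u)^sharpness
  out[idx] <- s / max(s)
  out
}

#' Simulate a drought time-course RNA-seq experiment
#'
#' Draws negative-binomial counts around genotype x condition x week means.
#' Drought-responsive genes deviate from the control mean by a planted smooth
#' log2 trajectory: pre-flowering responses are a bump over the drought-weeks
#' window, optionally followed by a recovery-window bump; post-flowering
#' responses are a bump over the post-flowering window. Every responsive
#' gene's trajectory is rescaled so its peak absolute value equals
#' \code{effect_size_log2}; non-responsive genes have identically zero
#' trajectories.
#'
#' @param config A [sim_config()].
#' @return List with elements \code{experiment} (a
#'   \code{\link{counts_experiment}}) and \code{truth}, the ground-truth
#'   table: a list holding the per-gene data frame \code{genes} (responsive
#'   flag per genotype x condition cell) and per-condition planted trajectory
#'   matrices (genes x weeks, on the log2 scale).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, seed = 7))
#' dim(sim$experiment$counts)  # 100 x 306
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  n <- config$n_genes
  weeks <- seq_len(config$n_weeks)
  gene_ids <- sprintf("SbGene%05d", seq_len(n))
  drought_conditions <- setdiff(config$conditions, "control")

  baseline <- stats::runif(n, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  dispersion <- rep_len(config$dispersion, n)

  n_resp <- round_half_up(config$frac_responsive * n)
  responsive_ids <- if (n_resp > 0) sort(sample(gene_ids, n_resp)) else character()

  ## planted log2 trajectories per drought condition (shared across genotypes)
  ## and per-cell responsiveness flags
  traj <- lapply(drought_conditions, function(cond) {
    matrix(0, n, length(weeks), dimnames = list(gene_ids, paste0("w", weeks)))
  })
  names(traj) <- drought_conditions
  flags <- matrix(FALSE, n, length(drought_conditions) * length(config$genotypes),
                  dimnames = list(gene_ids, as.vector(outer(
                    drought_conditions, config$genotypes, paste, sep = "."))))

  windows <- list(
    preflowering = list(active = intersect(config$drought_weeks, weeks),
                        recovery = intersect(config$recovery_weeks, weeks)),
    postflowering = list(active = intersect(config$post_weeks, weeks),
                         recovery = integer())
  )

  for (g in responsive_ids) {
    for (cond in drought_conditions) {
      win <- windows[[cond]] %||%
        list(active = weeks, recovery = integer())
      if (!length(win$active)) next
      sgn <- sample(c(-1, 1), 1)
      shape <- bump_shape(weeks, win$active, sharpness = stats::runif(1, 0.5, 2))
      curve <- sgn * shape
      if (length(win$recovery) && cond == "preflowering" &&
          stats::runif(1) < config$recovery_response_prob) {
        rec_sgn <- sample(c(-1, 1), 1)
        rec_amp <- stats::runif(1, 0.4, 1)
        curve <- curve + rec_sgn * rec_amp *
          bump_shape(weeks, win$recovery, sharpness = stats::runif(1, 0.5, 2))
      }
      peak <- max(abs(curve))
      if (peak == 0) next
      curve <- curve / peak * config$effect_size_log2
      ## which genotype cells respond: at least one, each with stated prob
      cell_on <- stats::runif(length(config$genotypes)) < config$prob_cell_response
      if (!any(cell_on)) cell_on[sample(length(cell_on), 1)] <- TRUE
      traj[[cond]][g, ] <- curve
      flags[g, paste(cond, config$genotypes[cell_on], sep = ".")] <- TRUE
    }
  }

  ## sample grid and library size factors
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      week = weeks,
                      condition = config$conditions,
                      genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "condition", "week", "replicate")]
  design <- data.frame(
    sample_id = sprintf("%s_%s_w%02d_r%d", grid$genotype, grid$condition,
                        grid$week, grid$replicate),
    genotype = grid$genotype,
    tissue = config$tissue,
    condition = grid$condition,
    week = grid$week,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  sf <- exp(stats::runif(nrow(design), log(config$size_factor_range[1]),
                         log(config$size_factor_range[2])))

  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cond <- design$condition[j]
    delta <- if (cond %in% drought_conditions) {
      on <- flags[, paste(cond, design$genotype[j], sep = ".")]
      ifelse(on, traj[[cond]][, design$week[j]], 0)
    } else {
      0
    }
    mu <- 2^(baseline + delta) * sf[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  storage.mode(counts) <- "integer"

  genes <- data.frame(gene_id = gene_ids,
                      responsive = gene_ids %in% responsive_ids,
                      stringsAsFactors = FALSE)
  for (cl in colnames(flags)) genes[[paste0("responsive_", cl)]] <- flags[, cl]

  list(
    experiment = counts_experiment(counts, design),
    truth = list(genes = genes,
                 trajectories = traj,
                 responsive_ids = responsive_ids,
                 size_factors = stats::setNames(sf, design$sample_id),
                 baseline_log2 = stats::setNames(baseline, gene_ids))
  )
}

#' Simulate GO annotations and a curated cell-wall list
#'
#' Assigns cell-wall GO terms (the four terms used for cell-wall HVG
#' filtering: plant-type cell wall biogenesis GO:0009832, cell wall
#' organization GO:0071555, cell wall organization or biogenesis GO:0071554,
#' cell wall biogenesis GO:0042546) to a deterministic number of genes
#' (\code{round_half_up(frac * n)}), draws a disjoint curated list, and gives
#' every annotated or curated gene a protein-family label whose default
#' family-to-category mapping yields biosynthesis / modification / signaling
#' classes.
#'
#' @param gene_ids Unique gene identifiers.
#' @param config A [sim_config()] (supplies the annotated fraction, overlap
#'   with the responsive set, curated-list size and seed), or \code{NULL} to
#'   use the remaining arguments directly.
#' @param responsive_ids Gene ids that are drought-responsive; the overlap
#'   parameter draws this share of the annotated genes from that set.
#' @param frac,overlap,n_curated,seed Used when \code{config} is \code{NULL}.
#' @return A \code{go_annotation_set} (see [go_annotation_set()]), with the
#'   planted per-gene category stored in \code{$families$category_truth}.
#' @export
simulate_go_annotations <- function(gene_ids, config = NULL,
                                    responsive_ids = character(),
                                    frac = 0.1, overlap = 0.5,
                                    n_curated = 10, seed = 1) {
  if (anyDuplicated(gene_ids)) stopf("gene ids must be unique")
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    frac <- config$frac_cellwall_annotated
    overlap <- config$overlap_responsive
    n_curated <- config$n_curated
    seed <- config$seed + 1L  # distinct stream from the count draw
  }
  with_seed(seed, {
    n <- length(gene_ids)
    n_cw <- round_half_up(frac * n)
    responsive_ids <- intersect(responsive_ids, gene_ids)
    n_from_resp <- min(round_half_up(overlap * n_cw), length(responsive_ids))
    pool_other <- setdiff(gene_ids, responsive_ids)
    n_from_other <- min(n_cw - n_from_resp, length(pool_other))
    cw <- c(if (n_from_resp > 0) sample(responsive_ids, n_from_resp),
            if (n_from_other > 0) sample(pool_other, n_from_other))
    cw <- sort(cw)

    terms <- if (length(cw)) {
      do.call(rbind, lapply(cw, function(g) {
        k <- sample(1:2, 1)
        data.frame(gene_id = g,
                   go_id = sample(cell_wall_go_terms, k),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(gene_id = character(), go_id = character(),
                 stringsAsFactors = FALSE)
    }

    non_cw <- setdiff(gene_ids, cw)
    curated <- if (n_curated > 0 && length(non_cw)) {
      sort(sample(non_cw, min(n_curated, length(non_cw))))
    } else {
      character()
    }

    fam_pool <- default_family_map()
    members <- sort(union(cw, curated))
    families <- data.frame(
      gene_id = members,
      family = if (length(members)) {
        sample(fam_pool$family, length(members), replace = TRUE,
               prob = fam_pool$sim_weight)
      } else character(),
      stringsAsFactors = FALSE
    )
    families$category_truth <-
      fam_pool$category[match(families$family, fam_pool$family)]

    go_annotation_set(terms = terms, curated = curated, families = families)
  })
}

#' Simulate a cell-wall chemistry assay table
#'
#' Replicate measurements per analyte x week x condition x genotype, drawn
#' lognormally around \code{control mean x (1 + planted effect)} with a given
#' coefficient of variation. The default effect table plants the kind of
#' drought effects reported for field-grown sorghum cell walls: leaf matrix
#' rhamnose/arabinose/glucose/galacturonic-acid increases of 62/33/62/37%
#' under pre-flowering drought.
#'
#' @param analytes Named numeric vector of control means (units are carried
#'   through unchanged, nmol per mg AIR by convention).
#' @param effects Data frame with columns \code{analyte}, \code{genotype},
#'   \code{condition}, \code{week}, \code{percent} (planted percent change
#'   versus control). Cells not listed have effect 0.
#' @param weeks,conditions,genotypes,n_replicates Assay design.
#' @param cv Replicate coefficient of variation (lognormal); \code{cv = 0}
#'   gives replicates exactly equal to the cell mean.
#' @param tissue Tissue label.
#' @param seed Integer seed.
#' @return List with \code{table} (an analyte table data frame: analyte,
#'   tissue, genotype, condition, week, replicate, quantity) and
#'   \code{truth} (planted percent change per cell).
#' @export
simulate_chem_dataset <- function(analytes = c(rhamnose = 20, arabinose = 150,
                                               glucose = 120, galacturonic_acid = 45,
                                               galactose = 60, xylose = 300),
                                  effects = default_chem_effects(),
                                  weeks = c(7, 14),
                                  conditions = c("control", "preflowering",
                                                 "postflowering"),
                                  genotypes = c("RTx430", "BTx642"),
                                  n_replicates = 3,
                                  cv = 0.10,
                                  tissue = "leaf",
                                  seed = 1) {
  if (cv < 0) stopf("replicate CV must be nonnegative")
  if (is.null(names(analytes)) || any(names(analytes) == "")) {
    stopf("analytes must be a named vector of control means")
  }
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        week = weeks, condition = conditions,
                        genotype = genotypes, analyte = names(analytes),
                        stringsAsFactors = FALSE)
    key <- function(a, g, c, w) paste(a, g, c, w, sep = "|")
    eff <- stats::setNames(effects$percent,
                           key(effects$analyte, effects$genotype,
                               effects$condition, effects$week))
    pct <- eff[key(grid$analyte, grid$genotype, grid$condition, grid$week)]
    pct[is.na(pct) | grid$condition == "control"] <- 0
    mu <- unname(analytes[grid$analyte]) * (1 + pct / 100)
    q <- if (cv == 0) mu else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(nrow(grid), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }
    tab <- data.frame(analyte = grid$analyte, tissue = tissue,
                      genotype = grid$genotype, condition = grid$condition,
                      week = grid$week, replicate = grid$replicate,
                      quantity = q, stringsAsFactors = FALSE)
    truth <- unique(data.frame(analyte = grid$analyte, tissue = tissue,
                               genotype = grid$genotype,
                               condition = grid$condition, week = grid$week,
                               percent_planted = pct,
                               stringsAsFactors = FALSE))
    list(table = tab, truth = truth)
  })
}

#' Default planted chemistry effects
#'
#' Percent changes echoing reported leaf matrix-monosaccharide drought
#' responses (rhamnose +62, arabinose +33, glucose +62, galacturonic acid
#' +37 at week 7 under pre-flowering drought in RTx430).
#' @return Data frame with columns analyte, genotype, condition, week, percent.
#' @export
default_chem_effects <- function() {
  data.frame(
    analyte = c("rhamnose", "arabinose", "glucose", "galacturonic_acid"),
    genotype = "RTx430",
    condition = "preflowering",
    week = 7,
    percent = c(62, 33, 62, 37),
    stringsAsFactors = FALSE
  )
}

#' Write all simulated tables to a directory
#'
#' Emits counts and design TSVs, the GO annotation two-column TSV plus the
#' curated list and family map, the truth tables, and the configuration as
#' YAML.
#'
#' @param sim Result of [simulate_experiment()].
#' @param annotations Result of [simulate_go_annotations()] (optional).
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, annotations = NULL, config = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_counts_experiment(sim$experiment,
                                   file.path(dir, "counts.tsv"),
                                   file.path(dir, "design.tsv"))
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in names(sim$truth$trajectories)) {
    m <- sim$truth$trajectories[[cond]]
    utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                       file.path(dir, paste0("truth_trajectory_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(annotations)) {
    write_go_annotations(annotations, file.path(dir, "annotations.tsv"),
                         curated_path = file.path(dir, "curated_genes.txt"),
                         family_path = file.path(dir, "families.tsv"))
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(paths)
}
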