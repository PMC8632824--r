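#' Default pipeline configuration
#'
#' Assembles the full run configuration, defaulting every module parameter:
#' simulated input matching the field design, mean-count filter 1,
#' spline df 4, HVG tail fraction 0.05 at adjusted p < 0.05 with signed-mean
#' ranking, drought/recovery windows 3-8 / 9-17, focus weeks 7 and 14, and
#' chemistry contrasts at FDR 0.25.
#'
#' @param n_genes Number of simulated genes.
#' @param seed Master seed for the run.
#' @param ... Overrides for any top-level entry.
#' @return A nested list (class \code{run_config}).
#' @export
default_run_config <- function(n_genes = 2000, seed = 1, ...) {
  cfg <- list(
    seed = seed,
    simulation = list(n_genes = n_genes, seed = seed),
    counts_path = NULL, design_path = NULL,
    annotations_path = NULL, curated_path = NULL, family_path = NULL,
    preprocess = list(min_mean = 1),
    de = list(df = 4),
    hvg = list(fraction = 0.05, alpha = 0.05, lfc_mode = "signed_mean",
               windows = list(drought = 3:8, recovery = 9:17)),
    cw = list(weeks_focus = c(7, 14), trend_band = 0.25),
    chem = list(weeks = c(7, 14), fdr = 0.25, alpha = 0.05, cv = 0.10,
                seed = seed)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file whose top-level keys override the defaults.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(
    n_genes = raw$simulation$n_genes %||% 2000,
    seed = raw$seed %||% 1
  )
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

manifest_entry <- function(stage, ...) {
  c(list(stage = stage), list(...))
}

write_manifest <- function(path, config, stages) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "droughtwall",
    version = as.character(utils::packageVersion("droughtwall")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the transcriptome pipeline
#'
#' simulate (or load) counts -> filter and upper-quartile normalize ->
#' spline time-course DE per genotype and drought condition (full course and
#' pre-flowering sub-periods) -> Fisher/BH combination and HVG selection
#' (eight lists, merged) -> cell-wall GO filtering and category summary.
#' All intermediate tables are written as TSV under \code{out_dir} together
#' with a JSON manifest; the same configuration and seed reproduce the
#' tables byte for byte (manifest timestamp aside).
#'
#' @param config A \code{run_config} (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory results: \code{sim},
#'   \code{norm}, \code{hvgs}, \code{cw}, \code{summary}, and
#'   \code{annotations}.
#' @export
run_transcriptome_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()

  ## stage 1: input
  if (!is.null(config$counts_path)) {
    experiment <- read_counts_experiment(config$counts_path, config$design_path)
    sim <- NULL
    truth <- NULL
  } else {
    scfg <- do.call(sim_config, config$simulation)
    sim <- simulate_experiment(scfg)
    experiment <- sim$experiment
    truth <- sim$truth
    write_simulation(sim, config = scfg, dir = file.path(out_dir, "simulated"))
  }
  stages$input <- manifest_entry("input", genes = nrow(experiment$counts),
                                 samples = ncol(experiment$counts))

  ## stage 2: annotations
  annotations <- if (!is.null(config$annotations_path)) {
    read_go_annotations(config$annotations_path,
                        curated_path = config$curated_path,
                        family_path = config$family_path)
  } else if (!is.null(sim)) {
    scfg <- do.call(sim_config, config$simulation)
    simulate_go_annotations(rownames(experiment$counts), scfg,
                            responsive_ids = truth$responsive_ids)
  } else {
    go_annotation_set(data.frame(gene_id = character(), go_id = character()))
  }
  write_go_annotations(annotations, file.path(out_dir, "annotations.tsv"),
                       curated_path = file.path(out_dir, "curated_genes.txt"),
                       family_path = file.path(out_dir, "families.tsv"))
  stages$annotations <- manifest_entry(
    "annotations", annotated_genes = length(unique(annotations$terms$gene_id)),
    curated = length(annotations$curated))

  ## stage 3: preprocess
  filtered <- filter_low_expressed(experiment, config$preprocess$min_mean)
  norm <- upper_quartile_normalize(filtered)
  write_normalized_matrix(norm, file.path(out_dir, "normalized.tsv"),
                          file.path(out_dir, "size_factors.tsv"))
  stages$preprocess <- manifest_entry("preprocess",
                                      genes_kept = nrow(norm$values),
                                      min_mean = config$preprocess$min_mean)

  ## stage 4: DE + HVG
  hvgs <- build_and_merge_lists(norm,
                                windows = config$hvg$windows,
                                df = config$de$df,
                                fraction = config$hvg$fraction,
                                alpha = config$hvg$alpha,
                                lfc_mode = config$hvg$lfc_mode)
  for (nm in names(hvgs$de)) {
    for (g in names(hvgs$de[[nm]])) {
      de <- hvgs$de[[nm]][[g]]
      utils::write.table(as.data.frame(de),
                         file.path(out_dir, sprintf("de_%s_%s.tsv", g, nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_hvg_set(hvgs, out_dir)
  stages$hvg <- manifest_entry("hvg", lists = length(hvgs$lists),
                               merged = nrow(hvgs$merged))

  ## stage 5: cell-wall filter + summary
  cw <- filter_by_go(hvgs, annotations)
  cls <- classify_function(cw$gene_id, annotations)
  cw$category <- cls$category
  cw$family <- cls$family
  utils::write.table(cw, file.path(out_dir, "cellwall_hvgs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_ <- summarize_counts(cw, hvgs,
                               weeks_focus = config$cw$weeks_focus,
                               trend_band = config$cw$trend_band)
  utils::write.table(summary_$counts, file.path(out_dir, "cw_summary_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_$genes, file.path(out_dir, "cw_summary_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$cellwall <- manifest_entry("cellwall", cw_hvgs = nrow(cw))

  write_manifest(file.path(out_dir, "manifest.json"), config, stages)
  invisible(list(sim = sim, truth = truth, norm = norm, hvgs = hvgs,
                 cw = cw, summary = summary_, annotations = annotations))
}

#' Run the chemistry pipeline
#'
#' Simulates (or loads) the analyte table, then computes
#' treatment-vs-control t-test contrasts with percent changes and BH
#' decisions for the focus weeks, writing the contrast and percent-change
#' reports plus a manifest.
#'
#' @param config A \code{run_config} or YAML path; \code{config$chem} may
#'   carry \code{table_path} to load a measured analyte table instead of
#'   simulating.
#' @param out_dir Output directory.
#' @return Invisibly, a list with \code{table}, \code{truth},
#'   \code{contrasts}.
#' @export
run_chem_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  chem <- config$chem
  if (!is.null(chem$table_path)) {
    tab <- read_analyte_table(chem$table_path)
    truth <- NULL
  } else {
    sim <- simulate_chem_dataset(cv = chem$cv %||% 0.10,
                                 weeks = chem$weeks %||% c(7, 14),
                                 seed = chem$seed %||% config$seed)
    tab <- sim$table
    truth <- sim$truth
    write_analyte_table(tab, file.path(out_dir, "analyte_table.tsv"))
  }
  stages$input <- manifest_entry("chem_input", rows = nrow(tab))
  contrasts <- chem_contrasts(tab, weeks = chem$weeks %||% c(7, 14),
                              fdr = chem$fdr %||% 0.25,
                              alpha = chem$alpha %||% 0.05,
                              remove_outliers = isTRUE(chem$remove_outliers))
  write_analyte_table(contrasts, file.path(out_dir, "chem_contrasts.tsv"))
  pct <- contrasts[, intersect(c("analyte", "tissue", "genotype", "week",
                                 "condition", "percent_change", "significant"),
                               names(contrasts))]
  write_analyte_table(pct, file.path(out_dir, "chem_percent_change.tsv"))
  stages$contrasts <- manifest_entry("chem_contrasts", rows = nrow(contrasts),
                                     significant = sum(contrasts$significant))
  write_manifest(file.path(out_dir, "chem_manifest.json"), config, stages)
  invisible(list(table = tab, truth = truth, contrasts = contrasts))
}
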