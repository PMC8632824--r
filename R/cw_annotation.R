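#' Cell-wall GO terms used for HVG filtering
#'
#' Plant-type cell wall biogenesis (GO:0009832), cell wall organization
#' (GO:0071555), cell wall organization or biogenesis (GO:0071554), and cell
#' wall biogenesis (GO:0042546).
#' @export
cell_wall_go_terms <- c("GO:0009832", "GO:0071555", "GO:0071554", "GO:0042546")

#' Construct a GO annotation set
#'
#' @param terms Data frame with columns \code{gene_id}, \code{go_id}
#'   (GO:NNNNNNN).
#' @param curated Character vector of curated cell-wall gene ids (may be
#'   empty); curated genes are retained by the cell-wall filter regardless
#'   of their GO terms.
#' @param families Optional data frame \code{gene_id}, \code{family} giving
#'   a protein-family label per gene, used by [classify_function()].
#' @return Object of class \code{go_annotation_set}.
#' @export
go_annotation_set <- function(terms, curated = character(), families = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_id") %in% names(terms))) {
    stopf("terms needs columns gene_id and go_id")
  }
  bad <- which(!grepl("^GO:\\d{7}$", terms$go_id))
  if (length(bad)) {
    stopf("malformed GO id '%s' in terms row %d", terms$go_id[bad[1]], bad[1])
  }
  structure(list(terms = terms, curated = as.character(curated),
                 families = families),
            class = "go_annotation_set")
}

#' @export
print.go_annotation_set <- function(x, ...) {
  cat("go_annotation_set:", length(unique(x$terms$gene_id)),
      "annotated genes,", nrow(x$terms), "gene-term pairs,",
      length(x$curated), "curated genes\n")
  invisible(x)
}

#' Read GO annotations from GAF 2.x or a two-column TSV
#'
#' GAF lines beginning with \code{!} are skipped; column 2 is taken as the
#' gene id and column 5 as the GO id. The two-column format is
#' \code{gene_id<TAB>GO:NNNNNNN}, with an optional header. Malformed GO ids
#' raise an error naming the offending line.
#'
#' @param path Annotation file.
#' @param format \code{"auto"} (sniff), \code{"gaf"}, or \code{"tsv"}.
#' @param curated_path Optional one-gene-per-line curated list.
#' @param family_path Optional TSV \code{gene_id<TAB>family}.
#' @return A \code{go_annotation_set}.
#' @export
read_go_annotations <- function(path, format = c("auto", "gaf", "tsv"),
                                curated_path = NULL, family_path = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    probe <- lines[!startsWith(lines, "!")]
    probe <- probe[nzchar(probe)]
    ncol1 <- length(strsplit(probe[1], "\t", fixed = TRUE)[[1]])
    format <- if (ncol1 >= 15) "gaf" else "tsv"
  }
  keep <- which(!startsWith(lines, "!") & nzchar(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (format == "gaf") {
    gene <- vapply(rows, `[`, character(1), 2L)
    go <- vapply(rows, `[`, character(1), 5L)
  } else {
    if (length(rows) && identical(tolower(rows[[1]][1]), "gene_id")) {
      keep <- keep[-1]; rows <- rows[-1]
    }
    gene <- vapply(rows, `[`, character(1), 1L)
    go <- vapply(rows, `[`, character(1), 2L)
  }
  bad <- which(is.na(go) | !grepl("^GO:\\d{7}$", go))
  if (length(bad)) {
    stopf("malformed GO id '%s' at line %d of %s",
          go[bad[1]], keep[bad[1]], path)
  }
  curated <- if (!is.null(curated_path)) readLines(curated_path) else character()
  families <- if (!is.null(family_path)) {
    utils::read.delim(family_path, stringsAsFactors = FALSE)
  } else NULL
  go_annotation_set(data.frame(gene_id = gene, go_id = go,
                               stringsAsFactors = FALSE),
                    curated = curated, families = families)
}

#' Write GO annotations as two-column TSV
#' @param annotations A \code{go_annotation_set}.
#' @param path Output TSV (gene_id, go_id).
#' @param curated_path,family_path Optional sidecar outputs.
#' @return Invisibly, the written paths.
#' @export
write_go_annotations <- function(annotations, path, curated_path = NULL,
                                 family_path = NULL) {
  utils::write.table(annotations$terms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(curated_path)) writeLines(annotations$curated, curated_path)
  if (!is.null(family_path) && !is.null(annotations$families)) {
    utils::write.table(annotations$families, family_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a gene set to cell-wall-related genes
#'
#' Keeps genes that carry at least one of the cell-wall GO terms or appear
#' on the curated list; each retained gene is tagged with its matching terms
#' (curated-only genes are tagged \code{"curated"}).
#'
#' @param genes Character vector of gene ids, or the \code{merged} data
#'   frame of an \code{hvg_set}, or an \code{hvg_set} itself.
#' @param annotations A \code{go_annotation_set}.
#' @param terms GO term ids defining "cell-wall related" (default
#'   [cell_wall_go_terms]).
#' @return Data frame \code{gene_id}, \code{tags} (semicolon-joined matched
#'   terms and/or "curated"); a subset of the input genes.
#' @export
filter_by_go <- function(genes, annotations, terms = cell_wall_go_terms) {
  stopifnot(inherits(annotations, "go_annotation_set"))
  if (inherits(genes, "hvg_set")) genes <- genes$merged$gene_id
  if (is.data.frame(genes)) genes <- genes$gene_id
  hits <- annotations$terms[annotations$terms$go_id %in% terms, , drop = FALSE]
  tag_list <- split(hits$go_id, hits$gene_id)
  out <- lapply(genes, function(g) {
    t <- sort(unique(tag_list[[g]]))
    if (g %in% annotations$curated) t <- c(t, "curated")
    if (!length(t)) return(NULL)
    data.frame(gene_id = g, tags = paste(t, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), tags = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Default family-to-category map
#'
#' Maps protein-family labels to the three cell-wall function categories:
#' polysaccharide synthases and transferases to biosynthesis; expansins,
#' XTHs, peroxidases, pectin esterases/lyases and glycosyl hydrolases to
#' modification; kinases to signaling. \code{sim_weight} is the sampling
#' weight the annotation simulator uses (modification-heavy, as observed in
#' drought HVG sets).
#' @return Data frame with columns \code{family}, \code{category},
#'   \code{sim_weight}.
#' @export
default_family_map <- function() {
  data.frame(
    family = c("cellulose synthase", "glycosyltransferase", "xylan synthase",
               "callose synthase",
               "expansin", "xyloglucan endotransglucosylase/hydrolase",
               "peroxidase", "pectin methylesterase", "pectate lyase",
               "glycosyl hydrolase",
               "wall-associated kinase", "receptor-like kinase"),
    category = c(rep("biosynthesis", 4), rep("modification", 6),
                 rep("signaling", 2)),
    sim_weight = c(0.08, 0.12, 0.06, 0.04,
                   0.14, 0.10, 0.10, 0.08, 0.06, 0.12,
                   0.05, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Classify cell-wall genes into function categories
#'
#' Assigns biosynthesis / modification / signaling from a family-to-category
#' table applied to each gene's family label. Genes without a mapped family
#' fall back to \code{"modification"} and are flagged.
#'
#' @param genes Character vector of gene ids.
#' @param annotations A \code{go_annotation_set} whose \code{families} table
#'   supplies each gene's family label.
#' @param family_map Data frame \code{family}, \code{category}; default
#'   [default_family_map()].
#' @param default_category Category used for unmapped genes.
#' @return Data frame \code{gene_id}, \code{family}, \code{category},
#'   \code{flagged} (TRUE when the default was used).
#' @export
classify_function <- function(genes, annotations,
                              family_map = default_family_map(),
                              default_category = "modification") {
  fams <- annotations$families
  fam <- if (!is.null(fams)) fams$family[match(genes, fams$gene_id)] else
    rep(NA_character_, length(genes))
  cat_ <- family_map$category[match(fam, family_map$family)]
  flagged <- is.na(cat_)
  if (any(flagged)) {
    warnf("%d gene(s) without a mapped family assigned '%s'",
          sum(flagged), default_category)
  }
  cat_[flagged] <- default_category
  data.frame(gene_id = genes, family = fam, category = cat_,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Summarize cell-wall HVGs by treatment and category
#'
#' Produces the per-treatment count summary (how many cell-wall HVGs of each
#' function category each drought treatment produced, per genotype) plus the
#' per-gene week-7 and week-14 log2 fold changes and a main-trend label. The
#' trend is the sign of the mean trajectory within the treatment's active
#' weeks: increased, decreased, or no change when the absolute mean is below
#' \code{trend_band} log2 units.
#'
#' @param cw Data frame from [filter_by_go()] merged with a
#'   \code{category} column (e.g. via [classify_function()]).
#' @param hvgs The \code{hvg_set} the genes came from (supplies source lists
#'   and the underlying DE trajectories).
#' @param weeks_focus Weeks at which to extract L (default 7 and 14).
#' @param windows Active-week windows per treatment used for the trend mean
#'   (defaults: preflowering 3-8, recovery 9-17, postflowering 10-17).
#' @param trend_band Half-width of the "no change" band (log2 units).
#' @return Object of class \code{cw_summary}: \code{counts} (treatment x
#'   genotype x category counts) and \code{genes} (per gene x genotype x
#'   treatment: L at the focus weeks, trend).
#' @export
summarize_counts <- function(cw, hvgs, weeks_focus = c(7, 14),
                             windows = list(preflowering = 3:8,
                                            recovery = 9:17,
                                            postflowering = 10:17),
                             trend_band = 0.25) {
  stopifnot(inherits(hvgs, "hvg_set"))
  if (!"category" %in% names(cw)) stopf("cw needs a 'category' column")
  merged <- hvgs$merged
  src <- merged$sources[match(cw$gene_id, merged$gene_id)]

  ## map each source list label to a treatment
  list_treatment <- function(lbl) {
    parts <- strsplit(lbl, "_", fixed = TRUE)[[1]]
    cond <- parts[2]; period <- parts[3]
    if (cond == "preflowering" && period == "recovery") "recovery" else cond
  }
  rows <- list()
  gene_rows <- list()
  for (i in seq_len(nrow(cw))) {
    labels <- strsplit(src[i] %||% "", ";", fixed = TRUE)[[1]]
    labels <- labels[nzchar(labels)]
    for (lbl in labels) {
      parts <- strsplit(lbl, "_", fixed = TRUE)[[1]]
      genotype <- parts[1]
      treatment <- list_treatment(lbl)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cw$gene_id[i], genotype = genotype, treatment = treatment,
        category = cw$category[i], stringsAsFactors = FALSE)
    }
  }
  long <- unique(do.call(rbind, rows) %||%
                   data.frame(gene_id = character(), genotype = character(),
                              treatment = character(), category = character()))
  counts <- if (nrow(long)) {
    as.data.frame(table(treatment = long$treatment, genotype = long$genotype,
                        category = long$category),
                  responseName = "n", stringsAsFactors = FALSE)
  } else {
    data.frame(treatment = character(), genotype = character(),
               category = character(), n = integer())
  }

  ## per-gene L extracts and trend from the full-course DE fits
  for (i in seq_len(nrow(long))) {
    g <- long$gene_id[i]; geno <- long$genotype[i]; trt <- long$treatment[i]
    cond <- if (trt == "recovery") "preflowering" else trt
    de <- hvgs$de[[paste(cond, "full", sep = "_")]][[geno]]
    if (is.null(de)) next
    L <- trajectory_matrix(de)
    if (!g %in% rownames(L)) next
    wk <- attr(de, "weeks")
    l7 <- if (weeks_focus[1] %in% wk) L[g, which(wk == weeks_focus[1])] else NA_real_
    l14 <- if (length(weeks_focus) > 1 && weeks_focus[2] %in% wk) {
      L[g, which(wk == weeks_focus[2])]
    } else NA_real_
    act <- intersect(windows[[trt]] %||% wk, wk)
    m <- mean(L[g, wk %in% act])
    trend <- if (is.na(m)) NA_character_
             else if (abs(m) < trend_band) "no change"
             else if (m > 0) "increased" else "decreased"
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = g, genotype = geno, treatment = trt,
      category = long$category[i],
      L_week7 = unname(l7), L_week14 = unname(l14),
      mean_L_active = m, trend = trend, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows) %||%
    data.frame(gene_id = character(), genotype = character(),
               treatment = character(), category = character(),
               L_week7 = numeric(), L_week14 = numeric(),
               mean_L_active = numeric(), trend = character())
  structure(list(counts = counts, genes = genes,
                 tissue = hvgs$tissue, trend_band = trend_band),
            class = "cw_summary")
}

#' @export
print.cw_summary <- function(x, ...) {
  cat("cw_summary (", paste(x$tissue, collapse = ","), "): ",
      length(unique(x$genes$gene_id)), " cell-wall HVGs\n", sep = "")
  if (nrow(x$counts)) {
    agg <- stats::aggregate(n ~ treatment + category, x$counts, sum)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
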