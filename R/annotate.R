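# Region-to-gene annotation by TSS proximity and acetylation-expression
# integration.

#' Read a TSS catalog from TSV
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @return Validated tibble.
#' @export
read_tss_catalog <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tbl))) {
    stop("TSS catalog must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl$gene_id)) stop("duplicated gene_id in TSS catalog", call. = FALSE)
  tbl
}

#' Annotate regions to genes within a TSS window
#'
#' Emits one row per (region, gene) pair for which the region overlaps the
#' interval `[tss - window, tss + window]`, i.e. the minimum distance from
#' the TSS to a region base is at most `window`. Strand is ignored for the
#' distance and retained for reporting. A gene may link to several regions
#' and vice versa.
#'
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`
#'   and (optionally) a `direction` column.
#' @param tss TSS catalog tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window Half-window in bp around each TSS (default 20000).
#' @return Tibble `region_id`, `gene_id`, `distance`, `region_direction`,
#'   `strand`; `distance` is 0 when the TSS lies inside the region.
#' @export
annotate_regions <- function(regions, tss, window = 20000) {
  assert_regions(regions)
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  regions <- regions[order(regions$chrom, regions$start), ]
  n_skipped <- sum(!tss$chrom %in% unique(regions$chrom))
  if (n_skipped > 0) {
    message(n_skipped, " TSS on chromosomes absent from the region set were skipped")
  }
  # region [a,b) is linked iff a <= tss + window and b >= tss - window;
  # expressed as a half-open overlap query with the window widened by 1.
  q <- tibble::tibble(chrom = tss$chrom,
                      start = tss$tss - window - 1,
                      end = tss$tss + window + 1)
  pairs <- overlap_join(q, regions)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(region_id = character(), gene_id = character(),
                          distance = integer(), region_direction = character(),
                          strand = character()))
  }
  t_pos <- tss$tss[pairs$query_idx]
  a <- regions$start[pairs$subject_idx]
  b <- regions$end[pairs$subject_idx]
  distance <- pmax(pmax(a - t_pos, t_pos - b), 0)
  dir <- if ("direction" %in% names(regions)) {
    regions$direction[pairs$subject_idx]
  } else {
    NA_character_
  }
  out <- tibble::tibble(
    region_id = regions$region_id[pairs$subject_idx],
    gene_id = tss$gene_id[pairs$query_idx],
    distance = as.integer(distance),
    region_direction = dir,
    strand = tss$strand[pairs$query_idx]
  )
  out[order(out$region_id, out$gene_id), ]
}

#' Gene sets near hyper- and hypoacetylated regions
#'
#' Deduplicated gene ids linked to regions of each direction. Genes near
#' both a hyper and a hypo region are kept in both sets and listed in
#' `conflicts`.
#'
#' @param links Output of [annotate_regions()] with `region_direction` set
#'   (typically from regions carrying [call_differential()] calls).
#' @param labels Direction labels, positive first (default
#'   `c("hyper", "hypo")`).
#' @return List with sorted character vectors `genes_near_hyper`,
#'   `genes_near_hypo`, `conflicts`.
#' @export
annotated_gene_sets <- function(links, labels = c("hyper", "hypo")) {
  hyper <- sort(unique(links$gene_id[links$region_direction %in% labels[1]]))
  hypo <- sort(unique(links$gene_id[links$region_direction %in% labels[2]]))
  conflicts <- intersect(hyper, hypo)
  if (length(conflicts) > 0) {
    message(length(conflicts), " gene(s) linked to both hyper and hypo regions")
  }
  list(genes_near_hyper = hyper, genes_near_hypo = hypo, conflicts = conflicts)
}

#' Acetylation-expression direction concordance
#'
#' Compares the expression log2 fold-change distribution of genes near
#' hyperacetylated and near hypoacetylated regions with that of all genes,
#' by one-sided Wilcoxon rank-sum tests in the expected direction (near
#' hyper shifted up; near hypo shifted down).
#'
#' @param gene_sets Output of [annotated_gene_sets()].
#' @param rna Tidy RNA differential results (`feature_id`, `log2fc`); genes
#'   in a set but absent from `rna` are excluded with a message.
#' @return Object of class `concordance_result`: `$summary` tibble (class,
#'   n, median_lfc, p) and `$data` long tibble of per-gene fold changes.
#' @export
concordance_analysis <- function(gene_sets, rna) {
  stopifnot(all(c("feature_id", "log2fc") %in% names(rna)))
  all_lfc <- rna$log2fc[!is.na(rna$log2fc)]
  pick <- function(genes) {
    miss <- setdiff(genes, rna$feature_id)
    if (length(miss) > 0) {
      message(length(miss), " linked gene(s) absent from RNA results were excluded")
    }
    rna$log2fc[match(intersect(genes, rna$feature_id), rna$feature_id)]
  }
  hyper_lfc <- pick(gene_sets$genes_near_hyper)
  hypo_lfc <- pick(gene_sets$genes_near_hypo)
  test <- function(v, alternative) {
    if (length(v) == 0) return(NA_real_)
    suppressWarnings(wilcox.test(v, all_lfc, alternative = alternative)$p.value)
  }
  summary <- tibble::tibble(
    class = c("all", "near_hyper", "near_hypo"),
    n = c(length(all_lfc), length(hyper_lfc), length(hypo_lfc)),
    median_lfc = c(median(all_lfc),
                   if (length(hyper_lfc)) median(hyper_lfc) else NA_real_,
                   if (length(hypo_lfc)) median(hypo_lfc) else NA_real_),
    p = c(NA_real_, test(hyper_lfc, "greater"), test(hypo_lfc, "less"))
  )
  data <- dplyr::bind_rows(
    tibble::tibble(class = "all", log2fc = all_lfc),
    tibble::tibble(class = "near_hyper", log2fc = hyper_lfc),
    tibble::tibble(class = "near_hypo", log2fc = hypo_lfc)
  )
  structure(list(summary = summary, data = data), class = "concordance_result")
}

#' @export
tidy.concordance_result <- function(x, ...) x$summary

#' @export
print.concordance_result <- function(x, ...) {
  cat("Acetylation-expression concordance\n")
  print(x$summary)
  invisible(x)
}

#' Fold-change distributions by annotation class
#'
#' @param object `concordance_result` object.
#' @param ... Unused.
#' @return A ggplot object (boxplots of expression log2FC per class).
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$class, y = .data$log2fc,
                               fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "expression log2 fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Overlap of annotated gene sets with differential expression calls
#'
#' Intersects genes near hyperacetylated regions with upregulated genes and
#' genes near hypoacetylated regions with downregulated genes.
#'
#' @param gene_sets Output of [annotated_gene_sets()].
#' @param rna_calls RNA results tibble with `feature_id` and `direction`
#'   (labels `up` / `down` / `ns`).
#' @return List of sorted character vectors `hyper_and_up`, `hypo_and_down`.
#' @export
overlap_gene_lists <- function(gene_sets, rna_calls) {
  stopifnot(all(c("feature_id", "direction") %in% names(rna_calls)))
  up <- rna_calls$feature_id[rna_calls$direction == "up"]
  down <- rna_calls$feature_id[rna_calls$direction == "down"]
  list(hyper_and_up = sort(intersect(gene_sets$genes_near_hyper, up)),
       hypo_and_down = sort(intersect(gene_sets$genes_near_hypo, down)))
}
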