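# End-to-end orchestration: consensus construction, differential testing of
# both arms, exploratory structure, annotation/integration and motif
# enrichment, with TSV outputs, a summary table and a checksum MANIFEST.

#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. The
#' path layout matches what [simulate_inputs()] writes; any input may also
#' be supplied explicitly.
#'
#' @param input_dir Directory holding the inputs (as written by
#'   [simulate_inputs()]); individual paths below override the defaults
#'   derived from it.
#' @param peaks Named character vector of peak BED paths.
#' @param chrom_sizes,chip_counts,rna_counts,tss,groups,motifs,name_map
#'   Input file paths.
#' @param sequences Named list per direction:
#'   `list(hyper = c(fg=, bg=), hypo = c(fg=, bg=))`; `NULL` entries skip
#'   motif analysis for that direction.
#' @param outdir Output directory.
#' @param min_len,min_support Consensus parameters (defaults 2000 bp, 2
#'   samples).
#' @param window TSS annotation window in bp (default 20000).
#' @param alpha Significance threshold (default 0.05).
#' @param use_padj Use BH-adjusted p for calls (default TRUE).
#' @param n_top_pca Top-variable regions used for PCA (default 500).
#' @param score_fraction Motif hit threshold (default 0.8).
#' @param autosomes Chromosome allowlist (default `chr1`..`chr22`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, peaks = NULL, chrom_sizes = NULL,
                            chip_counts = NULL, rna_counts = NULL, tss = NULL,
                            groups = NULL, motifs = NULL, name_map = NULL,
                            sequences = NULL, outdir = tempfile("diffacet_out_"),
                            min_len = 2000, min_support = 2, window = 20000,
                            alpha = 0.05, use_padj = TRUE, n_top_pca = 500,
                            score_fraction = 0.8,
                            autosomes = paste0("chr", 1:22)) {
  pick <- function(x, default) if (!is.null(x)) x else default
  if (!is.null(input_dir)) {
    bed <- list.files(file.path(input_dir, "peaks"), pattern = "\\.bed$",
                      full.names = TRUE)
    names(bed) <- sub("\\.bed$", "", basename(bed))
    peaks <- pick(peaks, bed)
    chrom_sizes <- pick(chrom_sizes, file.path(input_dir, "chrom_sizes.tsv"))
    chip_counts <- pick(chip_counts, file.path(input_dir, "chip_counts.tsv"))
    rna_counts <- pick(rna_counts, file.path(input_dir, "rna_counts.tsv"))
    tss <- pick(tss, file.path(input_dir, "tss.tsv"))
    groups <- pick(groups, file.path(input_dir, "groups.tsv"))
    motifs <- pick(motifs, file.path(input_dir, "motifs.meme"))
    name_map <- pick(name_map, file.path(input_dir, "motif_gene_map.tsv"))
    if (is.null(sequences)) {
      sequences <- list()
      for (d in c("hyper", "hypo")) {
        fgp <- file.path(input_dir, paste0("fg_", d, ".fa"))
        bgp <- file.path(input_dir, paste0("bg_", d, ".fa"))
        if (file.exists(fgp) && file.exists(bgp)) {
          sequences[[d]] <- c(fg = fgp, bg = bgp)
        }
      }
    }
  }
  existing <- c(unlist(peaks), chrom_sizes, chip_counts, rna_counts, tss,
                groups, motifs, name_map, unlist(sequences))
  missing <- existing[!is.null(existing) & !file.exists(existing)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, min_len > 0, min_support >= 1, window >= 0,
            score_fraction > 0, score_fraction <= 1)
  structure(list(peaks = peaks, chrom_sizes = chrom_sizes,
                 chip_counts = chip_counts, rna_counts = rna_counts,
                 tss = tss, groups = groups, motifs = motifs,
                 name_map = name_map, sequences = sequences, outdir = outdir,
                 min_len = min_len, min_support = min_support,
                 window = window, alpha = alpha, use_padj = use_padj,
                 n_top_pca = n_top_pca, score_fraction = score_fraction,
                 autosomes = autosomes),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes consensus construction from peak calls, count loading,
#' differential acetylation and expression testing, exploratory structure
#' (normalized matrix, sample clustering on differential regions, PCA of
#' top-variable regions, Manhattan table), TSS-window annotation,
#' acetylation-expression concordance, overlap gene lists, per-direction
#' motif enrichment and TF linkage. All tables are written as TSV under
#' `config$outdir` together with a `summary.tsv` of headline counts and a
#' `MANIFEST.tsv` of output checksums. Stages whose inputs are absent (RNA
#' arm, motif arm) are skipped and marked in the summary.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list with all stage results and the `summary` tibble.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[diffacet] ", ...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  chrom_sizes <- stage("inputs", readr::read_tsv(config$chrom_sizes,
                                                 show_col_types = FALSE))
  groups <- stage("inputs", readr::read_tsv(config$groups, show_col_types = FALSE))

  say("building consensus regions from ", length(config$peaks), " peak sets")
  consensus <- stage("consensus", build_consensus(
    config$peaks, chrom_sizes, min_len = config$min_len,
    min_support = config$min_support, autosomes = config$autosomes))
  res$consensus <- consensus
  write_bed(consensus, file.path(config$outdir, "consensus.bed"))

  say("differential acetylation on ", nrow(consensus), " regions")
  chip_counts <- stage("counts", load_count_matrix(config$chip_counts, groups))
  chip_fit <- stage("diff-chip", nb_wald_test(chip_counts, groups))
  chip_res <- call_differential(chip_fit, threshold = config$alpha,
                                use_padj = config$use_padj,
                                labels = c("hyper", "hypo"))
  res$chip_fit <- chip_fit
  res$chip_results <- chip_res
  readr::write_tsv(chip_res, file.path(config$outdir, "chip_differential.tsv"))

  say("exploratory structure")
  norm <- stage("explore", normalize_for_visualization(chip_counts))
  readr::write_tsv(norm, file.path(config$outdir, "normalized_matrix.tsv"))
  diff_ids <- chip_res$feature_id[chip_res$direction != "ns"]
  clust <- if (length(diff_ids) >= 1) {
    hierarchical_cluster(norm[norm$feature_id %in% diff_ids, ])
  } else {
    NULL
  }
  res$clustering <- clust
  pca <- stage("explore", pca_top_variable(
    norm, n_top = min(config$n_top_pca, nrow(norm))))
  res$pca <- pca
  readr::write_tsv(pca$scores, file.path(config$outdir, "pca_scores.tsv"))
  res$outliers <- detect_outlier_samples(pca, groups)
  reg_for_man <- consensus[consensus$region_id %in% chip_res$feature_id, ]
  man <- stage("explore", manhattan_table(chip_res, reg_for_man, chrom_sizes))
  res$manhattan <- man
  readr::write_tsv(man, file.path(config$outdir, "manhattan.tsv"))

  has_rna <- !is.null(config$rna_counts)
  rna_res <- NULL
  if (has_rna) {
    say("differential expression")
    rna_counts <- stage("counts", load_count_matrix(config$rna_counts, groups))
    rna_fit <- stage("diff-rna", nb_wald_test(rna_counts, groups))
    rna_res <- call_differential(rna_fit, threshold = config$alpha,
                                 use_padj = TRUE, labels = c("up", "down"))
    res$rna_fit <- rna_fit
    res$rna_results <- rna_res
    readr::write_tsv(rna_res, file.path(config$outdir, "rna_differential.tsv"))
  }

  say("annotating regions within ", config$window, " bp of a TSS")
  tss <- stage("annotate", read_tss_catalog(config$tss))
  diff_regions <- dplyr::left_join(consensus,
                                   chip_res[, c("feature_id", "direction")],
                                   by = c(region_id = "feature_id"))
  diff_regions <- diff_regions[!is.na(diff_regions$direction) &
                                 diff_regions$direction != "ns", ]
  links <- stage("annotate", annotate_regions(diff_regions, tss,
                                              window = config$window))
  res$links <- links
  readr::write_tsv(links, file.path(config$outdir, "region_gene_links.tsv"))
  gene_sets <- annotated_gene_sets(links)
  res$gene_sets <- gene_sets

  if (has_rna) {
    say("acetylation-expression integration")
    res$concordance <- stage("integrate", concordance_analysis(gene_sets, rna_res))
    readr::write_tsv(res$concordance$summary,
                     file.path(config$outdir, "concordance.tsv"))
    res$overlap <- overlap_gene_lists(gene_sets, rna_res)
    readr::write_tsv(
      tibble::tibble(
        gene_id = c(res$overlap$hyper_and_up, res$overlap$hypo_and_down),
        class = rep(c("hyper_and_up", "hypo_and_down"),
                    c(length(res$overlap$hyper_and_up),
                      length(res$overlap$hypo_and_down)))),
      file.path(config$outdir, "overlap_genes.tsv"))
  }

  has_motifs <- !is.null(config$motifs) && length(config$sequences) > 0
  if (has_motifs) {
    say("motif enrichment")
    pwms <- stage("motifs", read_meme(config$motifs))
    enr <- list()
    for (d in names(config$sequences)) {
      enr[[d]] <- stage("motifs", enrichment_test(
        pwms, config$sequences[[d]][["fg"]], config$sequences[[d]][["bg"]],
        score_fraction = config$score_fraction))
      readr::write_tsv(enr[[d]],
                       file.path(config$outdir, paste0("motif_enrichment_", d, ".tsv")))
    }
    res$enrichment <- enr
    if (has_rna && !is.null(config$name_map)) {
      nm <- readr::read_tsv(config$name_map, show_col_types = FALSE)
      res$tf_links <- stage("motifs", link_motifs_to_de_tfs(
        enr, rna_res, nm, threshold = config$alpha))
      readr::write_tsv(res$tf_links, file.path(config$outdir, "tf_links.tsv"))
    }
  }

  cnt <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  enr_count <- function(d) {
    if (is.null(res$enrichment[[d]])) return(NA_integer_)
    sum(res$enrichment[[d]]$padj < config$alpha, na.rm = TRUE)
  }
  summary <- tibble::tibble(
    metric = c("consensus_regions", "differential_regions", "hyper_regions",
               "hypo_regions", "genes_up", "genes_down", "genes_near_hyper",
               "genes_near_hypo", "overlap_hyper_up", "overlap_hypo_down",
               "enriched_motifs_hyper", "enriched_motifs_hypo",
               "linked_tfs_up", "linked_tfs_down"),
    value = c(nrow(consensus),
              sum(chip_res$direction != "ns"),
              sum(chip_res$direction == "hyper"),
              sum(chip_res$direction == "hypo"),
              cnt(if (has_rna) sum(rna_res$direction == "up")),
              cnt(if (has_rna) sum(rna_res$direction == "down")),
              length(gene_sets$genes_near_hyper),
              length(gene_sets$genes_near_hypo),
              cnt(if (has_rna) length(res$overlap$hyper_and_up)),
              cnt(if (has_rna) length(res$overlap$hypo_and_down)),
              enr_count("hyper"), enr_count("hypo"),
              cnt(if (!is.null(res$tf_links))
                sum(res$tf_links$gene_direction == "up")),
              cnt(if (!is.null(res$tf_links))
                sum(res$tf_links$gene_direction == "down")))
  )
  res$summary <- summary
  readr::write_tsv(summary, file.path(config$outdir, "summary.tsv"))

  files <- sort(setdiff(list.files(config$outdir, recursive = TRUE),
                        "MANIFEST.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files)))
  )
  readr::write_tsv(manifest, file.path(config$outdir, "MANIFEST.tsv"))
  res$manifest <- manifest
  say("done: ", nrow(manifest), " output files in ", config$outdir)
  invisible(res)
}
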