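# Exploratory structure: visualization normalization, clustering, PCA,
# Manhattan-plot data, outlier flagging.

#' Quantile-normalize a count or signal table
#'
#' Each column's sorted values are replaced by the row-wise means of the
#' column-sorted values. With the default `ties = "order"`, tied values are
#' assigned target values in their (stable) sort order, so after
#' normalization every column holds exactly the same multiset of values and
#' the transform is idempotent. With `ties = "mean"`, tied values within a
#' column instead all receive the mean of their tied target values (equal
#' inputs map to equal outputs, at the price of exact multiset identity on
#' discrete data).
#'
#' @param x Wide tibble (`feature_id` + numeric sample columns) or matrix.
#' @param ties Tie handling, `"order"` (default) or `"mean"`.
#' @return Object of the same shape with normalized values.
#' @export
quantile_normalize <- function(x, ties = c("order", "mean")) {
  ties <- match.arg(ties)
  tbl <- is.data.frame(x)
  m <- if (tbl) cm_matrix(x) else as.matrix(x)
  if (length(m) == 0) stop("empty matrix", call. = FALSE)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 columns", call. = FALSE)
  qn <- limma::normalizeQuantiles(m, ties = (ties == "mean"))
  dimnames(qn) <- dimnames(m)
  if (!tbl) return(qn)
  out <- x
  out[, -1] <- tibble::as_tibble(qn)
  out
}

#' Log2 transform with pseudocount
#'
#' `log2(x + pseudo)`; the default pseudocount of one read per region avoids
#' taking logs of zero.
#'
#' @param x Wide tibble or matrix of non-negative values.
#' @param pseudo Pseudocount (default 1).
#' @return Same shape, transformed.
#' @export
log2_pseudocount <- function(x, pseudo = 1) {
  tbl <- is.data.frame(x)
  m <- if (tbl) cm_matrix(x) else as.matrix(x)
  if (length(m) && any(m < 0)) stop("negative values not allowed", call. = FALSE)
  lm2 <- log2(m + pseudo)
  if (!tbl) return(lm2)
  out <- x
  out[, -1] <- tibble::as_tibble(lm2)
  out
}

#' Median-center rows
#'
#' Subtracts each row's median; with an odd number of samples every row
#' median becomes exactly zero.
#'
#' @param x Wide tibble or matrix.
#' @return Same shape, row-centered.
#' @export
median_center_rows <- function(x) {
  tbl <- is.data.frame(x)
  m <- if (tbl) cm_matrix(x) else as.matrix(x)
  cen <- m - apply(m, 1, median)
  if (!tbl) return(cen)
  out <- x
  out[, -1] <- tibble::as_tibble(cen)
  out
}

#' Visualization normalization pipeline
#'
#' Quantile normalization, then `log2(x + pseudo)`, then row median-centering
#' (in that order).
#'
#' @param counts Wide count tibble.
#' @param pseudo Pseudocount added before the log (default 1).
#' @return Normalized wide tibble.
#' @export
normalize_for_visualization <- function(counts, pseudo = 1) {
  counts |>
    quantile_normalize() |>
    log2_pseudocount(pseudo = pseudo) |>
    median_center_rows()
}

#' Hierarchical clustering of samples
#'
#' Deterministic agglomerative clustering of sample columns.
#'
#' @param x Wide tibble (features in rows) or matrix.
#' @param linkage Agglomeration method (default `"average"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @return List with the `hclust` tree and `leaf_order` (sample ids).
#' @export
hierarchical_cluster <- function(x, linkage = "average", metric = "euclidean") {
  m <- if (is.data.frame(x)) cm_matrix(x) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  tree <- hclust(dist(t(m), method = metric), method = linkage)
  list(tree = tree, leaf_order = colnames(m)[tree$order])
}

#' Cut a sample dendrogram into k clusters
#'
#' @param clustering Output of [hierarchical_cluster()].
#' @param k Number of clusters (default 2).
#' @return Tibble `sample`, `cluster`.
#' @export
cut_sample_tree <- function(clustering, k = 2) {
  cl <- cutree(clustering$tree, k = k)
  tibble::tibble(sample = names(cl), cluster = unname(cl))
}

#' PCA of the top-variable features
#'
#' Features are ranked by across-sample variance, the top `n_top` retained
#' (all features, with a warning, when fewer are available), rows centered,
#' and sample scores computed by SVD.
#'
#' @param x Wide tibble or matrix (features in rows).
#' @param n_top Number of most-variable features to use (default 500).
#' @return Object of class `chip_pca` with `$scores` (tibble `sample`,
#'   `PC1`, `PC2`, ...), `$var_explained`, `$n_features_used`.
#' @export
pca_top_variable <- function(x, n_top = 500) {
  m <- if (is.data.frame(x)) cm_matrix(x) else as.matrix(x)
  v <- apply(m, 1, var)
  if (all(v == 0)) stop("matrix has no variance", call. = FALSE)
  if (nrow(m) < n_top) {
    warning("only ", nrow(m), " features available (< n_top = ", n_top, "); using all",
            call. = FALSE)
    n_top <- nrow(m)
  }
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  sub <- m[keep, , drop = FALSE]
  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(sample = colnames(m)), scores)
  structure(list(scores = scores, var_explained = ve,
                 n_features_used = n_top),
            class = "chip_pca")
}

#' @export
tidy.chip_pca <- function(x, ...) x$scores

#' @export
glance.chip_pca <- function(x, ...) {
  tibble::tibble(n_features_used = x$n_features_used,
                 pc1_var = x$var_explained[1],
                 pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' PCA score plot
#'
#' @param object `chip_pca` object.
#' @param groups Optional data frame `sample`, `group` for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chip_pca <- function(object, groups = NULL, ...) {
  d <- object$scores
  if (!is.null(groups)) {
    d <- dplyr::left_join(d, groups, by = "sample")
  } else {
    d$group <- "sample"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan-plot table
#'
#' One row per region with a genome-cumulative x-coordinate, `-log10(p)` and
#' the direction class (`ns` / positive / negative labels as supplied by
#' [call_differential()]).
#'
#' @param results Differential results tibble with `feature_id`, `p`,
#'   `direction`.
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @param chrom_sizes Tibble `chrom`, `length` (defines chromosome order and
#'   cumulative offsets).
#' @return Tibble `region_id`, `chrom`, `midpoint`, `x_cum`, `neg_log10_p`,
#'   `direction`.
#' @export
manhattan_table <- function(results, regions, chrom_sizes) {
  stopifnot(all(c("feature_id", "p") %in% names(results)))
  idx <- match(regions$region_id, results$feature_id)
  if (anyNA(idx)) {
    stop("region(s) without a differential result: ",
         paste(head(regions$region_id[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  offsets <- c(0, cumsum(as.numeric(chrom_sizes$length)))[seq_len(nrow(chrom_sizes))]
  names(offsets) <- chrom_sizes$chrom
  mid <- (regions$start + regions$end) %/% 2
  tibble::tibble(
    region_id = regions$region_id,
    chrom = regions$chrom,
    midpoint = mid,
    x_cum = unname(offsets[regions$chrom]) + mid,
    neg_log10_p = -log10(pmax(results$p[idx], .Machine$double.xmin)),
    direction = if ("direction" %in% names(results)) results$direction[idx] else "ns"
  )
}

#' Manhattan plot
#'
#' @param tbl Output of [manhattan_table()].
#' @param colours Named colours for the direction classes.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(tbl, colours = c(ns = "black", hyper = "green4",
                                            hypo = "red3")) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x_cum, y = .data$neg_log10_p,
                                    colour = .data$direction)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = colours) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Flag outlier samples on the first two principal components
#'
#' A sample is flagged when its PC1 or PC2 score deviates from its group mean
#' by more than `k_sd` robust standard deviations (MAD-based). Reporting
#' only; exclusion is left to the user.
#'
#' @param pca `chip_pca` object.
#' @param groups Optional data frame `sample`, `group`; without it all
#'   samples form one group.
#' @param k_sd Flagging threshold in robust SDs (default 3).
#' @return Tibble `sample`, `pc`, `score`, `robust_z`, `flagged`.
#' @export
detect_outlier_samples <- function(pca, groups = NULL, k_sd = 3) {
  sc <- pca$scores
  pcs <- intersect(c("PC1", "PC2"), names(sc))
  grp <- if (is.null(groups)) rep("all", nrow(sc)) else
    as.character(groups$group[match(sc$sample, groups$sample)])
  out <- list()
  for (pc in pcs) {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      v <- sc[[pc]][idx]
      s <- mad(v)
      rz <- if (s > 0) abs(v - mean(v)) / s else rep(0, length(v))
      out[[length(out) + 1]] <- tibble::tibble(
        sample = sc$sample[idx], pc = pc, score = v,
        robust_z = rz, flagged = rz > k_sd
      )
    }
  }
  dplyr::bind_rows(out)
}
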