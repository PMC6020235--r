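#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with strictly positive counts in every sample) of the ratio of
#' the feature's count to its across-sample geometric mean. This is the
#' normalization used throughout the differential engine.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  assert_count_tbl(counts)
  m <- cm_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no feature has positive counts in all samples; ",
         "filter features or supply size factors", call. = FALSE)
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Moment-based, trend-moderated NB dispersions
#'
#' Per-feature method-of-moments dispersion on normalized counts,
#' `alpha_i = max((var_i - mean_i) / mean_i^2, 1e-8)`, where `var_i` is the
#' within-group pooled variance; a mean-dispersion trend
#' `alpha = a0 + a1 / mean` is fitted by least squares across features, and
#' the final estimate shrinks the per-feature value halfway to the trend
#' (`weight` controls the shrinkage).
#'
#' @param counts Wide count tibble.
#' @param size_factors Tibble `sample`, `size_factor` (default: estimated).
#' @param groups Data frame `sample`, `group` (two groups).
#' @param weight Moderation weight on the trend in `[0, 1]` (default 0.5).
#' @return Tibble `feature_id`, `mean`, `alpha_mom`, `alpha_trend`, `alpha`.
#' @export
estimate_dispersions <- function(counts, groups, size_factors = NULL, weight = 0.5) {
  assert_count_tbl(counts)
  assert_groups(groups, samples = names(counts)[-1])
  if (ncol(counts) - 1 < 3) stop("dispersion needs at least 3 samples", call. = FALSE)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  m <- cm_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  k <- sweep(m, 2, sf, "/")
  grp <- groups$group[match(colnames(m), groups$sample)]
  mu <- rowMeans(k)
  ss <- 0
  df <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    gm <- rowMeans(k[, idx, drop = FALSE])
    ss <- ss + rowSums((k[, idx, drop = FALSE] - gm)^2)
    df <- df + (length(idx) - 1)
  }
  if (df == 0) stop("need at least one group with >= 2 samples", call. = FALSE)
  v <- ss / df
  floor_a <- 1e-8
  a_mom <- ifelse(mu > 0, pmax((v - mu) / mu^2, floor_a), floor_a)
  ok <- mu > 0 & is.finite(a_mom)
  if (sum(ok) >= 3 && var(1 / mu[ok]) > 0) {
    fit <- lm(a_mom[ok] ~ I(1 / mu[ok]))
    a0 <- coef(fit)[1]
    a1 <- coef(fit)[2]
  } else {
    a0 <- mean(a_mom[ok])
    a1 <- 0
  }
  a_trend <- ifelse(mu > 0, pmax(a0 + a1 / mu, floor_a), floor_a)
  alpha <- pmax((1 - weight) * a_mom + weight * a_trend, floor_a)
  tibble::tibble(feature_id = rownames(m), mean = unname(mu),
                 alpha_mom = unname(a_mom), alpha_trend = unname(a_trend),
                 alpha = unname(alpha))
}

# Vectorized per-feature IRLS for the two-group NB GLM with log link and
# log size-factor offsets, dispersion fixed per feature. Returns beta (log
# scale), se of the group coefficient, and a convergence flag.
nb_irls <- function(y, sf, x, alpha, max_iter = 100, tol = 1e-8) {
  nf <- nrow(y)
  ns <- ncol(y)
  off <- matrix(log(sf), nf, ns, byrow = TRUE)
  k <- sweep(y, 2, sf, "/")
  m0 <- rowMeans(k[, x == 0, drop = FALSE])
  m1 <- rowMeans(k[, x == 1, drop = FALSE])
  b0 <- log(pmax(m0, 1e-3))
  b1 <- log(pmax(m1, 1e-3)) - b0
  converged <- rep(FALSE, nf)
  xr <- matrix(x, nf, ns, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xr + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    A <- rowSums(w)
    B <- rowSums(w * xr)
    C <- rowSums(w * xr * xr)
    Sy <- rowSums(w * z)
    Sxy <- rowSums(w * xr * z)
    det <- A * C - B * B
    det[det <= 0 | !is.finite(det)] <- NA_real_
    nb0 <- (C * Sy - B * Sxy) / det
    nb1 <- (A * Sxy - B * Sy) / det
    step_ok <- is.finite(nb0) & is.finite(nb1)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    newly <- step_ok & !converged & delta < tol
    upd <- step_ok & !converged
    b0[upd] <- nb0[upd]
    b1[upd] <- nb1[upd]
    converged <- converged | newly
    if (all(converged | !step_ok)) break
  }
  # standard error of the group coefficient from the observed Fisher
  # information at the converged estimate
  eta <- pmin(pmax(b0 + b1 * xr + off, -30), 30)
  mu <- exp(eta)
  w <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  A <- rowSums(w)
  B <- rowSums(w * xr)
  C <- rowSums(w * xr * xr)
  det <- A * C - B * B
  se <- sqrt(ifelse(det > 0, A / det, NA_real_))
  list(b0 = b0, b1 = b1, se = se, converged = converged)
}

#' Negative-binomial Wald test for a two-group design
#'
#' Fits, per feature, a negative-binomial GLM with log link on the design
#' `intercept + group indicator` with log size-factor offsets and fixed
#' (moderated) dispersion, by iteratively reweighted least squares. The Wald
#' statistic is the group coefficient divided by its standard error from the
#' Fisher information, referred to a standard normal (two-sided). No fold-
#' change shrinkage is applied. Features with zero counts in every sample are
#' dropped before testing; non-converged fits get `p = NA` and are excluded
#' from the Benjamini-Hochberg denominator.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param groups Data frame `sample`, `group`; `reference` names the baseline
#'   level so `log2fc` is the other group versus the reference.
#' @param reference Reference (control) group label (default `"control"`).
#' @param size_factors Optional precomputed size factors.
#' @param dispersions Optional precomputed dispersion tibble.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class `nb_diff`; see [tidy()] for the per-feature
#'   table (`feature_id`, `base_mean`, `log2fc`, `se`, `wald_z`, `p`, `padj`).
#' @export
nb_wald_test <- function(counts, groups, reference = "control",
                         size_factors = NULL, dispersions = NULL,
                         max_iter = 100, tol = 1e-8) {
  assert_count_tbl(counts)
  assert_groups(groups, samples = names(counts)[-1])
  m <- cm_matrix(counts)
  grp <- as.character(groups$group[match(colnames(m), groups$sample)])
  lev <- unique(grp)
  if (length(lev) != 2) stop("exactly two groups are required", call. = FALSE)
  if (!reference %in% lev) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  if (min(table(grp)) < 2) stop("both groups need >= 2 samples", call. = FALSE)
  nonzero <- rowSums(m) > 0
  n_dropped <- sum(!nonzero)
  if (n_dropped > 0) {
    message(n_dropped, " all-zero feature(s) dropped before testing")
  }
  counts_nz <- counts[nonzero, , drop = FALSE]
  m <- m[nonzero, , drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts_nz)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts_nz, groups, size_factors)
  }
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  alpha <- dispersions$alpha[match(rownames(m), dispersions$feature_id)]
  x <- as.numeric(grp != reference)
  fit <- nb_irls(m, sf, x, alpha, max_iter = max_iter, tol = tol)
  log2fc <- fit$b1 / log(2)
  se2 <- fit$se / log(2)
  z <- log2fc / se2
  p <- 2 * pnorm(-abs(z))
  p[!fit$converged | !is.finite(z)] <- NA_real_
  res <- tibble::tibble(
    feature_id = rownames(m),
    base_mean = rowMeans(sweep(m, 2, sf, "/")),
    log2fc = unname(log2fc),
    se = unname(se2),
    wald_z = unname(z),
    p = unname(p),
    padj = bh_adjust(unname(p))
  )
  structure(list(results = res, size_factors = size_factors,
                 dispersions = dispersions, reference = reference,
                 groups = tibble::tibble(sample = colnames(m), group = grp),
                 n_dropped = n_dropped,
                 n_nonconverged = sum(!fit$converged)),
            class = "nb_diff")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. `NA` p-values are propagated and
#' excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differential features by direction
#'
#' Adds a `direction` column: the positive label when significant with
#' `log2fc > 0`, the negative label when significant with `log2fc < 0`,
#' `"ns"` otherwise. Significance uses the adjusted p-value by default.
#'
#' @param results `nb_diff` object or tidy results tibble.
#' @param threshold Significance threshold (default 0.05).
#' @param use_padj Use `padj` (default) rather than raw `p`.
#' @param labels Length-2 labels for positive/negative calls
#'   (e.g. `c("hyper", "hypo")` for acetylation, `c("up", "down")` for RNA).
#' @return Results tibble with a `direction` column.
#' @export
call_differential <- function(results, threshold = 0.05, use_padj = TRUE,
                              labels = c("up", "down")) {
  if (inherits(results, "nb_diff")) results <- results$results
  stopifnot(all(c("log2fc", "p", "padj") %in% names(results)))
  crit <- if (use_padj) results$padj else results$p
  sig <- !is.na(crit) & crit < threshold
  results$direction <- dplyr::case_when(
    sig & results$log2fc > 0 ~ labels[1],
    sig & results$log2fc < 0 ~ labels[2],
    .default = "ns"
  )
  results
}

#' @export
tidy.nb_diff <- function(x, ...) x$results

#' @export
glance.nb_diff <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_features = nrow(r) + x$n_dropped,
    n_tested = sum(!is.na(r$p)),
    n_dropped = x$n_dropped,
    n_nonconverged = x$n_nonconverged,
    n_sig_padj_05 = sum(r$padj < 0.05, na.rm = TRUE),
    median_dispersion = median(x$dispersions$alpha)
  )
}

#' @export
print.nb_diff <- function(x, ...) {
  cat("Negative-binomial Wald test (", nrow(x$results), " features, ",
      nrow(x$groups), " samples; reference = ", x$reference, ")\n", sep = "")
  cat(" significant at padj < 0.05: ",
      sum(x$results$padj < 0.05, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' MA plot of a differential result
#'
#' @param object `nb_diff` object.
#' @param threshold Adjusted-p threshold used for colouring (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_diff <- function(object, threshold = 0.05, ...) {
  d <- object$results
  d$significant <- !is.na(d$padj) & d$padj < threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$base_mean, y = .data$log2fc,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change") +
    ggplot2::theme_minimal()
}
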