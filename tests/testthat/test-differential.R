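groups9 <- tibble::tibble(
  sample = c(paste0("case_", 1:5), paste0("control_", 1:4)),
  group = rep(c("case", "control"), c(5, 4))
)

sim_cm <- function(n, mu, lfc = 0, alpha = 0.05, sf = rep(1, 9), seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(feature_id = sprintf("f%05d", seq_len(n)))
  mu <- rep_len(mu, n)
  lfc <- rep_len(lfc, n)
  for (j in seq_len(9)) {
    m <- mu * sf[j] * 2^(lfc * (j <= 5))
    out[[groups9$sample[j]]] <- as.integer(rnbinom(n, mu = m, size = 1 / alpha))
  }
  out
}

test_that("size factors follow the median-of-ratios definition", {
  cm <- tibble::tibble(feature_id = c("a", "b", "c"),
                       s1 = c(5L, 9L, 12L), s2 = c(5L, 9L, 12L))
  expect_equal(estimate_size_factors(cm)$size_factor, c(1, 1))

  cm <- tibble::tibble(feature_id = c("a", "b", "c"),
                       s1 = c(2L, 4L, 6L), s2 = c(4L, 8L, 12L))
  expect_equal(estimate_size_factors(cm)$size_factor,
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # doubling one column doubles its size factor relative to the others
  cm2 <- cm
  cm2$s2 <- cm2$s2 * 2L
  sf <- estimate_size_factors(cm)$size_factor
  sf2 <- estimate_size_factors(cm2)$size_factor
  expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 2, tolerance = 1e-12)

  zero <- tibble::tibble(feature_id = c("a", "b"), s1 = c(0L, 3L), s2 = c(2L, 0L))
  expect_error(estimate_size_factors(zero), "positive counts")
})

test_that("dispersion estimation floors constants and tracks the truth", {
  cm <- sim_cm(200, mu = 100, alpha = 0.05, seed = 2)
  cm[1, -1] <- as.list(rep(50L, 9))  # constant feature: zero variance
  d <- estimate_dispersions(cm, groups9)
  expect_equal(d$alpha_mom[1], 1e-8)

  # Poisson data: moderated alpha near zero at high means
  cmp <- sim_cm(5000, mu = 150, alpha = 1e-8, seed = 3)
  dp <- estimate_dispersions(cmp, groups9)
  expect_lte(median(dp$alpha), 0.01)

  # NB alpha = 0.05 recovered within the stated band
  cmn <- sim_cm(5000, mu = stats::runif(5000, 50, 500), alpha = 0.05, seed = 4)
  dn <- estimate_dispersions(cmn, groups9)
  expect_gte(median(dn$alpha), 0.03)
  expect_lte(median(dn$alpha), 0.08)

  expect_error(
    estimate_dispersions(cm[, 1:3],
                         tibble::tibble(sample = c("case_1", "case_2"),
                                        group = c("case", "control"))),
    "at least 3 samples")
})

test_that("the Wald test is symmetric, label-antisymmetric and scale-invariant", {
  cm <- tibble::tibble(feature_id = c("a", "b"))
  for (s in groups9$sample) cm[[s]] <- c(40L, 7L)
  fit <- nb_wald_test(cm, groups9)
  expect_equal(tidy(fit)$log2fc, c(0, 0), tolerance = 1e-8)
  expect_equal(tidy(fit)$p, c(1, 1), tolerance = 1e-8)

  cm <- sim_cm(300, mu = stats::runif(300, 20, 400), lfc = rep(c(0, 1), 150),
               seed = 6)
  fit <- nb_wald_test(cm, groups9)
  swapped <- groups9
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  fit_sw <- nb_wald_test(cm, swapped)
  expect_equal(tidy(fit_sw)$log2fc, -tidy(fit)$log2fc, tolerance = 1e-6)
  expect_equal(tidy(fit_sw)$p, tidy(fit)$p, tolerance = 1e-6)

  # scaling one sample's counts by c: its size factor scales by c relative
  # to the others, and with consistently scaled factors and fixed
  # dispersions the fold-change estimates are stable
  cm3 <- cm
  cm3$case_2 <- cm3$case_2 * 3L
  sfa <- estimate_size_factors(cm)
  sfb <- estimate_size_factors(cm3)
  expect_equal((sfb$size_factor[2] / sfb$size_factor[1]) /
                 (sfa$size_factor[2] / sfa$size_factor[1]), 3,
               tolerance = 1e-12)
  disp <- estimate_dispersions(cm, groups9, sfa)
  fit_a <- nb_wald_test(cm, groups9, size_factors = sfa, dispersions = disp)
  sfc <- sfa
  sfc$size_factor[sfc$sample == "case_2"] <- 3 * sfc$size_factor[sfc$sample == "case_2"]
  fit_b <- nb_wald_test(cm3, groups9, size_factors = sfc, dispersions = disp)
  expect_lt(max(abs(tidy(fit_b)$log2fc - tidy(fit_a)$log2fc)), 0.1)
})

test_that("all-zero features are dropped and excluded from BH", {
  cm <- sim_cm(50, mu = 100, seed = 7)
  cm[3, -1] <- as.list(rep(0L, 9))
  expect_message(fit <- nb_wald_test(cm, groups9), "dropped")
  expect_equal(nrow(tidy(fit)), 49)
  expect_false("f00003" %in% tidy(fit)$feature_id)
  g <- glance(fit)
  expect_equal(g$n_features, 50)
  expect_equal(g$n_dropped, 1)
})

test_that("BH adjustment matches the step-up formula and handles NA", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))

  pna <- c(0.01, NA, 0.04)
  out <- bh_adjust(pna)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], oracle_bh(c(0.01, 0.04)))
})

test_that("direction calls respect significance and sign", {
  res <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        log2fc = c(2, -2, 0, 1.5),
                        p = c(1e-6, 1e-6, 1e-9, 0.2),
                        padj = c(1e-5, 1e-5, 1e-8, 0.4))
  out <- call_differential(res, labels = c("hyper", "hypo"))
  expect_equal(out$direction, c("hyper", "hypo", "ns", "ns"))
  out_raw <- call_differential(res, use_padj = FALSE)
  expect_equal(out_raw$direction, c("up", "down", "ns", "ns"))
})

test_that("log2 fold changes agree with an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  cm <- sim_cm(200, mu = stats::runif(200, 50, 400), lfc = rep(c(0, 2), 100),
               seed = 9)
  fit <- nb_wald_test(cm, groups9)
  m <- as.matrix(cm[, -1])
  rownames(m) <- cm$feature_id
  storage.mode(m) <- "integer"
  coldata <- data.frame(group = factor(groups9$group, levels = c("control", "case")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  expect_lt(mean(abs(tidy(fit)$log2fc - ref$log2FoldChange)), 0.1)
  expect_gt(cor(tidy(fit)$wald_z, ref$stat), 0.98)
})
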