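test_that("configuration validation enforces the documented invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_hyper = 0.6, frac_hypo = 0.6), "< 1")
  expect_error(sim_config(peak_dropout = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_case = 0), "positive")
  expect_error(sim_config(base_mean_range = c(100, 10)), "increasing")
})

test_that("the genome scaffold places TSS uniformly away from chromosome ends", {
  cfg <- sim_config(seed = 1)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$tss), 5000)
  expect_true(all(g$tss$chrom %in% paste0("chr", 1:5)))
  expect_true(all(g$tss$tss >= 1000 & g$tss$tss <= cfg$chrom_length - 1000))
  expect_true(all(g$tss$strand %in% c("+", "-")))

  empty <- simulate_genome(sim_config(n_genes = 0))
  expect_equal(nrow(empty$tss), 0)

  g2 <- simulate_genome(sim_config(seed = 1))
  expect_identical(g, g2)
})

test_that("true regions are disjoint with at least 5 kb gaps and planted labels", {
  cfg <- sim_config(seed = 3)
  tr <- simulate_ground_truth(cfg)$true_regions
  expect_equal(nrow(tr), 3000)
  by_chrom <- split(tr, tr$chrom)
  for (sub in by_chrom) {
    gaps <- sub$start[-1] - sub$end[-nrow(sub)]
    expect_true(all(gaps >= 5000))
  }
  expect_equal(sum(tr$status == "hyper"), round(0.015 * 3000))
  expect_equal(sum(tr$status == "hypo"), round(0.015 * 3000))
  expect_true(all(abs(tr$lfc[tr$status != "null"]) == cfg$planted_lfc))
  expect_true(all(tr$lfc[tr$status == "null"] == 0))
})

test_that("peak dropout follows its rate, with binomial-oracle bounds at seed 7", {
  cfg0 <- sim_config(peak_dropout = 0, seed = 7)
  truth0 <- simulate_ground_truth(cfg0)
  pk0 <- simulate_peaks(cfg0, truth0)
  expect_true(all(vapply(pk0, nrow, integer(1)) == cfg0$n_true_regions))

  cfg1 <- sim_config(peak_dropout = 1, seed = 7)
  pk1 <- simulate_peaks(cfg1, simulate_ground_truth(cfg1))
  expect_true(all(vapply(pk1, nrow, integer(1)) == 0))

  cfg <- sim_config(seed = 7)
  pk <- simulate_peaks(cfg, simulate_ground_truth(cfg))
  # each sample's retained-peak count ~ Binomial(3000, 0.8): check a
  # 6-sigma band around the expectation
  n <- cfg$n_true_regions
  expected <- n * (1 - cfg$peak_dropout)
  halfwidth <- 6 * sqrt(n * 0.8 * 0.2)
  counts <- vapply(pk, nrow, integer(1))
  expect_true(all(abs(counts - expected) <= halfwidth))
})

test_that("NB counts approach the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(n_true_regions = 1000, dispersion = 1e-8, seed = 5)
  truth <- simulate_ground_truth(cfg)
  cm <- simulate_counts(cfg, truth, size_factors = rep(1, 9))
  m <- as.matrix(cm[, -1])
  ctrl <- m[, 6:9]
  ratio <- apply(ctrl, 1, var) / rowMeans(ctrl)
  # at unit size factors the mean variance/mean ratio is 1 in the Poisson
  # limit (the median would sit near qchisq(0.5, 3)/3 with 4 samples)
  expect_equal(mean(ratio), 1, tolerance = 0.1)

  cm2 <- simulate_counts(cfg, truth, size_factors = rep(1, 9))
  expect_identical(cm, cm2)
})

test_that("expression truth obeys the coupling rule", {
  cfg0 <- sim_config(coupling_prob = 0, bg_de_rate = 0, seed = 6)
  tg0 <- simulate_ground_truth(cfg0)$true_genes
  expect_true(all(tg0$status == "null"))

  cfg1 <- sim_config(coupling_prob = 1, bg_de_rate = 0, seed = 6)
  truth1 <- simulate_ground_truth(cfg1)
  tg1 <- truth1$true_genes
  dr <- truth1$true_regions[truth1$true_regions$status != "null", ]
  dr$region_id <- dr$truth_id
  dr$direction <- dr$status
  links <- annotate_regions(dr, truth1$tss, window = cfg1$tss_window)
  linked <- unique(links$gene_id)
  expect_setequal(tg1$gene_id[tg1$status != "null"], linked)
  # every coupled gene's sign matches the direction of its nearest region
  links <- links[order(links$gene_id, links$distance), ]
  nearest <- links[!duplicated(links$gene_id), ]
  got <- tg1$status[match(nearest$gene_id, tg1$gene_id)]
  expect_equal(got, ifelse(nearest$region_direction == "hyper", "up", "down"))
  expect_true(all(abs(tg1$lfc[tg1$status != "null"]) == cfg1$planted_lfc))
})

test_that("PWMs are normalized and sequence planting matches its rates", {
  cfg <- sim_config(seed = 8)
  truth <- simulate_ground_truth(cfg)
  expect_length(truth$pwms, cfg$n_motifs)
  for (p in truth$pwms) {
    expect_true(all(abs(rowSums(p$matrix) - 1) < 1e-9))
    expect_true(nrow(p$matrix) >= 8 && nrow(p$matrix) <= 12)
  }

  sq <- simulate_sequences(cfg, truth, "hyper")
  expect_length(sq$foreground, cfg$n_sequences)
  expect_true(all(nchar(sq$foreground) == cfg$seq_length))
  planted <- truth$motif_truth$motif[truth$motif_truth$planted == "hyper"]
  cons <- pwm_consensus(truth$pwms[[planted[1]]])
  frac_fg <- mean(grepl(cons, sq$foreground, fixed = TRUE))
  frac_bg <- mean(grepl(cons, sq$background, fixed = TRUE))
  expect_gt(frac_fg, 0.35)
  expect_lt(frac_bg, 0.15)

  # with a single planted motif at rate 1, every foreground sequence holds
  # its consensus (several planted motifs may overwrite one another)
  cfg1 <- sim_config(n_motifs = 1, motif_plant_rate_fg = 1,
                     motif_plant_rate_bg = 0, seed = 8)
  truth1 <- simulate_ground_truth(cfg1)
  one <- simulate_sequences(cfg1, truth1, "hyper")
  cons1 <- pwm_consensus(truth1$pwms[[1]])
  expect_true(all(grepl(cons1, one$foreground, fixed = TRUE)))
  expect_false(any(grepl(cons1, one$background, fixed = TRUE)))

  masked <- simulate_sequences(cfg, truth, "hyper", mask_rate = 1)
  expect_true(all(grepl("N", masked$foreground)))
})

test_that("input bundles are reproducible byte-for-byte under a fixed seed", {
  cfg <- sim_config(n_true_regions = 60, n_genes = 40, n_sequences = 10,
                    seq_length = 100, seed = 9)
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  m1 <- simulate_inputs(cfg, d1)
  m2 <- simulate_inputs(cfg, d2)
  expect_equal(m1$file, m2$file)
  expect_equal(m1$md5, m2$md5)
  expect_equal(sum(grepl("^peaks/", m1$file)), 9)
  m3 <- simulate_inputs(sim_config(n_true_regions = 60, n_genes = 40,
                                   n_sequences = 10, seq_length = 100,
                                   seed = 10),
                        file.path(withr::local_tempdir(), "b3"))
  expect_false(all(m3$md5 == m1$md5))
})
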