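sharp_pwm <- function(consensus, name = "m1") {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0.05, length(codes), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(codes), codes)] <- 0.85
  diffacet:::new_pwm(name, m)
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

test_that("scanning finds consensus matches on either strand and skips Ns", {
  pwm <- sharp_pwm("ACGTACGTAA")
  expect_true(scan_sequence(pwm, "ACGTACGTAA", score_fraction = 1))
  expect_false(scan_sequence(pwm, paste(rep("N", 50), collapse = "")))

  set.seed(41)
  flank <- function(core) {
    paste0(paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), core,
           paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  }
  expect_true(scan_sequence(pwm, flank(revcomp("ACGTACGTAA"))))
  expect_message(out <- scan_sequence(pwm, "ACG"), "shorter")
  expect_false(out)
})

test_that("the scanner agrees with a naive reference and is strand-symmetric", {
  set.seed(42)
  pwm <- sharp_pwm(paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""))
  seqs <- vapply(1:60, function(i) {
    s <- sample(c("A", "C", "G", "T"), 500, TRUE)
    if (i %% 4 == 0) s[sample(450, 1) + 0:9] <- strsplit(pwm_consensus(pwm), "")[[1]]
    if (i %% 7 == 0) s[sample(400, 1) + 0:30] <- "N"
    paste(s, collapse = "")
  }, character(1))
  got <- vapply(seqs, scan_sequence, logical(1), pwm = pwm)
  want <- vapply(seqs, oracle_scan, logical(1), pwm = pwm)
  expect_equal(unname(got), unname(want))
  expect_gt(sum(got), 0)

  rc_seqs <- vapply(seqs, revcomp, character(1))
  got_rc <- vapply(rc_seqs, scan_sequence, logical(1), pwm = pwm)
  expect_equal(unname(got_rc), unname(got))
})

test_that("MEME files round-trip with normalized probability rows", {
  cfg <- sim_config(seed = 2)
  truth <- simulate_ground_truth(cfg)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.meme")
  write_meme(truth$pwms, p)
  back <- read_meme(p)
  expect_equal(names(back), names(truth$pwms))
  for (nm in names(back)) {
    expect_equal(back[[nm]]$matrix, unname(truth$pwms[[nm]]$matrix) |>
                   `colnames<-`(c("A", "C", "G", "T")), tolerance = 1e-6)
    expect_true(all(abs(rowSums(back[[nm]]$matrix) - 1) < 1e-9))
  }
  expect_error(read_meme(tempfile()), "not found")
})

test_that("Fisher enrichment matches the hypergeometric tail sum", {
  pwms <- list(m1 = sharp_pwm("ACGTACGT"))
  # equal rates: odds ratio 1, p past 0.5
  p_eq <- fisher.test(matrix(c(10, 40, 10, 40), 2, byrow = TRUE),
                      alternative = "greater")$p.value
  expect_equal(p_eq, oracle_fisher_greater(10, 40, 10, 40), tolerance = 1e-12)
  expect_gte(p_eq, 0.5)

  p_enr <- fisher.test(matrix(c(30, 20, 5, 45), 2, byrow = TRUE),
                       alternative = "greater")$p.value
  expect_equal(p_enr, oracle_fisher_greater(30, 20, 5, 45), tolerance = 1e-12)

  # monotonicity: one extra foreground hit never increases p
  for (a in 5:15) {
    expect_lte(oracle_fisher_greater(a + 1, 49 - a, 10, 40),
               oracle_fisher_greater(a, 50 - a, 10, 40))
  }
})

test_that("enrichment_test builds correct tables over sequence sets", {
  set.seed(43)
  pwm <- sharp_pwm("ACGTTGCAGT")
  rand_seq <- function() paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  plant <- function(s) {
    pos <- sample(280, 1)
    substr(s, pos, pos + 9) <- "ACGTTGCAGT"
    s
  }
  fg <- vapply(1:50, function(i) {
    s <- rand_seq()
    if (i <= 30) plant(s) else s
  }, character(1))
  bg <- vapply(1:50, function(i) {
    s <- rand_seq()
    if (i <= 3) plant(s) else s
  }, character(1))
  out <- enrichment_test(list(mA = pwm), fg, bg)
  expect_gte(out$fg_hits, 30)
  expect_equal(out$fg_total, 50)
  expect_equal(out$p,
               oracle_fisher_greater(out$fg_hits, 50 - out$fg_hits,
                                     out$bg_hits, 50 - out$bg_hits),
               tolerance = 1e-12)
  expect_error(enrichment_test(list(), fg, bg), "empty motif set")
  expect_error(enrichment_test(list(mA = pwm), character(0), bg), "non-empty")

  # the empirical background model still detects a strongly planted motif
  out_emp <- enrichment_test(list(mA = pwm), fg, bg,
                             background_model = "empirical")
  expect_lt(out_emp$p, 0.001)
})

test_that("motif-TF linkage joins enrichment direction with expression calls", {
  enr <- list(hyper = tibble::tibble(motif = c("m1", "m2"), fg_hits = c(40L, 5L),
                                     fg_total = 50L, bg_hits = c(2L, 5L),
                                     bg_total = 50L, odds_ratio = c(96, 1),
                                     p = c(1e-12, 0.6), padj = c(2e-12, 0.6)),
              hypo = tibble::tibble(motif = "m3", fg_hits = 30L, fg_total = 50L,
                                    bg_hits = 1L, bg_total = 50L,
                                    odds_ratio = 73.5, p = 1e-10, padj = 1e-10))
  rna <- tibble::tibble(feature_id = c("gU", "gD", "gX"),
                        direction = c("up", "down", "ns"))
  nm <- tibble::tibble(motif = c("m1", "m2", "m3"),
                       gene_id = c("gU", "gX", "gD"))
  out <- link_motifs_to_de_tfs(enr, rna, nm)
  expect_equal(nrow(out), 2)
  expect_equal(out$gene_id[out$region_direction == "hyper"], "gU")
  expect_equal(out$gene_id[out$region_direction == "hypo"], "gD")

  none <- link_motifs_to_de_tfs(list(hyper = enr$hyper[0, ]), rna, nm)
  expect_equal(nrow(none), 0)
  expect_error(link_motifs_to_de_tfs(enr, rna, NULL), "name_map")
})
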