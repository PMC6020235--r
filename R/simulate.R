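# Synthetic-data generator: produces every pipeline input (peak calls,
# region and gene count matrices, TSS catalog, PWMs, foreground/background
# sequences) with known ground truth, emulating a two-group ChIP-seq +
# RNA-seq study (n = 5 cases vs n = 4 controls, ~3% differential regions
# at log2FC +/- 2, NB counts, expression coupled to nearby regions).

#' Simulation configuration
#'
#' Collects and validates all generator parameters. Defaults emulate the
#' study design the pipeline targets: 5 case vs 4 control samples, five
#' 10-Mb autosomes, 3000 true regions of which 1.5% are hyper- and 1.5%
#' hypoacetylated at log2FC 2, NB dispersion 0.05, and expression fold
#' changes coupled to regions within 20 kb of a TSS with probability 0.7.
#'
#' @param n_case,n_control Samples per group.
#' @param n_chromosomes,chrom_length Genome shape (autosomes `chr1..chrN`).
#' @param n_true_regions Number of true (non-overlapping, >= 5 kb apart)
#'   signal regions.
#' @param frac_hyper,frac_hypo Fractions of true regions with planted
#'   positive / negative log2 fold change.
#' @param planted_lfc Absolute planted log2 fold change (case vs control).
#' @param base_mean_range Range of per-feature base mean counts.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param peak_dropout Probability a true region is missed in one sample's
#'   peak calls.
#' @param n_genes Genes in the TSS catalog.
#' @param coupling_prob Probability a gene with a TSS within `tss_window` of
#'   a planted differential region receives a concordant expression LFC.
#' @param bg_de_rate Background rate of independently DE genes (default 0.02).
#' @param tss_window Coupling/annotation window in bp (default 20000).
#' @param n_motifs Number of PWMs; about half are planted.
#' @param motif_plant_rate_fg,motif_plant_rate_bg Fractions of foreground /
#'   background sequences receiving a planted consensus.
#' @param n_sequences,seq_length Sequences per set and their length in bp.
#' @param seed Master seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_case = 5, n_control = 4, n_chromosomes = 5,
                       chrom_length = 1e7, n_true_regions = 3000,
                       frac_hyper = 0.015, frac_hypo = 0.015,
                       planted_lfc = 2.0, base_mean_range = c(20, 500),
                       dispersion = 0.05, peak_dropout = 0.2,
                       n_genes = 5000, coupling_prob = 0.7,
                       bg_de_rate = 0.02, tss_window = 20000,
                       n_motifs = 10, motif_plant_rate_fg = 0.5,
                       motif_plant_rate_bg = 0.05,
                       n_sequences = 200, seq_length = 500, seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control,
              n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_true_regions = n_true_regions, frac_hyper = frac_hyper,
              frac_hypo = frac_hypo, planted_lfc = planted_lfc,
              base_mean_range = base_mean_range, dispersion = dispersion,
              peak_dropout = peak_dropout, n_genes = n_genes,
              coupling_prob = coupling_prob, bg_de_rate = bg_de_rate,
              tss_window = tss_window, n_motifs = n_motifs,
              motif_plant_rate_fg = motif_plant_rate_fg,
              motif_plant_rate_bg = motif_plant_rate_bg,
              n_sequences = n_sequences, seq_length = seq_length, seed = seed)
  probs <- c(frac_hyper, frac_hypo, peak_dropout, coupling_prob, bg_de_rate,
             motif_plant_rate_fg, motif_plant_rate_bg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (frac_hyper + frac_hypo >= 1) stop("frac_hyper + frac_hypo must be < 1", call. = FALSE)
  counts <- c(n_case, n_control, n_chromosomes, chrom_length, n_true_regions,
              n_genes, n_motifs, n_sequences, seq_length)
  if (any(counts < 0) || any(counts[c(1:4, 7:9)] <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (dispersion < 0 || planted_lfc < 0) stop("dispersion and planted_lfc must be >= 0", call. = FALSE)
  if (length(base_mean_range) != 2 || base_mean_range[1] <= 0 ||
      base_mean_range[2] < base_mean_range[1]) {
    stop("base_mean_range must be an increasing positive pair", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

sim_samples <- function(config) {
  c(paste0("case_", seq_len(config$n_case)),
    paste0("control_", seq_len(config$n_control)))
}

#' Sample-to-group table for a simulation
#'
#' @param config A [sim_config()].
#' @return Tibble `sample`, `group` (`case` / `control`).
#' @export
sim_groups <- function(config) {
  tibble::tibble(
    sample = sim_samples(config),
    group = rep(c("case", "control"), c(config$n_case, config$n_control))
  )
}

#' Simulate the genome scaffold: chromosome sizes and TSS catalog
#'
#' Places `n_genes` transcription start sites uniformly at random across the
#' autosomes (no TSS within 1 kb of a chromosome end), with random strand.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_sizes` (tibble `chrom`, `length`) and `tss`
#'   (tibble `gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_genome <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- tibble::tibble(chrom = chroms,
                                length = rep(as.integer(config$chrom_length),
                                             config$n_chromosomes))
  tss <- with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_genes
    if (n == 0) {
      tibble::tibble(gene_id = character(), chrom = character(),
                     tss = integer(), strand = character())
    } else {
      tibble::tibble(
        gene_id = sprintf("gene%05d", seq_len(n)),
        chrom = sample(chroms, n, replace = TRUE),
        tss = as.integer(floor(runif(n, 1000, config$chrom_length - 1000))),
        strand = sample(c("+", "-"), n, replace = TRUE)
      )
    }
  })
  list(chrom_sizes = chrom_sizes, tss = tss)
}

# Non-overlapping true regions with >= `gap` bp between neighbours.
simulate_true_regions <- function(config, gap = 5000) {
  with_seed(stage_seed(config$seed, 2L), {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    n <- config$n_true_regions
    per_chrom <- table(factor(sort(rep_len(seq_along(chroms), n)),
                              levels = seq_along(chroms)))
    out <- list()
    for (ci in seq_along(chroms)) {
      k <- as.integer(per_chrom[ci])
      if (k == 0) next
      w <- as.integer(floor(runif(k, 500, 1501)))
      slack <- config$chrom_length - sum(w) - (k - 1) * gap
      if (slack < 0) stop("chromosome too short for requested regions", call. = FALSE)
      u <- runif(k + 1)
      extra <- floor(u / sum(u) * slack)
      starts <- cumsum(c(extra[1], head(w, -1) + gap + extra[-1][seq_len(k - 1)]))
      out[[ci]] <- tibble::tibble(chrom = chroms[ci],
                                  start = as.integer(starts),
                                  end = as.integer(starts + w))
    }
    regions <- dplyr::bind_rows(out)
    n_hyper <- round(config$frac_hyper * n)
    n_hypo <- round(config$frac_hypo * n)
    status <- rep("null", n)
    idx <- sample(n, n_hyper + n_hypo)
    status[idx[seq_len(n_hyper)]] <- "hyper"
    status[idx[n_hyper + seq_len(n_hypo)]] <- "hypo"
    regions$truth_id <- sprintf("true%05d", seq_len(n))
    regions$status <- status
    regions$lfc <- ifelse(status == "hyper", config$planted_lfc,
                          ifelse(status == "hypo", -config$planted_lfc, 0))
    regions$base_mean <- runif(n, config$base_mean_range[1], config$base_mean_range[2])
    regions
  })
}

# Gene truth: genes with a TSS within tss_window of a differential true
# region receive its direction with probability coupling_prob; a background
# fraction of the remaining genes is DE independently.
simulate_gene_truth <- function(config, genome, true_regions) {
  with_seed(stage_seed(config$seed, 3L), {
    tss <- genome$tss
    status <- rep("null", nrow(tss))
    diff_regions <- true_regions[true_regions$status != "null", ]
    if (nrow(diff_regions) > 0 && nrow(tss) > 0) {
      dr <- diff_regions[order(diff_regions$chrom, diff_regions$start), ]
      dr$region_id <- dr$truth_id
      dr$direction <- dr$status
      links <- annotate_regions(dr, tss, window = config$tss_window)
      if (nrow(links) > 0) {
        # closest region decides a gene's direction when several link
        links <- links[order(links$gene_id, links$distance), ]
        first <- !duplicated(links$gene_id)
        gdir <- links$region_direction[first]
        gid <- links$gene_id[first]
        couple <- runif(length(gid)) < config$coupling_prob
        gi <- match(gid[couple], tss$gene_id)
        status[gi] <- ifelse(gdir[couple] == "hyper", "up", "down")
      }
    }
    bg_pool <- which(status == "null")
    bg <- bg_pool[runif(length(bg_pool)) < config$bg_de_rate]
    status[bg] <- sample(c("up", "down"), length(bg), replace = TRUE)
    tibble::tibble(
      gene_id = tss$gene_id,
      status = status,
      lfc = ifelse(status == "up", config$planted_lfc,
                   ifelse(status == "down", -config$planted_lfc, 0))
    )
  })
}

# Sharpened random PWMs (consensus base probability 0.85) plus planting
# truth: ~half the motifs are planted, split between the hyper and hypo
# sequence sets.
simulate_pwms <- function(config) {
  with_seed(stage_seed(config$seed, 4L), {
    pwms <- list()
    for (i in seq_len(config$n_motifs)) {
      w <- sample(8:12, 1)
      cons <- sample(1:4, w, replace = TRUE)
      mat <- matrix(0.05, w, 4, dimnames = list(NULL, DNA))
      mat[cbind(seq_len(w), cons)] <- 0.85
      name <- sprintf("motif%02d", i)
      pwms[[name]] <- new_pwm(name, mat)
    }
    n_planted <- max(1L, round(config$n_motifs / 2))
    planted_idx <- sample(config$n_motifs, n_planted)
    n_hyper_m <- ceiling(n_planted * 0.6)
    planted <- rep("no", config$n_motifs)
    planted[planted_idx[seq_len(n_hyper_m)]] <- "hyper"
    if (n_planted > n_hyper_m) {
      planted[planted_idx[(n_hyper_m + 1):n_planted]] <- "hypo"
    }
    list(pwms = pwms,
         motif_truth = tibble::tibble(motif = names(pwms), planted = planted))
  })
}

#' Generate the full simulation ground truth
#'
#' Runs the deterministic truth-generation stages (genome scaffold, true
#' regions, coupled gene truth, PWMs and motif-to-gene map) for a
#' configuration. All downstream simulators take this object.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `config`, `chrom_sizes`, `tss`,
#'   `true_regions`, `true_genes`, `pwms`, `motif_truth`, `name_map`.
#' @export
simulate_ground_truth <- function(config) {
  genome <- simulate_genome(config)
  true_regions <- simulate_true_regions(config)
  true_genes <- simulate_gene_truth(config, genome, true_regions)
  mot <- simulate_pwms(config)
  # motif -> TF gene map: planted hyper motifs point at upregulated genes,
  # planted hypo motifs at downregulated genes, the rest at null genes, so
  # end-to-end TF linkage has a recoverable truth.
  up_genes <- true_genes$gene_id[true_genes$status == "up"]
  down_genes <- true_genes$gene_id[true_genes$status == "down"]
  null_genes <- true_genes$gene_id[true_genes$status == "null"]
  name_map <- with_seed(stage_seed(config$seed, 5L), {
    pick <- function(pool, fallback, k) {
      src <- if (length(pool) >= k) pool else c(pool, fallback)
      src[seq_len(k)]
    }
    mt <- mot$motif_truth
    gene <- character(nrow(mt))
    gene[mt$planted == "hyper"] <- pick(up_genes, null_genes, sum(mt$planted == "hyper"))
    gene[mt$planted == "hypo"] <- pick(down_genes, null_genes, sum(mt$planted == "hypo"))
    gene[mt$planted == "no"] <- pick(null_genes, true_genes$gene_id, sum(mt$planted == "no"))
    tibble::tibble(motif = mt$motif, gene_id = gene)
  })
  structure(list(config = config, chrom_sizes = genome$chrom_sizes,
                 tss = genome$tss, true_regions = true_regions,
                 true_genes = true_genes, pwms = mot$pwms,
                 motif_truth = mot$motif_truth, name_map = name_map),
            class = "sim_truth")
}

#' Simulate per-sample peak calls
#'
#' Each sample's peak set is the true region set minus independent dropouts
#' at rate `peak_dropout`, with both ends of every surviving peak jittered
#' by up to +/- 200 bp (clipped to the chromosome).
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_ground_truth()] object.
#' @return Named list (one per sample) of peak tibbles
#'   (`chrom`, `start`, `end`).
#' @export
simulate_peaks <- function(config, truth) {
  with_seed(stage_seed(config$seed, 6L), {
    samples <- sim_samples(config)
    tr <- truth$true_regions
    out <- list()
    for (s in samples) {
      keep <- runif(nrow(tr)) >= config$peak_dropout
      pk <- tr[keep, c("chrom", "start", "end")]
      if (nrow(pk) > 0) {
        pk$start <- pmax(pk$start + sample(-200:200, nrow(pk), replace = TRUE), 0L)
        pk$end <- pmin(pk$end + sample(-200:200, nrow(pk), replace = TRUE),
                       as.integer(config$chrom_length))
        bad <- pk$end <= pk$start
        pk <- pk[!bad, ]
      }
      out[[s]] <- pk
    }
    out
  })
}

#' Map a region set onto the simulation truth
#'
#' Each region inherits the status, planted LFC and base mean of the true
#' region it overlaps (true regions are >= 5 kb apart, so the mapping is
#' unambiguous for consensus-scale regions); regions overlapping no true
#' region are background.
#'
#' @param regions Region tibble (sorted or not) with `region_id`.
#' @param truth A [simulate_ground_truth()] object.
#' @return `regions` plus `status`, `lfc`, `truth_id` columns (`base_mean`
#'   as `mu0`).
#' @export
map_regions_to_truth <- function(regions, truth) {
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  tr <- truth$true_regions[order(truth$true_regions$chrom, truth$true_regions$start), ]
  pairs <- overlap_join(regions, tr)
  regions$status <- "background"
  regions$lfc <- 0
  regions$mu0 <- NA_real_
  regions$truth_id <- NA_character_
  if (nrow(pairs) > 0) {
    first <- !duplicated(pairs$query_idx)
    qi <- pairs$query_idx[first]
    si <- pairs$subject_idx[first]
    regions$status[qi] <- tr$status[si]
    regions$lfc[qi] <- tr$lfc[si]
    regions$mu0[qi] <- tr$base_mean[si]
    regions$truth_id[qi] <- tr$truth_id[si]
  }
  regions
}

#' Simulate a region-by-sample NB count matrix
#'
#' Counts follow `NB(mean = mu_i * s_j * 2^(lfc_i * case_j), Var = mu +
#' alpha mu^2)` with sample size factors `s_j` drawn log-uniformly from
#' `[0.5, 2]`. Regions overlapping a true region use its base mean and
#' planted LFC; other regions get a background mean from the low end of
#' `base_mean_range`.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_ground_truth()] object.
#' @param regions Region set to quantify (normally the consensus built from
#'   [simulate_peaks()] output; defaults to the true regions).
#' @param size_factors Optional fixed per-sample size factors (length
#'   `n_case + n_control`); by default they are drawn log-uniformly from
#'   `[0.5, 2]`.
#' @return Wide count tibble (`feature_id` + one column per sample).
#' @export
simulate_counts <- function(config, truth, regions = NULL, size_factors = NULL) {
  if (is.null(regions)) {
    regions <- truth$true_regions
    regions$region_id <- regions$truth_id
  }
  mapped <- map_regions_to_truth(regions, truth)
  with_seed(stage_seed(config$seed, 7L), {
    lo <- config$base_mean_range[1]
    span <- diff(config$base_mean_range)
    n_bg <- sum(is.na(mapped$mu0))
    mapped$mu0[is.na(mapped$mu0)] <- runif(n_bg, lo, lo + 0.1 * span)
    sim_nb_matrix(mapped$region_id, mapped$mu0, mapped$lfc, config, size_factors)
  })
}

# Shared NB sampler for region and gene counts (called inside with_seed).
sim_nb_matrix <- function(ids, mu0, lfc, config, size_factors = NULL) {
  groups <- sim_groups(config)
  s <- if (is.null(size_factors)) {
    exp(runif(nrow(groups), log(0.5), log(2)))
  } else {
    rep_len(size_factors, nrow(groups))
  }
  out <- tibble::tibble(feature_id = ids)
  for (j in seq_len(nrow(groups))) {
    is_case <- groups$group[j] == "case"
    mu <- mu0 * s[j] * 2^(lfc * as.numeric(is_case))
    y <- if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    out[[groups$sample[j]]] <- as.integer(y)
  }
  out
}

#' Simulate a gene-by-sample RNA count matrix
#'
#' Gene base means are uniform over `base_mean_range`; planted fold changes
#' come from the coupled gene truth (see [simulate_ground_truth()]); counts
#' are NB with the configured dispersion and log-uniform size factors.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_ground_truth()] object.
#' @param size_factors Optional fixed per-sample size factors, as in
#'   [simulate_counts()].
#' @return Wide count tibble (`feature_id` = gene ids).
#' @export
simulate_expression <- function(config, truth, size_factors = NULL) {
  with_seed(stage_seed(config$seed, 8L), {
    tg <- truth$true_genes
    mu0 <- runif(nrow(tg), config$base_mean_range[1], config$base_mean_range[2])
    sim_nb_matrix(tg$gene_id, mu0, tg$lfc, config, size_factors)
  })
}

#' Simulate motif-planted foreground and background sequences
#'
#' Generates `n_sequences` foreground and background sequences of
#' `seq_length` bp of i.i.d. uniform A/C/G/T; the consensus of every motif
#' planted for `direction` is inserted at a uniform random position in a
#' fraction `motif_plant_rate_fg` of the foreground and
#' `motif_plant_rate_bg` of the background sequences.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_ground_truth()] object.
#' @param direction Which planted motif set to use (`"hyper"` or `"hypo"`).
#' @param mask_rate Optional fraction of sequences receiving a run of 50
#'   `N`s at a random position (default 0: no masking).
#' @return List `foreground`, `background` (named character vectors) and
#'   `pwms` (the full PWM list).
#' @export
simulate_sequences <- function(config, truth, direction = "hyper",
                               mask_rate = 0) {
  stopifnot(direction %in% c("hyper", "hypo"))
  offset <- if (direction == "hyper") 9L else 10L
  with_seed(stage_seed(config$seed, offset), {
    n <- config$n_sequences
    len <- config$seq_length
    rand_seqs <- function(m) {
      vapply(seq_len(m),
             function(i) paste(sample(DNA, len, replace = TRUE), collapse = ""),
             character(1))
    }
    fg <- rand_seqs(n)
    bg <- rand_seqs(n)
    planted <- truth$motif_truth$motif[truth$motif_truth$planted == direction]
    insert <- function(seqs, motif_name, rate) {
      cons <- pwm_consensus(truth$pwms[[motif_name]])
      w <- nchar(cons)
      hit <- runif(length(seqs)) < rate
      for (i in which(hit)) {
        pos <- sample.int(len - w + 1, 1)
        substr(seqs[i], pos, pos + w - 1) <- cons
      }
      seqs
    }
    for (m in planted) {
      fg <- insert(fg, m, config$motif_plant_rate_fg)
      bg <- insert(bg, m, config$motif_plant_rate_bg)
    }
    if (mask_rate > 0) {
      mask <- function(seqs) {
        hit <- runif(length(seqs)) < mask_rate
        for (i in which(hit)) {
          pos <- sample.int(len - 50 + 1, 1)
          substr(seqs[i], pos, pos + 49) <- paste(rep("N", 50), collapse = "")
        }
        seqs
      }
      fg <- mask(fg)
      bg <- mask(bg)
    }
    names(fg) <- sprintf("fg_%s_%03d", direction, seq_len(n))
    names(bg) <- sprintf("bg_%s_%03d", direction, seq_len(n))
    list(foreground = fg, background = bg, pwms = truth$pwms)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the ground truth and every pipeline input for a configuration
#' and writes them under `dir`: per-sample peak BEDs, chromosome sizes, TSS
#' catalog, region counts on the consensus built from the simulated peaks,
#' RNA counts, group labels, motif file, motif-to-gene map, per-direction
#' foreground/background FASTA, and ground-truth tables for evaluation.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble manifest (`file`, `md5`).
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  truth <- simulate_ground_truth(config)
  readr::write_tsv(truth$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  readr::write_tsv(truth$tss, file.path(dir, "tss.tsv"))
  readr::write_tsv(sim_groups(config), file.path(dir, "groups.tsv"))
  peaks <- simulate_peaks(config, truth)
  for (s in names(peaks)) {
    write_bed(peaks[[s]], file.path(dir, "peaks", paste0(s, ".bed")))
  }
  consensus <- build_consensus(peaks, truth$chrom_sizes,
                               autosomes = paste0("chr", seq_len(config$n_chromosomes)))
  write_count_matrix(simulate_counts(config, truth, consensus),
                     file.path(dir, "chip_counts.tsv"))
  write_count_matrix(simulate_expression(config, truth),
                     file.path(dir, "rna_counts.tsv"))
  write_meme(truth$pwms, file.path(dir, "motifs.meme"))
  readr::write_tsv(truth$name_map, file.path(dir, "motif_gene_map.tsv"))
  for (dirn in c("hyper", "hypo")) {
    sq <- simulate_sequences(config, truth, direction = dirn)
    write_fasta(sq$foreground, file.path(dir, paste0("fg_", dirn, ".fa")))
    write_fasta(sq$background, file.path(dir, paste0("bg_", dirn, ".fa")))
  }
  readr::write_tsv(truth$true_regions, file.path(dir, "truth_regions.tsv"))
  readr::write_tsv(truth$true_genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(truth$motif_truth, file.path(dir, "truth_motifs.tsv"))
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "MANIFEST.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  readr::write_tsv(manifest, file.path(dir, "MANIFEST.tsv"))
  invisible(manifest)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
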