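# PWM-based transcription-factor binding-motif enrichment: minimal MEME
# motif I/O, log-odds scanning of both strands, Fisher's exact enrichment
# test, and linkage of enriched motifs to differentially expressed TFs.

DNA <- c("A", "C", "G", "T")

#' Read position probability matrices in minimal MEME format
#'
#' Parses `MOTIF <name>` blocks followed by a
#' `letter-probability matrix` header and one row of four probabilities
#' (A C G T) per motif position.
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of PWMs; each a list with `name`, `matrix`
#'   (width x 4, columns A,C,G,T) and `background` (uniform by default).
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("no MOTIF blocks in ", path, call. = FALSE)
  pwms <- list()
  for (i in seq_along(starts)) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1]][2]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:to]
    rows <- grep("^[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}$", block, value = TRUE)
    if (length(rows) == 0) stop("motif ", name, " has no probability rows", call. = FALSE)
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    colnames(mat) <- DNA
    if (any(abs(rowSums(mat) - 1) > 1e-6)) {
      stop("motif ", name, ": probability rows must sum to 1", call. = FALSE)
    }
    pwms[[name]] <- new_pwm(name, mat)
  }
  pwms
}

#' Write PWMs in minimal MEME format
#'
#' @param pwms Named list of PWMs (as from [read_meme()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

new_pwm <- function(name, matrix, background = rep(0.25, 4)) {
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 4, all(matrix >= 0))
  colnames(matrix) <- DNA
  list(name = name, matrix = matrix, background = background)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A PWM object.
#' @return Character string of the per-position argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA[apply(pwm$matrix, 1, which.max)], collapse = "")
}

# log2-odds matrix with probabilities floored at 1e-4 (pseudo-probability)
pwm_log_odds <- function(pwm) {
  log2(pmax(pwm$matrix, 1e-4) / rep(pwm$background, each = nrow(pwm$matrix)))
}

pwm_max_score <- function(pwm) sum(apply(pwm_log_odds(pwm), 1, max))

seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA)  # N and others -> NA
}

# best log-odds window score of codes (NA codes poison their windows)
best_window_score <- function(lo, codes) {
  w <- nrow(lo)
  n <- length(codes) - w + 1
  if (n < 1) return(-Inf)
  s <- numeric(n)
  for (k in seq_len(w)) {
    s <- s + lo[k, ][codes[k:(k + n - 1)]]
  }
  s[is.na(s)] <- -Inf
  max(s)
}

#' Scan a sequence for a motif hit
#'
#' Scores every window of both strands with the PWM's log2-odds (probability
#' floor 1e-4; uniform background by default) and reports a hit when the best
#' window reaches `score_fraction` of the motif's maximum attainable score.
#' Windows containing `N` are skipped; sequences shorter than the motif
#' cannot hit.
#'
#' @param pwm A PWM object.
#' @param seq Character string over A/C/G/T/N.
#' @param score_fraction Fraction of the maximum score required (default 0.8).
#' @return Logical: does the sequence contain a hit?
#' @export
scan_sequence <- function(pwm, seq, score_fraction = 0.8) {
  codes <- seq_to_codes(seq)
  w <- nrow(pwm$matrix)
  if (length(codes) < w) {
    message("sequence shorter than motif width; no hit possible")
    return(FALSE)
  }
  lo <- pwm_log_odds(pwm)
  thr <- score_fraction * pwm_max_score(pwm)
  fwd <- best_window_score(lo, codes)
  if (fwd >= thr) return(TRUE)
  rc <- rev(ifelse(is.na(codes), NA_integer_, 5L - codes))
  best_window_score(lo, rc) >= thr
}

#' Hit matrix of motifs against sequences
#'
#' @param pwms Named list of PWMs.
#' @param seqs Character vector of sequences (or `DNAStringSet`).
#' @param score_fraction Hit threshold as in [scan_sequence()].
#' @return Logical matrix, sequences x motifs.
#' @export
scan_hits <- function(pwms, seqs, score_fraction = 0.8) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  hits <- matrix(FALSE, length(seqs), length(pwms),
                 dimnames = list(names(seqs), names(pwms)))
  codes_list <- lapply(seqs, seq_to_codes)
  rc_list <- lapply(codes_list, function(cc) rev(ifelse(is.na(cc), NA_integer_, 5L - cc)))
  for (j in seq_along(pwms)) {
    lo <- pwm_log_odds(pwms[[j]])
    thr <- score_fraction * pwm_max_score(pwms[[j]])
    w <- nrow(lo)
    for (i in seq_along(seqs)) {
      if (length(codes_list[[i]]) < w) next
      hit <- best_window_score(lo, codes_list[[i]]) >= thr ||
        best_window_score(lo, rc_list[[i]]) >= thr
      hits[i, j] <- hit
    }
  }
  hits
}

#' Motif enrichment in foreground versus background sequences
#'
#' For each motif, counts hit-positive sequences in the foreground and
#' background sets, forms the 2x2 table, and tests for enrichment in the
#' foreground with a one-sided Fisher's exact test; p-values are BH-adjusted
#' across motifs.
#'
#' @param pwms Named list of PWMs (non-empty).
#' @param foreground,background Character vectors of sequences, paths to
#'   FASTA files, or `DNAStringSet`s.
#' @param score_fraction Hit threshold as in [scan_sequence()].
#' @param background_model `"uniform"` (default) scores against equal base
#'   probabilities; `"empirical"` uses the base composition of the
#'   background sequence set.
#' @return Tibble `motif`, `fg_hits`, `fg_total`, `bg_hits`, `bg_total`,
#'   `odds_ratio`, `p`, `padj`, sorted by `padj`.
#' @export
enrichment_test <- function(pwms, foreground, background, score_fraction = 0.8,
                            background_model = c("uniform", "empirical")) {
  background_model <- match.arg(background_model)
  if (length(pwms) == 0) stop("empty motif set", call. = FALSE)
  fg <- load_sequences(foreground)
  bg <- load_sequences(background)
  if (length(fg) == 0 || length(bg) == 0) {
    stop("foreground and background must be non-empty", call. = FALSE)
  }
  if (background_model == "empirical") {
    tab <- table(factor(unlist(strsplit(toupper(bg), "")), levels = DNA))
    freqs <- pmax(as.numeric(tab) / sum(tab), 1e-4)
    pwms <- lapply(pwms, function(p) {
      p$background <- freqs / sum(freqs)
      p
    })
  }
  fg_hits <- colSums(scan_hits(pwms, fg, score_fraction))
  bg_hits <- colSums(scan_hits(pwms, bg, score_fraction))
  a <- fg_hits; b <- length(fg) - fg_hits
  c_ <- bg_hits; d <- length(bg) - bg_hits
  p <- vapply(seq_along(pwms), function(i) {
    fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2, byrow = TRUE),
                alternative = "greater")$p.value
  }, numeric(1))
  out <- tibble::tibble(
    motif = names(pwms),
    fg_hits = as.integer(a), fg_total = length(fg),
    bg_hits = as.integer(c_), bg_total = length(bg),
    odds_ratio = (a * d) / (b * c_),
    p = p,
    padj = bh_adjust(p)
  )
  out[order(out$padj, out$p), ]
}

load_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(as.character(Biostrings::readDNAStringSet(x)))
  }
  x
}

#' Link enriched motifs to differentially expressed transcription factors
#'
#' Joins per-direction motif enrichment results with RNA differential calls
#' through a motif-to-gene map: a TF is reported when its motif is enriched
#' (adjusted p below `threshold`) in the hyper-direction foreground and its
#' transcript is called `up`, or the hypo/`down` mirror.
#'
#' @param enrichment Named list with elements `hyper` and/or `hypo`, each an
#'   [enrichment_test()] result.
#' @param rna_calls RNA results tibble with `feature_id`, `direction`.
#' @param name_map Data frame `motif`, `gene_id` mapping motif names to gene
#'   ids; motifs absent from the map are reported via `message()`.
#' @param threshold Enrichment padj threshold (default 0.05).
#' @return Tibble `motif`, `gene_id`, `region_direction`, `gene_direction`.
#' @export
link_motifs_to_de_tfs <- function(enrichment, rna_calls, name_map,
                                  threshold = 0.05) {
  if (missing(name_map) || is.null(name_map)) {
    stop("a motif-to-gene name_map is required", call. = FALSE)
  }
  stopifnot(all(c("motif", "gene_id") %in% names(name_map)))
  want <- list(hyper = "up", hypo = "down")
  out <- list()
  for (dir in names(want)) {
    enr <- enrichment[[dir]]
    if (is.null(enr) || nrow(enr) == 0) next
    sig <- enr$motif[!is.na(enr$padj) & enr$padj < threshold]
    unmatched <- setdiff(sig, name_map$motif)
    if (length(unmatched) > 0) {
      message(length(unmatched), " enriched motif(s) without a gene mapping: ",
              paste(unmatched, collapse = ", "))
    }
    genes <- name_map$gene_id[match(sig, name_map$motif)]
    keep <- !is.na(genes)
    gd <- rna_calls$direction[match(genes[keep], rna_calls$feature_id)]
    hit <- !is.na(gd) & gd == want[[dir]]
    if (any(hit)) {
      out[[dir]] <- tibble::tibble(
        motif = sig[keep][hit],
        gene_id = genes[keep][hit],
        region_direction = dir,
        gene_direction = want[[dir]]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(motif = character(), gene_id = character(),
                          region_direction = character(),
                          gene_direction = character()))
  }
  dplyr::bind_rows(out)
}

#' Motif enrichment dot plot
#'
#' @param tbl [enrichment_test()] result.
#' @param threshold padj threshold line (default 0.05).
#' @return A ggplot object.
#' @export
plot_motif_enrichment <- function(tbl, threshold = 0.05) {
  d <- tbl
  d$motif <- factor(d$motif, levels = rev(d$motif))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$padj, 1e-300)),
                                  y = .data$motif,
                                  size = .data$fg_hits / .data$fg_total)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(threshold), linetype = 2) +
    ggplot2::labs(x = expression(-log[10](padj)), y = NULL,
                  size = "fg hit rate") +
    ggplot2::theme_minimal()
}
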