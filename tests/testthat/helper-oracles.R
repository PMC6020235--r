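# Independent brute-force oracles used across the suite. These deliberately
# use different algorithms from the package (coverage vectors, all-pairs
# scans, direct formulae) so agreement is informative.

# Merge oracle: quadratic union-find over pairwise overlaps (>= 1 shared
# base, half-open, so bookended intervals stay separate), then per-component
# outermost coordinates.
oracle_merge <- function(regions) {
  out <- list()
  for (ch in sort(unique(regions$chrom))) {
    sub <- regions[regions$chrom == ch, ]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n)) {
      js <- which(sub$start[i] < sub$end & sub$end[i] > sub$start)
      for (j in js[js > i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    agg <- lapply(split(seq_len(n), comp), function(idx) {
      tibble::tibble(chrom = ch, start = min(sub$start[idx]),
                     end = max(sub$end[idx]))
    })
    out[[ch]] <- dplyr::bind_rows(agg)
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$chrom, res$start), ]
  tibble::remove_rownames(res)
}

# All-pairs support oracle: for every merged region, count samples having at
# least one overlapping interval (>= 1 shared base, half-open).
oracle_support <- function(merged, peak_sets) {
  vapply(seq_len(nrow(merged)), function(i) {
    sum(vapply(peak_sets, function(ps) {
      any(ps$chrom == merged$chrom[i] &
            ps$start < merged$end[i] & ps$end > merged$start[i])
    }, logical(1)))
  }, integer(1))
}

# All-pairs TSS-window annotation oracle.
oracle_annotate <- function(regions, tss, window) {
  rows <- list()
  for (g in seq_len(nrow(tss))) {
    for (r in seq_len(nrow(regions))) {
      if (regions$chrom[r] != tss$chrom[g]) next
      t <- tss$tss[g]
      d <- max(max(regions$start[r] - t, t - regions$end[r]), 0)
      if (d <= window) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          region_id = regions$region_id[r], gene_id = tss$gene_id[g],
          distance = as.integer(d))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(region_id = character(), gene_id = character(),
                          distance = integer()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$region_id, out$gene_id), ]
}

# All-pairs read counting oracle.
oracle_count <- function(regions, pos) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(pos$chrom == regions$chrom[i] & pos$pos >= regions$start[i] &
          pos$pos < regions$end[i])
  }, integer(1))
}

# Direct Benjamini-Hochberg step-up with monotonicity enforcement.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# One-sided (enrichment) Fisher p as an explicit hypergeometric tail sum via
# log-binomial coefficients.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b      # foreground total
  n <- c + d      # background total
  k <- a + c      # total hits
  lo <- max(0, k - n)
  hi <- min(k, m)
  logp <- vapply(a:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  mx <- max(logp)
  exp(mx) * sum(exp(logp - mx))
}

# Naive PWM scanner: explicit per-offset loops on both strands.
oracle_scan <- function(pwm, seq, score_fraction = 0.8) {
  bases <- c("A", "C", "G", "T")
  lo <- log2(pmax(pwm$matrix, 1e-4) / 0.25)
  w <- nrow(lo)
  maxs <- sum(apply(lo, 1, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  scan1 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch) - w + 1
    if (n < 1) return(FALSE)
    for (i in seq_len(n)) {
      sc <- 0
      ok <- TRUE
      for (k in seq_len(w)) {
        j <- match(ch[i + k - 1], bases)
        if (is.na(j)) { ok <- FALSE; break }
        sc <- sc + lo[k, j]
      }
      if (ok && sc >= score_fraction * maxs) return(TRUE)
    }
    FALSE
  }
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  scan1(seq) || scan1(rc)
}

random_regions <- function(n, chroms = c("chr1", "chr2", "chr3"),
                           max_coord = 19000) {
  start <- sample.int(max_coord - 1200, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(1000, n, replace = TRUE))
}
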