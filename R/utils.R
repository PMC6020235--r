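# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a stage-specific seed from a master seed; keeps results of each
# simulation stage independent of the order in which stages are invoked.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + stage * 7919L
}

assert_regions <- function(x, what = "regions") {
  if (!is.data.frame(x)) stop(what, " must be a data frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | is.na(x$start) | is.na(x$end))) {
    stop(what, " contains missing coordinates", call. = FALSE)
  }
  if (any(x$start < 0)) stop(what, " has negative start coordinates", call. = FALSE)
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop(what, sprintf(": interval with end <= start at row %d (%s:%s-%s)",
                       bad, x$chrom[bad], x$start[bad], x$end[bad]),
         call. = FALSE)
  }
  invisible(x)
}

# Overlap join of query intervals against a *sorted, disjoint* subject set
# (half-open coordinates; overlap requires >= 1 shared base). Returns a tibble
# of (query_idx, subject_idx) pairs. Both inputs need chrom/start/end.
overlap_join <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  }
  out_q <- vector("list", 0L)
  out_s <- vector("list", 0L)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    s_start <- subject$start[si]
    s_end <- subject$end[si]
    # first subject with end > q.start; last subject with start < q.end
    j1 <- findInterval(query$start[qi], s_end) + 1L
    j2 <- findInterval(query$end[qi], s_start, left.open = TRUE)
    n_hit <- pmax(j2 - j1 + 1L, 0L)
    keep <- n_hit > 0L
    if (!any(keep)) next
    reps <- n_hit[keep]
    out_q[[length(out_q) + 1L]] <- rep(qi[keep], reps)
    out_s[[length(out_s) + 1L]] <- si[sequence(reps, from = j1[keep])]
  }
  if (length(out_q) == 0) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  }
  tibble::tibble(query_idx = unlist(out_q), subject_idx = unlist(out_s))
}

# Convert a wide count tibble (feature_id + one column per sample) to an
# integer matrix with feature rownames.
cm_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "feature_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

assert_count_tbl <- function(counts, what = "counts") {
  if (!is.data.frame(counts) || names(counts)[1] != "feature_id") {
    stop(what, " must be a data frame whose first column is 'feature_id'",
         call. = FALSE)
  }
  if (anyDuplicated(counts$feature_id)) {
    stop(what, ": duplicated feature_id: ",
         counts$feature_id[anyDuplicated(counts$feature_id)], call. = FALSE)
  }
  if (anyDuplicated(names(counts))) stop(what, ": duplicated sample ids", call. = FALSE)
  m <- cm_matrix(counts)
  if (length(m) && (any(!is.finite(m)) || any(m < 0))) {
    stop(what, ": counts must be finite and non-negative", call. = FALSE)
  }
  if (length(m) && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(what, sprintf(": non-integer count at feature '%s', sample '%s'",
                       rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  invisible(counts)
}

assert_groups <- function(groups, samples = NULL) {
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    stop("groups must be a data frame with columns 'sample' and 'group'",
         call. = FALSE)
  }
  if (anyDuplicated(groups$sample)) stop("duplicated sample in groups", call. = FALSE)
  if (!is.null(samples)) {
    miss <- setdiff(samples, groups$sample)
    if (length(miss) > 0) {
      stop("samples missing from groups: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(groups)
}
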