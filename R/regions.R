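#' Read a BED file of intervals
#'
#' Reads BED3+ (tab-separated, 0-based half-open, no header). `track` and
#' `browser` lines are skipped. Only the first three columns are used.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted as in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(keep)[which(nf < 3)[1]]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields", bad, path),
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(keep)[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates", bad, path),
         call. = FALSE)
  }
  out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1L),
                        start = start, end = end)
  assert_regions(out, paste0("BED file ", path))
  out
}

#' Write intervals to a BED file
#'
#' @param regions A region tibble with `chrom`, `start`, `end`; any further
#'   columns are written as additional BED fields in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  assert_regions(regions)
  cols <- c("chrom", "start", "end", setdiff(names(regions), c("chrom", "start", "end")))
  readr::write_tsv(regions[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Stretch intervals to a minimum length
#'
#' Intervals already at least `min_len` long are returned unchanged. Shorter
#' intervals are extended symmetrically about their midpoint to exactly
#' `min_len`; if the symmetric window would cross a chromosome boundary it is
#' shifted to fit inside `[0, chrom_length)` preserving its length, and only
#' truncated to the full chromosome when the chromosome itself is shorter than
#' `min_len`.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param min_len Minimum interval length in bp (default 2000).
#' @param chrom_sizes Tibble with columns `chrom` and `length`.
#' @return The region tibble with adjusted coordinates (other columns kept).
#' @export
stretch_regions <- function(regions, min_len = 2000, chrom_sizes) {
  assert_regions(regions)
  stopifnot(min_len > 0)
  if (nrow(regions) == 0) return(regions)
  len_map <- setNames(as.numeric(chrom_sizes$length), chrom_sizes$chrom)
  clen <- unname(len_map[regions$chrom])
  if (anyNA(clen)) {
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(unique(regions$chrom[is.na(clen)]), collapse = ", "), call. = FALSE)
  }
  if (any(regions$end > clen)) {
    stop("interval end exceeds chromosome length", call. = FALSE)
  }
  width <- regions$end - regions$start
  short <- width < min_len
  if (any(short)) {
    mid <- (regions$start + regions$end) %/% 2
    ns <- mid - min_len %/% 2
    ne <- ns + min_len
    # shift into bounds, preserving length
    shift_r <- pmax(0 - ns, 0)
    ns <- ns + shift_r
    ne <- ne + shift_r
    shift_l <- pmax(ne - clen, 0)
    ns <- ns - shift_l
    ne <- ne - shift_l
    # chromosome shorter than min_len: truncate to the whole chromosome
    ns <- pmax(ns, 0)
    ne <- pmin(ne, clen)
    regions$start[short] <- as.integer(ns[short])
    regions$end[short] <- as.integer(ne[short])
  }
  regions
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into the minimal set of maximal intervals:
#' two intervals merge if and only if they share at least one base
#' (half-open semantics; bookended intervals with `end == start` do not
#' merge). Output is sorted by (chrom, start) and pairwise disjoint.
#'
#' @param regions Region tibble; may be unsorted and overlapping.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
merge_regions <- function(regions) {
  assert_regions(regions)
  if (nrow(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  x <- regions[order(regions$chrom, regions$start, regions$end), c("chrom", "start", "end")]
  run_end <- stats::ave(x$end, x$chrom, FUN = cummax)
  new_block <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                   x$start[-1] >= run_end[-nrow(x)])
  block_last <- c(which(new_block)[-1] - 1L, nrow(x))
  tibble::tibble(
    chrom = x$chrom[new_block],
    start = as.integer(x$start[new_block]),
    end = as.integer(run_end[block_last])
  )
}

#' Count per-sample support of merged regions
#'
#' For each merged region, counts how many samples contribute at least one
#' interval overlapping it (>= 1 shared base). Intended use: `merged` is the
#' merge of the union of the per-sample sets, so every region has support
#' >= 1; a zero-support region signals an inconsistency and raises an error.
#'
#' @param merged Sorted, disjoint region tibble (output of [merge_regions()]).
#' @param peak_sets Named list of per-sample region tibbles, or a single
#'   tibble with a `sample` column.
#' @return `merged` with an integer `sample_support` column.
#' @export
region_support <- function(merged, peak_sets) {
  assert_regions(merged, "merged")
  if (is.data.frame(peak_sets)) {
    stopifnot("sample" %in% names(peak_sets))
    peak_sets <- split(peak_sets[, c("chrom", "start", "end")], peak_sets$sample)
  }
  support <- integer(nrow(merged))
  for (ps in peak_sets) {
    hits <- overlap_join(ps, merged)
    idx <- unique(hits$subject_idx)
    support[idx] <- support[idx] + 1L
  }
  if (nrow(merged) > 0 && any(support == 0)) {
    stop("internal inconsistency: merged region with zero sample support",
         call. = FALSE)
  }
  merged$sample_support <- support
  merged
}

#' Build a consensus region set from per-sample peak calls
#'
#' Implements the common-reference construction: per-sample peaks are
#' stretched to at least `min_len` bp, pooled and merged on outermost
#' coordinates, and only regions supported by at least `min_support`
#' independent samples (and, by default, lying on autosomes) are retained.
#'
#' @param peaks Named character vector of BED file paths (names = sample ids),
#'   or a named list of region tibbles.
#' @param chrom_sizes Tibble with columns `chrom`, `length`.
#' @param min_len Minimum stretched peak length in bp (default 2000).
#' @param min_support Minimum number of supporting samples (default 2).
#' @param autosomes_only Keep only chromosomes in `autosomes` (default TRUE).
#' @param autosomes Chromosome-name allowlist (default `chr1`..`chr22`).
#' @return Tibble `region_id`, `chrom`, `start`, `end`, `sample_support`,
#'   sorted and disjoint.
#' @export
build_consensus <- function(peaks, chrom_sizes, min_len = 2000, min_support = 2,
                            autosomes_only = TRUE,
                            autosomes = paste0("chr", 1:22)) {
  if (is.character(peaks)) {
    if (is.null(names(peaks))) names(peaks) <- basename(peaks)
    peaks <- lapply(peaks, read_bed)
  }
  if (length(peaks) < 2) stop("need at least two peak sets", call. = FALSE)
  stretched <- lapply(peaks, stretch_regions, min_len = min_len,
                      chrom_sizes = chrom_sizes)
  pooled <- dplyr::bind_rows(stretched)
  merged <- merge_regions(pooled)
  merged <- region_support(merged, stretched)
  out <- merged[merged$sample_support >= min_support, ]
  if (autosomes_only) out <- out[out$chrom %in% autosomes, ]
  if (nrow(out) == 0) {
    warning("consensus region set is empty", call. = FALSE)
  }
  out <- out[order(out$chrom, out$start), ]
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out[, c("region_id", "chrom", "start", "end", "sample_support")]
}
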