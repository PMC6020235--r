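#' Count reads falling in disjoint regions
#'
#' A read is assigned to a region when its 5' position lies within
#' `[start, end)`; because the region set is disjoint each read is counted at
#' most once. Reads on chromosomes absent from the region set are ignored
#' (a tally is reported via `message()`).
#'
#' @param regions Sorted, disjoint region tibble with a `region_id` column
#'   (e.g. output of [build_consensus()]).
#' @param reads Named list of per-sample tibbles with columns `chrom`, `pos`
#'   (0-based 5' positions), or a single tibble with a `sample` column.
#' @return Wide count tibble: `feature_id` then one integer column per sample.
#' @export
count_reads_in_regions <- function(regions, reads) {
  assert_regions(regions)
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  if (is.data.frame(reads)) {
    stopifnot("sample" %in% names(reads))
    reads <- split(reads[, c("chrom", "pos")], reads$sample)
  }
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, ]
  out <- tibble::tibble(feature_id = regions$region_id)
  n_skipped <- 0L
  for (s in names(reads)) {
    rd <- reads[[s]]
    if (nrow(rd) > 0 && (any(is.na(rd$pos)) || any(rd$pos < 0))) {
      stop("malformed read positions for sample ", s, call. = FALSE)
    }
    counts <- integer(nrow(regions))
    for (ch in unique(rd$chrom)) {
      ri <- which(regions$chrom == ch)
      pos <- rd$pos[rd$chrom == ch]
      if (length(ri) == 0) {
        n_skipped <- n_skipped + length(pos)
        next
      }
      idx <- findInterval(pos, regions$start[ri])
      ok <- idx >= 1L
      idx <- idx[ok]
      inside <- pos[ok] < regions$end[ri][idx]
      tab <- tabulate(idx[inside], nbins = length(ri))
      counts[ri] <- counts[ri] + tab
    }
    out[[s]] <- counts
  }
  if (n_skipped > 0) {
    message(n_skipped, " read(s) on chromosomes absent from the region list were ignored")
  }
  out
}

#' Load a count matrix from TSV
#'
#' Expects a header row, a first column of feature ids and one integer column
#' per sample. Validates integrality, non-negativity, id uniqueness, and that
#' every sample carries a group label.
#'
#' @param path TSV file path.
#' @param groups Data frame with columns `sample`, `group` covering every
#'   sample column in the file.
#' @return Wide count tibble (`feature_id` + sample columns).
#' @export
load_count_matrix <- function(path, groups) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "feature_id"
  tbl$feature_id <- as.character(tbl$feature_id)
  assert_count_tbl(tbl, paste0("count matrix ", path))
  assert_groups(groups, samples = names(tbl)[-1])
  tbl
}

#' Write a count matrix to TSV
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  assert_count_tbl(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}
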