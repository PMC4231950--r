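#' Coerce to a bin-count table
#'
#' All model-fitting functions in chipmix accept either a bare vector of
#' non-negative integer counts (one per fixed-width genomic bin) or a data
#' frame with a `count` column, optionally carrying `chrom`, `start` and
#' `end` coordinate columns produced by [bin_reads()].  `as_counts()`
#' normalises either form to a tibble and validates the count invariants.
#'
#' @param x A non-negative integer vector, or a data frame with a `count`
#'   column (and optionally `chrom`, `start`, `end`).
#' @param bin_width Optional bin width in bp; when `start` positions are
#'   present they must be offsets from the first start by whole bins.
#' @return A tibble with at least a `count` column.
#' @examples
#' as_counts(c(0, 3, 1))
#' @export
as_counts <- function(x, bin_width = NULL) {
  if (is.data.frame(x)) {
    if (!"count" %in% names(x)) {
      abort("count table must have a `count` column")
    }
    out <- as_tibble(x)
  } else if (is.numeric(x)) {
    out <- tibble(count = as.double(x))
  } else {
    abort("counts must be a numeric vector or a data frame with a `count` column")
  }
  cnt <- out$count
  if (length(cnt) == 0L) abort("counts are empty")
  if (anyNA(cnt) || any(!is.finite(cnt))) abort("counts contain missing or non-finite values")
  if (any(cnt < 0)) abort("counts must be non-negative")
  if (any(abs(cnt - round(cnt)) > 1e-8)) abort("counts must be integer-valued")
  out$count <- round(cnt)
  bw <- bin_width %||% attr(x, "bin_width", exact = TRUE)
  if (!is.null(bw) && "start" %in% names(out) && nrow(out) > 1L) {
    st <- out$start
    if (any(diff(st) <= 0)) abort("bin starts must be strictly increasing")
    if (any((st - st[1L]) %% bw != 0)) {
      abort("bin starts must be whole-bin offsets from the first start")
    }
  }
  if (!is.null(bw)) attr(out, "bin_width") <- bw
  out
}

count_values <- function(counts) {
  as_counts(counts)$count
}

# aggregate counts to unique values with multiplicities; the workhorse
# representation for all likelihoods (bin counts are small integers with
# heavy ties, so this is mathematically identical and much faster)
count_table <- function(counts) {
  x <- count_values(counts)
  tab <- table(x)
  list(x = as.numeric(names(tab)), m = as.numeric(tab), n = length(x))
}

#' Bin read start positions into fixed-width genomic bins
#'
#' Tiles `[0, chrom_length)` with consecutive `bin_width`-bp bins (a final
#' partial bin is dropped so all bins have equal width), assigns each read
#' to the bin containing its start position, and removes every bin that
#' overlaps an excluded region (telomere/centromere-style masks) by at
#' least one bp.  Dropped bins are removed from the output entirely, not
#' zero-filled.  Duplicate read positions are retained.
#'
#' @param reads Data frame of read start positions with columns `chrom` and
#'   `pos` (0-based bp).  All reads must be on a single chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param bin_width Bin width in bp (default 100).
#' @param excluded Optional data frame of excluded regions with columns
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from [read_bed()].
#'   Intervals on other chromosomes are ignored with a warning.
#' @return A tibble with columns `chrom`, `start`, `end`, `count`, one row
#'   per retained bin, with a `bin_width` attribute.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", pos = c(5, 105, 110))
#' bin_reads(reads, chrom_length = 300, bin_width = 100)
#' @export
bin_reads <- function(reads, chrom_length, bin_width = 100L, excluded = NULL) {
  if (!is.data.frame(reads)) abort("`reads` must be a data frame")
  pos_col <- intersect(c("pos", "start"), names(reads))[1L]
  if (is.na(pos_col) || !"chrom" %in% names(reads)) {
    abort("`reads` must have columns `chrom` and `pos` (or `start`)")
  }
  if (bin_width < 1L) abort("`bin_width` must be at least 1")
  pos <- reads[[pos_col]]
  if (any(pos < 0 | pos >= chrom_length)) {
    abort(sprintf(
      "%d read position(s) fall outside [0, %d)",
      sum(pos < 0 | pos >= chrom_length), as.integer(chrom_length)
    ))
  }
  chroms <- unique(as.character(reads$chrom))
  if (length(chroms) > 1L) abort("`reads` must be on a single chromosome")
  chrom <- if (length(chroms)) chroms else "chr"

  n_bins <- chrom_length %/% bin_width
  if (n_bins < 1L) abort("`chrom_length` shorter than one bin")
  idx <- pos %/% bin_width + 1L
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  starts <- (seq_len(n_bins) - 1L) * bin_width
  keep <- rep(TRUE, n_bins)

  if (!is.null(excluded) && nrow(excluded) > 0L) {
    excl <- as_regions(excluded)
    other <- setdiff(unique(excl$chrom), chrom)
    if (length(other)) {
      warn(sprintf(
        "excluded regions on unknown chromosome(s) ignored: %s",
        paste(other, collapse = ", ")
      ))
    }
    excl <- excl[excl$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(excl))) {
      # bin [s, s + w) overlaps [a, b) iff s < b and a < s + w
      keep <- keep & !(starts < excl$end[k] & excl$start[k] < starts + bin_width)
    }
  }

  out <- tibble(
    chrom = chrom,
    start = starts[keep],
    end = starts[keep] + bin_width,
    count = as.double(counts[keep])
  )
  attr(out, "bin_width") <- as.integer(bin_width)
  out
}

#' Read and write bin-count tables
#'
#' Count tables are headered tab-separated text with either a single
#' `count` column or columns `chrom`, `start`, `count` (plus optional
#' `end`).  Writing then reading reproduces the table.
#'
#' @param path File path.
#' @param counts A count table (see [as_counts()]).
#' @return `read_counts()` returns a tibble with a `count` column.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(out) == 1L && !"count" %in% names(out)) names(out) <- "count"
  if (any(out$count < 0)) abort("negative count in count table")
  as_counts(out)
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(as_counts(counts), path, progress = FALSE)
  invisible(path)
}
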