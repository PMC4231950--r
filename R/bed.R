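#' Genomic region sets (BED3)
#'
#' Regions are plain tibbles with columns `chrom`, `start`, `end` in the
#' BED convention: 0-based, half-open `[start, end)`.  `as_regions()`
#' validates and normalises (sorts and merges overlapping or book-ended
#' intervals per chromosome), so a region set is always non-overlapping.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`.
#' @return A normalised tibble of regions.
#' @export
as_regions <- function(x) {
  if (!is.data.frame(x)) abort("regions must be a data frame")
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) abort("regions need columns chrom, start, end")
  out <- as_tibble(x)[need]
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  if (any(out$start >= out$end)) abort("every region must satisfy start < end")
  if (any(out$start < 0)) abort("region starts must be non-negative")
  out$chrom <- as.character(out$chrom)
  merge_regions(out)
}

# sort and merge overlapping/adjacent intervals within each chromosome
merge_regions <- function(regions) {
  regions |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_block = .data$start > dplyr::lag(cummax(.data$end), default = -Inf),
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read and write BED3 interval files
#'
#' Three-column BED: tab-separated `chrom`, `start`, `end` with 0-based
#' half-open coordinates and no header.  Overlapping intervals are merged
#' on load.  A malformed line raises an error naming the line number.
#'
#' @param path File path.
#' @param regions A region tibble (see [as_regions()]).
#' @return `read_bed()` returns a normalised region tibble; an empty file
#'   yields an empty region set.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(as_regions(tibble(chrom = character(), start = double(), end = double())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(f, i) {
    if (length(f) < 3L) {
      abort(sprintf("malformed BED line %d: expected at least 3 tab-separated fields", i))
    }
    st <- suppressWarnings(as.numeric(f[2L]))
    en <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(st) || is.na(en) || st < 0 || st >= en) {
      abort(sprintf("malformed BED line %d: need 0 <= start < end", i))
    }
    tibble(chrom = f[1L], start = st, end = en)
  }
  out <- purrr::imap(fields, parse_one) |> purrr::list_rbind()
  as_regions(out)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  out <- as_regions(regions)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
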