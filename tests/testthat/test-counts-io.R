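test_that("bin_reads tiles the chromosome and assigns reads to bins", {
  reads <- tibble::tibble(chrom = "chr1", pos = c(5, 105, 110))
  out <- bin_reads(reads, chrom_length = 300, bin_width = 100)
  expect_equal(out$count, c(1, 2, 0))
  expect_equal(out$start, c(0, 100, 200))
  expect_equal(out$end, c(100, 200, 300))
  expect_equal(attr(out, "bin_width"), 100L)
})

test_that("bins overlapping an excluded region are dropped, not zeroed", {
  reads <- tibble::tibble(chrom = "chr1", pos = 5)
  excl <- tibble::tibble(chrom = "chr1", start = 0, end = 50)
  out <- bin_reads(reads, chrom_length = 300, bin_width = 100, excluded = excl)
  expect_equal(out$count, c(0, 0))
  expect_equal(out$start, c(100, 200))
  # a 1 bp overlap is enough to drop a bin
  excl2 <- tibble::tibble(chrom = "chr1", start = 99, end = 101)
  out2 <- bin_reads(reads, chrom_length = 300, bin_width = 100, excluded = excl2)
  expect_equal(out2$start, 200)
})

test_that("binning conserves reads and is invariant to read order", {
  n_reads <- 10000L
  pos <- withr::with_seed(99L, sort(floor(runif(n_reads, 0, 1e6))))
  reads <- tibble::tibble(chrom = "chr1", pos = pos)
  out <- bin_reads(reads, chrom_length = 1e6, bin_width = 100)
  expect_equal(sum(out$count), n_reads)
  shuffled <- reads[withr::with_seed(100L, sample(n_reads)), ]
  expect_equal(bin_reads(shuffled, 1e6, 100), out)
  # a final partial bin is dropped together with its reads
  out2 <- bin_reads(reads, chrom_length = 1e6 + 50, bin_width = 100)
  expect_equal(sum(out2$count), n_reads)
  expect_equal(nrow(out2), 10000L)
})

test_that("bin_reads validates its input", {
  reads <- tibble::tibble(chrom = "chr1", pos = c(5, 400))
  expect_error(bin_reads(reads, chrom_length = 300, bin_width = 100), "outside")
  expect_warning(
    bin_reads(
      tibble::tibble(chrom = "chr1", pos = 5), 300, 100,
      excluded = tibble::tibble(chrom = "chrX", start = 0, end = 10)
    ),
    "unknown chromosome"
  )
  expect_error(
    bin_reads(tibble::tibble(chrom = c("chr1", "chr2"), pos = c(1, 1)), 300, 100),
    "single chromosome"
  )
})

test_that("BED round trip reproduces the region set, merging on load", {
  path <- withr::local_tempfile(fileext = ".bed")
  reg <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
  write_bed(reg, path)
  expect_equal(read_bed(path), as_regions(reg))

  # overlapping and book-ended intervals merge to a normalised set
  messy <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(10, 15, 30, 0),
    end = c(20, 30, 40, 5)
  )
  write_bed(messy, path)
  merged <- read_bed(path)
  expect_equal(merged$start, c(10, 0))
  expect_equal(merged$end, c(40, 5))
})

test_that("empty and malformed BED files are handled", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), path)
  expect_equal(nrow(read_bed(path)), 0L)
  writeLines(c("chr1\t1\t10", "chr1\t20"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t30\t10"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("count tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(c(0, 3, 1), path)
  expect_equal(read_counts(path)$count, c(0, 3, 1))

  binned <- bin_reads(tibble::tibble(chrom = "c", pos = c(5, 105)), 300, 100)
  write_counts(binned, path)
  back <- read_counts(path)
  expect_equal(back$count, binned$count)
  expect_equal(back$start, binned$start)

  readr::write_tsv(tibble::tibble(count = c(1, -2)), path)
  expect_error(read_counts(path), "negative")
})

test_that("count validation enforces the invariants", {
  expect_error(as_counts(c(1, -1)), "non-negative")
  expect_error(as_counts(c(1, 1.5)), "integer")
  expect_error(as_counts(numeric()), "empty")
  bad <- tibble::tibble(start = c(0, 100, 150), count = c(1, 2, 3))
  expect_error(as_counts(bad, bin_width = 100), "whole-bin")
})
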