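test_that("half-open overlap convention holds, including bookended intervals", {
  iv <- function(chrom, s, e, build = "hg38") genome_intervals(chrom, s, e, build)
  expect_true(interval_overlaps(iv("chr1", 0, 10), iv("chr1", 9, 20)))
  expect_false(interval_overlaps(iv("chr1", 0, 10), iv("chr1", 10, 20)))
  expect_false(interval_overlaps(iv("chr1", 0, 10), iv("chr2", 0, 10)))
  # symmetric
  expect_equal(interval_overlaps(iv("chr1", 5, 15), iv("chr1", 0, 10)),
               interval_overlaps(iv("chr1", 0, 10), iv("chr1", 5, 15)))
  # mismatched builds never silently FALSE
  expect_error(interval_overlaps(iv("chr1", 0, 10), iv("chr1", 0, 10, "hg19")),
               "build")
})

test_that("interval invariants are enforced at construction", {
  expect_error(genome_intervals("chr1", 10, 10, "hg38"), "start >= end")
  expect_error(genome_intervals("chr1", -1, 10, "hg38"), "negative")
  expect_error(genome_intervals("", 0, 10, "hg38"), "chromosome")
  expect_error(genome_intervals("chr1", 0, 10, "mm10"), "build")
})

test_that("merge_collapse unions overlapping and bookended intervals with provenance", {
  x <- genome_intervals("chr1", c(1, 50), c(100, 150), "hg38",
                        provenance = list("a|t1", "b|t2"))
  m <- merge_collapse(x)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 150))
  expect_equal(m$provenance[[1]], c("a|t1", "b|t2"))

  # bookended pair merges at gap = 0 (bedtools-merge default)
  b <- merge_collapse(genome_intervals("chr1", c(0, 10), c(10, 20), "hg38"))
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(0, 20))

  expect_equal(nrow(merge_collapse(genome_intervals(character(0), numeric(0),
                                                    numeric(0), character(0)))), 0)
  expect_error(merge_collapse(genome_intervals("chr1", c(0, 0), c(5, 5),
                                               c("hg19", "hg38"))), "build")
})

test_that("merge_collapse preserves per-base coverage, is idempotent and order-invariant", {
  set.seed(11)
  for (rep in 1:25) {
    x <- random_interval_set(sample.int(60, 1))
    m <- merge_collapse(x)
    expect_true(same_coverage(x, m, c("chr1", "chr2"), 1e5))
    expect_true(all(m$start[-1] >= m$start[-nrow(m)] | m$chrom[-1] != m$chrom[-nrow(m)]))
    # pairwise disjoint, non-bookended per chromosome
    by_chrom <- split(m, m$chrom)
    for (b in by_chrom) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
    expect_equal(merge_collapse(m), m)
    shuffled <- x[sample.int(nrow(x)), ]
    expect_equal(merge_collapse(shuffled), m)
  }
})

test_that("merge_collapse honours a positive gap tolerance", {
  x <- genome_intervals("chr1", c(0, 15), c(10, 25), "hg38")
  expect_equal(nrow(merge_collapse(x, gap = 4)), 2)
  expect_equal(nrow(merge_collapse(x, gap = 5)), 1)
})

test_that("interval_intersect matches per-base intersection on random sets", {
  set.seed(13)
  for (rep in 1:10) {
    a <- random_interval_set(30)
    b <- random_interval_set(30)
    got <- interval_intersect(a, b)
    ca <- coverage_vector(a, c("chr1", "chr2"), 1e5)
    cb <- coverage_vector(b, c("chr1", "chr2"), 1e5)
    want <- Map(`&`, ca, cb)
    expect_identical(coverage_vector(got, c("chr1", "chr2"), 1e5), want)
  }
})

test_that("BED round-trip preserves coordinates and provenance, sorted", {
  x <- genome_intervals("chr1", c(500, 100, 300), c(600, 200, 400), "hg38",
                        provenance = list("FANTOM_enh|pancreas",
                                          c("ENCODE_tfbs|liver", "FANTOM_enh|pancreas"),
                                          character(0)))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, p)
  back <- read_bed(p, build = "hg38")
  expect_equal(back$start, c(100, 300, 500))
  expect_equal(back$provenance[[3]], "FANTOM_enh|pancreas")
  expect_equal(back$provenance[[2]], character(0))
  # read . write . read is identity
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("read_bed reports malformed lines with their line number and accepts gzip", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200", "chr1\tfoo\t300"), p)
  expect_error(read_bed(p, "hg38"), "line 3")
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), p)
  expect_error(read_bed(p, "hg38"), "line 2.*start >= end")

  gz <- withr::local_tempfile(fileext = ".bed.gz")
  con <- gzfile(gz, "wt"); writeLines("chr1\t100\t200\tds|t", con); close(con)
  got <- read_bed(gz, "hg38")
  expect_equal(got$end, 200)
  expect_equal(got$provenance[[1]], "ds|t")
})

test_that("chromosome names are normalized at load time by default", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "chr2\t10\t20"), p)
  expect_equal(read_bed(p, "hg38")$chrom, c("chr1", "chr2"))
  expect_equal(read_bed(p, "hg38", normalize_chrom = FALSE)$chrom, c("1", "chr2"))
})

test_that("write_bed can emit a UCSC custom-track header", {
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(genome_intervals("chr1", 0, 5, "hg38"), p, ucsc_track_header = "my track")
  expect_equal(readLines(p)[1], 'track name="my track"')
})
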