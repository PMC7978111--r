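test_that("registration collapses on ingest and guards duplicate keys", {
  store <- track_store("hg38")
  iv <- genome_intervals("chr1", c(100, 150), c(200, 260), "hg38")
  store <- register_track(store, iv, "FANTOM_enh", "pancreas", "enhancer")
  tr <- store$tracks$intervals[[1]]
  expect_equal(nrow(tr), 1)
  expect_equal(c(tr$start, tr$end), c(100, 260))
  expect_equal(tr$provenance[[1]], "FANTOM_enh|pancreas")

  expect_error(register_track(store, iv, "FANTOM_enh", "pancreas", "enhancer"),
               "already registered")
  store <- register_track(store, iv[1, ], "FANTOM_enh", "pancreas", "enhancer",
                          replace = TRUE)
  expect_equal(nrow(store$tracks), 1)
  expect_error(register_track(store, iv, "x", "y", "nonsense"), "class")
})

test_that("tissue availability groups tissues by covered classes", {
  store <- track_store("hg38")
  iv <- genome_intervals("chr1", 0, 10, "hg38")
  store <- register_track(store, iv, "ds1", "pancreas", "enhancer")
  store <- register_track(store, iv, "ds1", "liver", "enhancer")
  store <- register_track(store, iv, "ds2", "pancreas", "promoter")
  av <- available_tissues(store)
  expect_equal(nrow(av), 2)
  expect_equal(av$classes[av$tissue == "pancreas"], "enhancer,promoter")
  expect_equal(available_tissues(store, cls = "promoter")$tissue, "pancreas")
})

test_that("replicate collapse unions coverage and rejects mixed keys", {
  mk <- function(s, e) tibble::tibble(
    dataset = "ds", tissue = "t", cls = "enhancer", build = "hg38",
    intervals = list(genome_intervals("chr1", s, e, "hg38")))
  reps <- dplyr::bind_rows(mk(0, 100), mk(50, 150))
  out <- collapse_replicates(reps)
  expect_equal(nrow(out), 1)
  got <- out$intervals[[1]]
  expect_equal(c(got$start, got$end), c(0, 150))

  disj <- dplyr::bind_rows(mk(200, 300), mk(0, 100))
  got2 <- collapse_replicates(disj)$intervals[[1]]
  expect_equal(got2$start, c(0, 200))

  one <- mk(5, 10)
  expect_equal(collapse_replicates(one)$intervals[[1]]$start, 5)

  mixed <- dplyr::bind_rows(mk(0, 10), dplyr::mutate(mk(0, 10), tissue = "u"))
  expect_error(collapse_replicates(mixed), "mixed")

  # span never grows: union <= sum of parts, equality iff disjoint
  sum_span <- sum(purrr::map_dbl(reps$intervals, total_span))
  expect_lt(total_span(out$intervals[[1]]), sum_span)
  expect_equal(total_span(collapse_replicates(disj)$intervals[[1]]),
               sum(purrr::map_dbl(disj$intervals, total_span)))
})

test_that("CAGE promoter derivation applies the strict TPM cut and 200 bp upstream extension", {
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(1000, 3000, 5000), end = c(1010, 3010, 5010),
    strand = c("+", "+", "-"), tpm = c(12, 9.99, 10),
    sample = "pancreas", build = "hg38")
  out <- promoters_from_cage(peaks)
  expect_equal(nrow(out), 2)             # tpm 9.99 dropped ("below 10")
  expect_equal(c(out$start[1], out$end[1]), c(800, 1010))   # "+" extends left
  expect_equal(c(out$start[2], out$end[2]), c(5000, 5210))  # "-" extends right; tpm 10 kept
  expect_equal(out$end - out$start, rep(10 + 200, 2))

  clamp <- promoters_from_cage(tibble::tibble(
    chrom = "chr1", start = 50, end = 60, strand = "+", tpm = 20,
    sample = "s", build = "hg38"))
  expect_equal(clamp$start, 0)

  bad <- peaks; bad$strand <- NA_character_
  expect_error(promoters_from_cage(bad), "strand")
})

test_that("CAGE output span matches a per-base oracle on random peak sets", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    s <- sample.int(5e4, n) + 500
    peaks <- tibble::tibble(chrom = "chr1", start = s, end = s + sample.int(50, n),
                            strand = sample(c("+", "-"), n, replace = TRUE),
                            tpm = stats::runif(n, 0, 20), sample = "s", build = "hg38")
    out <- promoters_from_cage(peaks)
    surv <- peaks[peaks$tpm >= 10, ]
    ext <- tibble::tibble(
      chrom = surv$chrom,
      start = pmax(0, ifelse(surv$strand == "+", surv$start - 200, surv$start)),
      end = ifelse(surv$strand == "+", surv$end, surv$end + 200),
      build = "hg38")
    expect_true(same_coverage(out, ext, "chr1", 1e5))
  }
})

test_that("CAGE peak tables read back with the expected columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", start = 100, end = 120,
                                  strand = "+", tpm = 11.5, sample = "liver"), p)
  peaks <- read_cage_peaks(p, "hg19")
  expect_equal(peaks$build, "hg19")
  expect_equal(nrow(promoters_from_cage(peaks)), 1)
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", start = 1, end = 2), bad)
  expect_error(read_cage_peaks(bad, "hg19"), "missing column")
})

test_that("ccRE splitting respects annotation tokens and reports skips", {
  x <- genome_intervals("chr1", c(0, 10, 20, 30), c(5, 15, 25, 35), "hg38")
  x$name <- c("promoter-like", "PLS", "dELS", "weird")
  expect_message(out <- split_ccres(x), "skipped 1")
  expect_equal(out$cls, c("enhancer", "promoter"))
  expect_equal(out$n_records, c(1L, 2L))
  expect_equal(attr(out, "skipped") + sum(out$n_records), nrow(x))

  allbad <- x; allbad$name <- "???"
  expect_error(split_ccres(allbad), "class token")
  expect_error(split_ccres(x[0, ]), "empty")
})

test_that("track summaries compute counts, mean size and span on collapsed intervals", {
  s <- summarize_track(genome_intervals("chr1", c(0, 200), c(100, 250), "hg38"))
  expect_equal(unlist(s), c(region_count = 2, mean_size_bp = 75, total_span_bp = 150))
  s1 <- summarize_track(genome_intervals("chr1", 7, 8, "hg38"))
  expect_equal(unlist(s1), c(region_count = 1, mean_size_bp = 1, total_span_bp = 1))
  s2 <- summarize_track(genome_intervals("chr1", c(0, 10), c(10, 20), "hg38"))
  expect_equal(s2$region_count, 1)
})

test_that("a store round-trips through its YAML manifest", {
  dir <- withr::local_tempdir()
  write_bed(genome_intervals("chr1", c(10, 400), c(120, 480), "hg38"),
            file.path(dir, "a.bed"))
  write_bed(genome_intervals("chr1", 50, 90, "hg38"), file.path(dir, "b.bed"))
  yaml::write_yaml(list(build = "hg38", tracks = list(
    list(dataset = "ds1", tissue = "pancreas", class = "enhancer", path = "a.bed"),
    list(dataset = "ds1", tissue = "liver", class = "enhancer", path = "b.bed")
  )), file.path(dir, "store.yaml"))
  store <- build_store(file.path(dir, "store.yaml"))
  expect_equal(nrow(store$tracks), 2)
  td <- tidy(store)
  expect_equal(td$region_count, c(2, 1))
  g <- glance(store)
  expect_equal(g$n_tissues, 2)
})

test_that("merge_collapse agrees with IRanges::reduce as an independent cross-check", {
  skip_if_not_installed("IRanges")
  set.seed(31)
  x <- random_interval_set(120, chroms = "chr1")
  got <- merge_collapse(x)
  ir <- IRanges::reduce(IRanges::IRanges(start = x$start + 1, end = x$end))
  expect_equal(got$start, BiocGenerics::start(ir) - 1)
  expect_equal(got$end, as.numeric(BiocGenerics::end(ir)))
})
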