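# A hand-built micro-store around one "+" gene at chr8:[11000,20000)
micro_setup <- function() {
  reg <- mini_registry("BLK", "chr8", "+", 11000, 20000, build = "hg38")
  store <- track_store("hg38")
  # region near the TSS, active in tissue A only; tissue B has an unrelated region
  store <- register_track(store, genome_intervals("chr8", 10500, 10900, "hg38"),
                          "ds", "A", "enhancer")
  store <- register_track(store, genome_intervals("chr8", 300000, 300400, "hg38"),
                          "ds", "B", "enhancer")
  list(reg = reg, store = store)
}

test_that("active-in-any keeps a region present in a single target tissue, with provenance", {
  ms <- micro_setup()
  q <- search_query("hg38", "BLK", c("A", "B"),
                    dataset_config("ds", 5000, 1000, "any"))
  got <- search_cis(ms$store, ms$reg, "ds", q)
  expect_equal(nrow(got), 1)
  expect_equal(got$provenance[[1]], "ds|A")
})

test_that("active-in-all excludes a region absent from an available tissue track", {
  ms <- micro_setup()
  q <- search_query("hg38", "BLK", c("A", "B"),
                    dataset_config("ds", 5000, 1000, "all"))
  got <- search_cis(ms$store, ms$reg, "ds", q)
  expect_equal(nrow(got), 0)
})

test_that("active-in-all quantifies only over available tissue tracks", {
  ms <- micro_setup()
  # tissue C has no track in this dataset: it must not veto
  q <- search_query("hg38", "BLK", c("A", "C"),
                    dataset_config("ds", 5000, 1000, "all"))
  expect_warning(got <- search_cis(ms$store, ms$reg, "ds", q), "C")
  expect_equal(nrow(got), 1)
  expect_error(search_cis(ms$store, ms$reg, "nosuchds", q), "unknown dataset")
})

test_that("run_search composes, merges and keeps cross-dataset provenance", {
  ms <- micro_setup()
  # second dataset overlapping the tissue-A region
  store <- register_track(ms$store, genome_intervals("chr8", 10700, 11100, "hg38"),
                          "ds2", "A", "promoter")
  q <- search_query("hg38", "BLK", "A",
                    dplyr::bind_rows(dataset_config("ds", 5000, 1000, "any"),
                                     dataset_config("ds2", 5000, 1000, "any")))
  res <- run_search(store, ms$reg, q)
  expect_s3_class(res, "search_result")
  expect_equal(res$stats$region_count, 1)      # overlapping regions merged
  expect_setequal(res$intervals$provenance[[1]], c("ds2|A", "ds|A"))
  expect_equal(res$stats$total_span_bp, 11100 - 10500)

  # degenerate composition: one dataset, one tissue == collapse(search_cis)
  q1 <- search_query("hg38", "BLK", "A", dataset_config("ds", 5000, 1000, "any"))
  res1 <- run_search(store, ms$reg, q1)
  expect_equal(res1$intervals[, c("chrom", "start", "end")],
               merge_collapse(search_cis(store, ms$reg, "ds", q1))[, c("chrom", "start", "end")])

  expect_error(run_search(store, ms$reg,
                          search_query("hg38", "NOSUCH", "A",
                                       dataset_config("ds", 5000, 1000))),
               "no query gene")
  expect_error(run_search(store, ms$reg,
                          search_query("hg38", "BLK", "Z",
                                       dataset_config("ds", 5000, 1000))),
               "no track")
})

test_that("query invariants are enforced", {
  expect_error(search_query("hg38", character(0), "A", dataset_config("ds")), "gene")
  expect_error(search_query("hg38", "BLK", character(0), dataset_config("ds")), "tissue")
  expect_error(search_query("hg38", "BLK", "A"), "dataset or the miRNA")
  expect_error(dataset_config("ds", mode = "sometimes"), "arg")
})

test_that("results export to table, BED and a 1-based UCSC position payload", {
  ms <- micro_setup()
  store <- register_track(ms$store, genome_intervals("chr8", 10600, 11000, "hg38"),
                          "ds", "C", "enhancer")
  q <- search_query("hg38", "BLK", c("A", "C"), dataset_config("ds", 5000, 1000, "any"))
  res <- run_search(store, ms$reg, q)
  out <- result_to_outputs(res, bed_path = withr::local_tempfile(fileext = ".bed"))
  # one merged interval supported by two (dataset, tissue) pairs -> 2 table rows
  expect_equal(nrow(out$table), 2)
  expect_equal(sort(out$table$tissue), c("A", "C"))
  expect_equal(out$ucsc$position, "chr8:10501-11000")
  bed <- readLines(out$bed_path)
  expect_match(bed[1], "^track name=")
  expect_equal(length(bed), 2)

  # empty result -> valid empty outputs, not an error
  qa <- search_query("hg38", "BLK", "B", dataset_config("ds", 5000, 1000, "any"))
  res0 <- run_search(store, ms$reg, qa)
  out0 <- result_to_outputs(res0, bed_path = withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(out0$table), 0)
  expect_equal(readLines(out0$bed_path), 'track name="regusearch"')
})

test_that("display position uses 1-based inclusive coordinates", {
  reg <- mini_registry("BLK", "chr8", "+", 11000, 20000, build = "hg38")
  store <- track_store("hg38")
  store <- register_track(store, genome_intervals("chr8", 11000, 20000, "hg38"),
                          "ds", "A", "enhancer")
  q <- search_query("hg38", "BLK", "A", dataset_config("ds", 0, 0, "any"))
  res <- run_search(store, reg, q)
  expect_equal(result_to_outputs(res)$ucsc$position, "chr8:11001-20000")
})

test_that("run_search matches the literal brute-force oracle on toy stores", {
  m <- toy_mirna()
  reg <- toy_registry()
  for (seed in c(101, 202)) {
    store <- toy_store(seed)
    for (mode in c("any", "all")) {
      q <- search_query("hg38", c("GENA", "GENB"), c("t1", "t3"),
                        dplyr::bind_rows(dataset_config("ds1", 4000, 1000, mode),
                                         dataset_config("ds2", 2000, 500, mode)),
                        mirna = list(source = "both"))
      got <- suppressWarnings(run_search(store, reg, q,
                                         interactions = m$interactions,
                                         mirna_loci = m$loci))
      want <- brute_search_regions(store, reg, q,
                                   interactions = m$interactions, loci = m$loci)
      expect_true(same_coverage(got$intervals, want, c("chrS1", "chrS2"), 1e5))
    }
  }
})

test_that("tidy/glance expose the traceability table and summary", {
  ms <- micro_setup()
  q <- search_query("hg38", "BLK", c("A", "B"), dataset_config("ds", 5000, 1000, "any"))
  res <- run_search(ms$store, ms$reg, q)
  td <- tidy(res)
  expect_named(td, c("chrom", "start", "end", "build", "dataset", "tissue"))
  g <- glance(res)
  expect_equal(g$region_count, 1)
  expect_equal(g$n_tissues, 1)
  expect_s3_class(autoplot(res), "ggplot")
})
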