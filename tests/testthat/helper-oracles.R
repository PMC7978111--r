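# Independent brute-force oracles and tiny in-memory fixtures.
# The oracles never call the interval engine they check: coverage is
# enumerated base by base, and the search oracle re-applies the selection
# conditions literally with its own window arithmetic.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# per-base membership over bases 0..max_coord-1, one logical vector per chrom
coverage_vector <- function(x, chroms, max_coord) {
  out <- lapply(stats::setNames(chroms, chroms), function(cc) logical(max_coord))
  for (i in seq_len(nrow(x))) {
    cc <- x$chrom[i]
    if (!cc %in% chroms) next
    lo <- x$start[i] + 1
    hi <- min(x$end[i], max_coord)
    if (lo <= hi) out[[cc]][lo:hi] <- TRUE
  }
  out
}

same_coverage <- function(a, b, chroms, max_coord) {
  identical(coverage_vector(a, chroms, max_coord),
            coverage_vector(b, chroms, max_coord))
}

random_interval_set <- function(n, max_coord = 1e5, chroms = c("chr1", "chr2"),
                                build = "hg38", max_width = 500) {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- sample.int(max_coord - max_width, n, replace = TRUE) - 1
  genome_intervals(sample(chroms, n, replace = TRUE), s, s + w, build,
                   provenance = lapply(seq_len(n), function(i) {
                     sprintf("ds%d|t%d", sample.int(3, 1), sample.int(3, 1))
                   }))
}

# ---- toy store + registry for search-oracle checks -------------------------

toy_registry <- function(build = "hg38") {
  reg <- tibble(
    gene = c("GENA", "GENA", "GENB", "GENC"),
    tx_id = c("NM_a1", "NM_a2", "NM_b1", "NM_c1"),
    chrom = c("chrS1", "chrS1", "chrS1", "chrS2"),
    strand = c("+", "+", "-", "+"),
    tx_start = c(30000, 31000, 62000, 40000),
    tx_end = c(45000, 44000, 78000, 52000),
    build = build
  )
  class(reg) <- c("transcript_registry", class(reg))
  reg
}

toy_store <- function(seed, n_regions_per_track = 40, build = "hg38") {
  set.seed(seed)
  store <- track_store(build)
  datasets <- tibble(dataset = c("ds1", "ds2", "ds3"),
                     cls = c("enhancer", "promoter", "accessible_chromatin"))
  for (d in seq_len(nrow(datasets))) {
    for (tis in c("t1", "t2", "t3", "t4")) {
      iv <- random_interval_set(n_regions_per_track, max_coord = 1e5,
                                chroms = c("chrS1", "chrS2"), build = build)
      iv$provenance <- rep(list(character(0)), nrow(iv))
      store <- register_track(store, iv, dataset = datasets$dataset[d],
                              tissue = tis, cls = datasets$cls[d])
    }
  }
  store
}

toy_mirna <- function(build = "hg38") {
  loci <- tibble(chrom = c("chrS1", "chrS1", "chrS2"),
                 start = c(5000, 90000, 5000), end = c(5080, 90080, 5080),
                 build = build,
                 provenance = rep(list(character(0)), 3),
                 mirna_id = c("mir-1", "mir-2", "mir-3"))
  interactions <- tibble(mirna_id = c("mir-1", "mir-2", "mir-3"),
                         gene = c("GENA", "GENB", "GENB"),
                         source = "experimental",
                         evidence = "strong", region = NA_character_)
  list(loci = loci, interactions = interactions)
}

# literal re-check of the selection protocol, with its own window arithmetic
brute_search_regions <- function(store, registry, query,
                                 interactions = NULL, loci = NULL) {
  ov1 <- function(tab, chrom, s, e) {
    any(tab$chrom == chrom & pmax(tab$start, s) < pmin(tab$end, e))
  }
  picked <- list()
  for (k in seq_len(nrow(query$datasets))) {
    cfg <- query$datasets[k, ]
    tracks <- store$tracks[store$tracks$dataset == cfg$dataset &
                             store$tracks$tissue %in% query$tissues, ]
    if (nrow(tracks) == 0) next
    tx <- registry[toupper(registry$gene) %in% toupper(query$genes), ]
    tss <- ifelse(tx$strand == "+", tx$tx_start, tx$tx_end - 1)
    wins <- tibble(
      chrom = tx$chrom,
      start = pmax(0, ifelse(tx$strand == "+", tss - cfg$upstream_bp,
                             tss - cfg$downstream_bp)),
      end = ifelse(tx$strand == "+", tss + cfg$downstream_bp + 1,
                   tss + cfg$upstream_bp + 1)
    )
    regions <- bind_rows(tracks$intervals)
    for (i in seq_len(nrow(regions))) {
      R <- regions[i, ]
      cond1 <- ov1(wins, R$chrom, R$start, R$end)
      if (!cond1) next
      present <- vapply(seq_len(nrow(tracks)), function(j) {
        ov1(tracks$intervals[[j]], R$chrom, R$start, R$end)
      }, logical(1))
      cond2 <- if (cfg$mode == "any") any(present) else all(present)
      if (cond2) picked[[length(picked) + 1]] <-
          R[, c("chrom", "start", "end", "build")]
    }
  }
  if (!is.null(query$mirna) && !is.null(interactions) && !is.null(loci)) {
    ia <- interactions[toupper(interactions$gene) %in% toupper(query$genes), ]
    chrom_tracks <- store$tracks[store$tracks$cls == "accessible_chromatin" &
                                   store$tracks$tissue %in% query$tissues, ]
    for (id in unique(ia$mirna_id)) {
      lc <- loci[loci$mirna_id == id, ]
      if (nrow(lc) == 0) next
      for (i in seq_len(nrow(lc))) {
        open <- any(vapply(chrom_tracks$intervals, function(tr) {
          ov1(tr, lc$chrom[i], lc$start[i], lc$end[i])
        }, logical(1)))
        if (open) picked[[length(picked) + 1]] <-
            lc[i, c("chrom", "start", "end", "build")]
      }
    }
  }
  out <- bind_rows(picked)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  build = character(0))
  }
  out$provenance <- rep(list(character(0)), nrow(out))
  out
}

# brute-force VCF record filter: parse the file independently, loop regions
brute_vcf_keep <- function(vcf_path, regions) {
  lines <- readLines(vcf_path, warn = FALSE)
  recs <- lines[!grepl("^#", lines)]
  vapply(recs, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    pos <- as.numeric(f[2])
    ref <- f[4]; alt <- f[5]
    width <- if (grepl("^<", alt) || grepl("\\[|\\]", alt)) 1 else nchar(ref)
    s <- pos - 1; e <- s + width
    hit <- FALSE
    for (i in seq_len(nrow(regions))) {
      if (regions$chrom[i] == f[1] && max(regions$start[i], s) < min(regions$end[i], e)) {
        hit <- TRUE; break
      }
    }
    hit
  }, logical(1), USE.NAMES = FALSE)
}

mini_registry <- function(gene, chrom, strand, tx_start, tx_end, build = "hg38",
                          tx_id = NULL) {
  n <- length(tx_start)
  reg <- tibble(gene = rep_len(gene, n),
                tx_id = tx_id %||% sprintf("NM_%d", seq_len(n)),
                chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                tx_start = tx_start, tx_end = tx_end,
                build = rep_len(build, n))
  class(reg) <- c("transcript_registry", class(reg))
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
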