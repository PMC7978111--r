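#' Specification for a synthetic regulatory-genomics fixture
#'
#' Describes a fully seeded synthetic dataset: a transcript table, a track
#' store with planted tissue-specific regulators plus random decoys, miRNA
#' interaction tables and loci, a patient VCF with in-regulator and
#' out-of-regulator variants, an evaluation case table, and a truth table
#' recording for every planted variant the minimal query that must recover
#' it and a query that must not. Coordinates live on synthetic chromosomes
#' (`chrS1`, `chrS2`, ...) so no real genomic positions are implied; the
#' build tag only selects the coordinate-system label.
#'
#' The defaults emulate the contrasts of real regulatory collections:
#' a sparse, narrow enhancer dataset; a medium-density promoter dataset;
#' and a dense, wide accessible-chromatin dataset — across 4 tissues and
#' 12 genes, with 12 evaluation cases of which 8 are recoverable by the
#' best-matching tissue, 2 only by the wider related-tissue set, and 2
#' only by the tissue-unselected control (regulators active solely in an
#' unrelated tissue).
#'
#' @param seed Integer RNG seed; fully determines the fixture.
#' @param build Genome build tag.
#' @param n_tissues Number of tissues (2–6; default 4).
#' @param n_genes Number of genes (>= number of cases).
#' @param chrom_length Length of each of the two synthetic chromosomes.
#' @param n_single,n_multi,n_unselected_only Case counts per recovery
#'   scope.
#' @param n_decoy_variants Out-of-regulator variants in the VCF.
#' @param upstream_bp,downstream_bp Search spans the planted regulators are
#'   placed within (and that the truth-table queries use).
#' @param datasets Tibble describing the datasets: `dataset`, `cls`,
#'   `decoy_n` (decoys per track), `w_min`, `w_max` (decoy widths).
#' @return A `fixture_spec` object (a validated list).
#' @export
fixture_spec <- function(seed = 1L,
                         build = "hg38",
                         n_tissues = 4,
                         n_genes = 12,
                         chrom_length = 5e6,
                         n_single = 8, n_multi = 2, n_unselected_only = 2,
                         n_decoy_variants = 30,
                         upstream_bp = 50000, downstream_bp = 50000,
                         datasets = NULL) {
  if (is.null(datasets)) {
    datasets <- tibble(
      dataset = c("FANTOM_enh", "SCREEN_prom", "ENCODE_chromatin"),
      cls = c("enhancer", "promoter", "accessible_chromatin"),
      decoy_n = c(40L, 80L, 150L),
      w_min = c(100, 150, 200),
      w_max = c(600, 350, 2000)
    )
  }
  n_cases <- n_single + n_multi + n_unselected_only
  if (n_genes < n_cases) abort("fixture needs at least as many genes as cases")
  if (n_tissues < 3) abort("fixture needs >= 3 tissues (best / related / unrelated)")
  if (!build %in% genome_builds()) abort("unsupported build")
  stopifnot(all(datasets$cls %in% regulator_classes()))
  structure(list(seed = as.integer(seed), build = build, n_tissues = n_tissues,
                 n_genes = n_genes, chrom_length = chrom_length,
                 n_single = n_single, n_multi = n_multi,
                 n_unselected_only = n_unselected_only,
                 n_decoy_variants = n_decoy_variants,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 datasets = datasets),
            class = "fixture_spec")
}

fixture_tissues <- function(n) {
  pool <- c("pancreas", "liver", "brain", "heart", "kidney", "lung")
  pool[seq_len(n)]
}

# uniform random intervals avoiding a set of reserved spans (with margin)
random_intervals <- function(n, chrom_lengths, w_min, w_max, avoid, margin = 1000) {
  out <- vector("list", n)
  chroms <- names(chrom_lengths)
  for (i in seq_len(n)) {
    repeat {
      chrom <- sample(chroms, 1)
      w <- sample(seq(w_min, w_max), 1)
      s <- sample.int(chrom_lengths[[chrom]] - w, 1)
      clash <- nrow(avoid) > 0 &&
        any(avoid$chrom == chrom & (avoid$start - margin) < (s + w) & s < (avoid$end + margin))
      if (!clash) break
    }
    out[[i]] <- tibble(chrom = chrom, start = s, end = s + w)
  }
  bind_rows(out)
}

#' Generate a synthetic fixture
#'
#' Materialises a [fixture_spec()] both in memory and on disk, writing the
#' exact file formats the rest of the package reads: a genePred-style gene
#' table, per-track BED files with a YAML store manifest, miRNA
#' interaction TSVs and a locus BED, a single-sample VCF, the evaluation
#' case CSV and the truth CSV. The same seed always yields byte-identical
#' files. The caller's RNG state is left untouched.
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Output directory (created if needed).
#' @return List with the in-memory objects (`registry`, `store`,
#'   `interactions`, `mirna_loci`, `cases`, `truth`, `plants`) and `paths`
#'   to every written file.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  build <- spec$build
  chrom_lengths <- c(chrS1 = spec$chrom_length, chrS2 = spec$chrom_length)
  tissues <- fixture_tissues(spec$n_tissues)
  n_cases <- spec$n_single + spec$n_multi + spec$n_unselected_only

  ## ---- genes: 1-3 transcripts each, both strands -------------------------
  per_chrom <- ceiling(spec$n_genes / length(chrom_lengths))
  gene_rows <- list()
  g <- 0
  for (chrom in names(chrom_lengths)) {
    k <- min(per_chrom, spec$n_genes - g)
    if (k == 0) break
    centers <- round(seq(4e5, chrom_lengths[[chrom]] - 4e5, length.out = max(k, 2)))[seq_len(k)]
    for (c0 in centers) {
      g <- g + 1
      span <- sample(10000:50000, 1)
      strand <- sample(c("+", "-"), 1)
      n_tx <- sample(1:3, 1)
      gstart <- c0 - round(span / 2)
      for (t in seq_len(n_tx)) {
        j1 <- sample(0:1000, 1); j2 <- sample(0:1000, 1)
        gene_rows[[length(gene_rows) + 1]] <- tibble(
          name = sprintf("NM_%04d.%d", g, t), chrom = chrom, strand = strand,
          txStart = gstart + j1, txEnd = gstart + span - j2,
          name2 = sprintf("GENE%02d", g)
        )
      }
    }
  }
  gene_tab <- bind_rows(gene_rows)
  gene_path <- file.path(out_dir, "genes.tsv")
  readr::write_tsv(gene_tab, gene_path)
  registry <- load_gene_table(gene_path, build)

  ## ---- cases and planted regulators --------------------------------------
  scopes <- c(rep("single", spec$n_single), rep("multi", spec$n_multi),
              rep("unselected", spec$n_unselected_only))
  categories <- rep(c("promoter", "intragenic", "distal"), length.out = n_cases)
  case_genes <- sprintf("GENE%02d", seq_len(n_cases))
  ds_cycle <- rep(spec$datasets$dataset, length.out = n_cases)

  plants <- list()   # planted regulator intervals with their tissues/dataset
  cases <- list()
  truth <- list()
  for (i in seq_len(n_cases)) {
    gene <- case_genes[i]
    tx <- transcripts_for(registry, gene)
    t1 <- tx[1, ]
    tss <- if (t1$strand == "+") t1$tx_start else t1$tx_end - 1
    # variant placement by target category (0-based base p)
    p <- switch(categories[i],
      promoter = {
        d <- sample(1:100, 1)
        if (t1$strand == "+") tss - d else tss + d
      },
      intragenic = floor((t1$tx_start + t1$tx_end) / 2),
      distal = {
        d <- sample(5000:30000, 1)
        up_of_all <- if (t1$strand == "+") min(tx$tx_start) else max(tx$tx_end) - 1
        if (t1$strand == "+") up_of_all - d else up_of_all + d
      }
    )
    # planted regulator containing the variant
    w <- sample(200:800, 1)
    off <- sample(20:(w - 20), 1)
    plant_start <- p - off
    plant_end <- plant_start + w

    best <- sample(tissues, 1)
    related <- sample(setdiff(tissues, best), min(2, spec$n_tissues - 2))
    unrelated_pool <- setdiff(tissues, c(best, related))
    unrelated <- sample(unrelated_pool, 1)
    plant_tissues <- switch(scopes[i],
      single = best,
      multi = related[1],
      unselected = unrelated
    )
    excluding <- switch(scopes[i],
      single = unrelated,
      multi = best,
      unselected = best
    )
    plants[[i]] <- tibble(chrom = t1$chrom, start = plant_start, end = plant_end,
                          dataset = ds_cycle[i],
                          tissue = list(plant_tissues), case = i)
    cases[[i]] <- tibble(chrom = t1$chrom, pos = p + 1, ref = "A", gene = gene,
                         best_tissue = best,
                         related_tissues = paste(related, collapse = ";"),
                         build = build)
    truth[[i]] <- tibble(case = i, chrom = t1$chrom, pos = p + 1, ref = "A",
                         gene = gene, category = categories[i],
                         dataset = ds_cycle[i],
                         plant_tissues = paste(plant_tissues, collapse = ";"),
                         best_tissue = best,
                         related_tissues = paste(related, collapse = ";"),
                         recover_scope = scopes[i],
                         excluding_tissue = excluding,
                         upstream_bp = spec$upstream_bp,
                         downstream_bp = spec$downstream_bp,
                         mode = "any",
                         plant_start = plant_start, plant_end = plant_end)
  }
  plants <- bind_rows(plants)
  cases <- bind_rows(cases)
  truth <- bind_rows(truth)

  ## ---- miRNA loci, interactions, and their chromatin support -------------
  mir_ids <- sprintf("hsa-mir-%d", 101:106)
  mir_chrom <- rep(names(chrom_lengths), length.out = length(mir_ids))
  mir_start <- round(seq(1.5e5, 2.5e5, length.out = length(mir_ids))) +
    ifelse(seq_along(mir_ids) %% 2 == 0, 60000, 0)
  mir_loci <- tibble(chrom = mir_chrom, start = mir_start,
                     end = mir_start + 80, build = build,
                     provenance = rep(list(character(0)), length(mir_ids)),
                     name = mir_ids, mirna_id = mir_ids)
  # mir-101 open in tissue 1; mir-102 open in tissue 2 only; others closed
  mir_support <- tibble(
    chrom = mir_loci$chrom[1:2],
    start = mir_loci$start[1:2] - 50, end = mir_loci$end[1:2] + 50,
    dataset = "ENCODE_chromatin", tissue = list(tissues[1], tissues[2]),
    case = NA_integer_
  )
  interactions_exp <- tibble(
    mirna_id = c("hsa-mir-101", "hsa-mir-102", "hsa-mir-103", "hsa-mir-101"),
    gene = c(case_genes[1], case_genes[2], case_genes[3], case_genes[1]),
    evidence = c("strong", "weak", "strong", "weak")
  )
  interactions_pred <- tibble(
    mirna_id = c("hsa-mir-104", "hsa-mir-105", "hsa-mir-106"),
    gene = c(case_genes[1], case_genes[2], case_genes[4]),
    evidence = "predicted",
    region = c("3UTR", "5UTR", "3UTR")
  )

  ## ---- track store: plants + decoys --------------------------------------
  reserved <- bind_rows(plants[, c("chrom", "start", "end")],
                        mir_support[, c("chrom", "start", "end")],
                        mir_loci[, c("chrom", "start", "end")])
  planted_all <- bind_rows(plants, mir_support)
  store <- track_store(build)
  track_dir <- file.path(out_dir, "tracks")
  if (!dir.exists(track_dir)) dir.create(track_dir)
  manifest <- list(build = build, tracks = list())
  for (d in seq_len(nrow(spec$datasets))) {
    ds <- spec$datasets$dataset[d]
    cls <- spec$datasets$cls[d]
    for (tis in tissues) {
      decoys <- random_intervals(spec$datasets$decoy_n[d], chrom_lengths,
                                 spec$datasets$w_min[d], spec$datasets$w_max[d],
                                 avoid = reserved)
      mine <- planted_all[planted_all$dataset == ds &
                            purrr::map_lgl(planted_all$tissue, \(tt) tis %in% tt), ]
      iv <- bind_rows(decoys, mine[, c("chrom", "start", "end")])
      iv$build <- build
      iv$provenance <- rep(list(character(0)), nrow(iv))
      iv <- arrange(iv, .data$chrom, .data$start, .data$end)
      bed_path <- file.path(track_dir, sprintf("%s__%s.bed", ds, tis))
      write_bed(iv, bed_path)
      store <- register_track(store, iv, dataset = ds, tissue = tis, cls = cls)
      manifest$tracks[[length(manifest$tracks) + 1]] <-
        list(dataset = ds, tissue = tis, class = cls,
             path = file.path("tracks", basename(bed_path)))
    }
  }
  manifest_path <- file.path(out_dir, "store.yaml")
  yaml::write_yaml(manifest, manifest_path)

  ## ---- VCF: case variants, edge-straddlers, out-of-regulator decoys ------
  all_regions <- merge_collapse(bind_rows(store$tracks$intervals))
  vcf_rows <- tibble(chrom = cases$chrom, pos = cases$pos, ref = cases$ref,
                     alt = "G", id = sprintf("case%02d", seq_len(nrow(cases))))
  p1 <- plants[1, ]
  straddle <- tibble(
    chrom = rep(p1$chrom, 3),
    pos = c(p1$start - 1, p1$start + 3, p1$start - 3),    # 1-based POS
    ref = c("AAAAA", "AAA", "AAAA"),                      # last one bookends the plant
    alt = c("A", "TTT", "A"),
    id = c("del_straddle", "mnv_inside", "del_bookended")
  )
  decoy_pos <- list()
  while (length(decoy_pos) < spec$n_decoy_variants) {
    chrom <- sample(names(chrom_lengths), 1)
    p <- sample.int(chrom_lengths[[chrom]] - 1, 1)
    r <- all_regions[all_regions$chrom == chrom, ]
    if (nrow(r) == 0 || !any(r$start < (p + 1) & p < r$end)) {
      decoy_pos[[length(decoy_pos) + 1]] <- tibble(chrom = chrom, pos = p + 1,
                                                   ref = "A", alt = "T",
                                                   id = sprintf("decoy%02d", length(decoy_pos) + 1))
    }
  }
  vcf_rows <- bind_rows(vcf_rows, straddle, bind_rows(decoy_pos)) |>
    arrange(.data$chrom, .data$pos)
  vcf_path <- file.path(out_dir, "variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE1",
    sprintf("%s\t%d\t%s\t%s\t%s\t50\tPASS\t.\tGT\t0/1",
            vcf_rows$chrom, as.integer(vcf_rows$pos), vcf_rows$id,
            vcf_rows$ref, vcf_rows$alt)
  ), vcf_path)

  ## ---- tables -------------------------------------------------------------
  cases_path <- file.path(out_dir, "cases.csv")
  readr::write_csv(cases, cases_path)
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(truth, truth_path)
  exp_path <- file.path(out_dir, "mirna_experimental.tsv")
  readr::write_tsv(interactions_exp, exp_path)
  pred_path <- file.path(out_dir, "mirna_predicted.tsv")
  readr::write_tsv(interactions_pred, pred_path)
  loci_path <- file.path(out_dir, "mirna_loci.bed")
  loci_out <- mir_loci
  loci_out$provenance <- lapply(mir_loci$mirna_id, function(id) character(0))
  writeLines(sprintf("%s\t%d\t%d\t%s", loci_out$chrom, as.integer(loci_out$start),
                     as.integer(loci_out$end), loci_out$name), loci_path)

  list(spec = spec,
       registry = registry,
       store = store,
       interactions = list(experimental = load_interactions(exp_path, "experimental"),
                           predicted = suppressMessages(load_interactions(pred_path, "predicted"))),
       mirna_loci = mir_loci,
       cases = cases,
       truth = truth,
       plants = plants,
       tissues = tissues,
       paths = list(genes = gene_path, manifest = manifest_path,
                    tracks = track_dir, vcf = vcf_path, cases = cases_path,
                    truth = truth_path, mirna_experimental = exp_path,
                    mirna_predicted = pred_path, mirna_loci = loci_path))
}

#' Check a fixture's truth table against the search engine
#'
#' For every truth-table row, runs the stated minimal query (which must
#' recover the planted variant) and the stated excluding query (which must
#' not). Used by tests and by the evaluation of planted-truth recovery.
#'
#' @param fx A generated fixture (from [generate_fixture()]).
#' @return Tibble with one row per truth row: `case`, `recovered`,
#'   `excluded`.
#' @export
check_fixture_truth <- function(fx) {
  truth <- fx$truth
  purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    minimal_tissues <- switch(tr$recover_scope,
      single = tr$best_tissue,
      multi = unique(c(tr$best_tissue, strsplit(tr$related_tissues, ";")[[1]])),
      unselected = fx$tissues
    )
    cfg <- dataset_config(tr$dataset, tr$upstream_bp, tr$downstream_bp, tr$mode)
    run1 <- suppressWarnings(run_search(fx$store, fx$registry,
      search_query(fx$spec$build, tr$gene, minimal_tissues, cfg)))
    run0 <- suppressWarnings(run_search(fx$store, fx$registry,
      search_query(fx$spec$build, tr$gene, tr$excluding_tissue, cfg)))
    v <- genome_intervals(tr$chrom, tr$pos - 1, tr$pos, fx$spec$build)
    hit <- function(r) {
      iv <- r$intervals
      any(iv$chrom == v$chrom & pmax(iv$start, v$start) < pmin(iv$end, v$end))
    }
    tibble(case = tr$case, recovered = hit(run1), excluded = !hit(run0))
  }) |> bind_rows()
}
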