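#' Per-dataset search configuration
#'
#' TSS window spans and tissue-activity mode for one cis-regulatory
#' dataset. `mode = "any"` keeps a region present in at least one target
#' tissue track of the dataset; `mode = "all"` requires presence in every
#' *available* target tissue track (tissues without a track in the dataset
#' do not veto). Spans are explicit configuration — there are no implicit
#' per-dataset magic numbers.
#'
#' @param dataset Dataset id as registered in the track store.
#' @param upstream_bp,downstream_bp TSS window spans in bp (default 50000).
#' @param mode `"any"` or `"all"`.
#' @return One-row tibble of dataset configuration.
#' @export
dataset_config <- function(dataset, upstream_bp = 50000, downstream_bp = 50000,
                           mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  tibble(dataset = dataset, upstream_bp = upstream_bp,
         downstream_bp = downstream_bp, mode = mode)
}

#' Build a search query
#'
#' A query names the genome build, target genes, target tissues, the
#' enabled cis-regulatory datasets with their per-dataset windows and
#' modes, and an optional miRNA branch configuration.
#'
#' @param build Genome build tag.
#' @param genes Character vector of HGNC symbols (>= 1).
#' @param tissues Character vector of tissue labels (>= 1).
#' @param datasets Tibble of per-dataset configs, e.g.
#'   `dplyr::bind_rows(dataset_config("FANTOM_enh"), ...)`; may be empty
#'   only when the miRNA branch is enabled.
#' @param mirna Optional list: `source` ("both"/"experimental"/"predicted"),
#'   `evidence` (whitelist or NULL), `chromatin_datasets` (or NULL).
#' @param strand_aware_windows Passed through to TSS window construction.
#' @return A `search_query` object.
#' @export
search_query <- function(build, genes, tissues, datasets = NULL, mirna = NULL,
                         strand_aware_windows = TRUE) {
  if (length(genes) < 1) abort("a query needs at least one gene")
  if (length(tissues) < 1) abort("a query needs at least one tissue")
  if (is.null(datasets)) {
    datasets <- tibble(dataset = character(0), upstream_bp = numeric(0),
                       downstream_bp = numeric(0), mode = character(0))
  }
  if ((nrow(datasets) == 0) && is.null(mirna)) {
    abort("a query needs at least one enabled dataset or the miRNA branch")
  }
  if (nrow(datasets) > 0 && !all(datasets$mode %in% c("any", "all"))) {
    abort("dataset mode must be 'any' or 'all'")
  }
  structure(list(build = build, genes = genes, tissues = tissues,
                 datasets = datasets, mirna = mirna,
                 strand_aware_windows = strand_aware_windows),
            class = "search_query")
}

# (dataset, tissue) pairs of a dataset's tracks restricted to queried tissues
dataset_tissue_tracks <- function(store, dataset, tissues) {
  store$tracks[store$tracks$dataset == dataset & store$tracks$tissue %in% tissues, ]
}

#' Search one cis-regulatory dataset
#'
#' Implements the per-dataset selection protocol: a region of the dataset
#' is included if (1) it overlaps a TSS window of a target gene, built with
#' the dataset's spans, and (2) under `mode = "any"` it is present in any
#' target tissue track of the dataset, or under `mode = "all"` in every
#' available target tissue track. "Present in" a tissue track means >= 1 bp
#' overlap; dataset region boundaries differ between tissues, so exact
#' coordinate identity would be too strict. Provenance lists every
#' (dataset, tissue) pair whose track contains the region.
#'
#' @param store Track store.
#' @param registry Transcript registry.
#' @param dataset Dataset id (must exist in the store).
#' @param query A `search_query` whose `datasets` table configures this
#'   dataset.
#' @return Annotated interval tibble (pre-merge candidate regions).
#' @export
search_cis <- function(store, registry, dataset, query) {
  if (!dataset %in% store$tracks$dataset) {
    abort(sprintf("unknown dataset id: %s", dataset))
  }
  cfg <- query$datasets[query$datasets$dataset == dataset, ]
  if (nrow(cfg) != 1) abort(sprintf("query does not configure dataset %s", dataset))
  empty <- genome_intervals(character(0), numeric(0), numeric(0), character(0))

  tracks <- dataset_tissue_tracks(store, dataset, query$tissues)
  missing <- setdiff(query$tissues, tracks$tissue)
  if (length(missing) > 0) {
    warn(sprintf("dataset %s has no track for tissue(s): %s", dataset,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(tracks) == 0) return(empty)

  windows <- tss_windows_for_genes(registry, query$genes, cfg$upstream_bp,
                                   cfg$downstream_bp,
                                   strand_aware = query$strand_aware_windows)

  # candidate universe: every region of the dataset's available target
  # tissue tracks, restricted first to TSS-window overlap (equivalent to
  # checking the conditions in the literal order)
  cand <- bind_rows(tracks$intervals) |>
    distinct(.data$chrom, .data$start, .data$end, .data$build)
  win_union <- merge_collapse(windows[, c("chrom", "start", "end", "build", "provenance")])
  cand <- cand[overlaps_any_collapsed(cand, win_union), ]
  if (nrow(cand) == 0) return(empty)

  # per-tissue presence: stored tracks are collapsed, so binary search applies
  present <- vapply(seq_len(nrow(tracks)), function(j) {
    overlaps_any_collapsed(cand, tracks$intervals[[j]])
  }, logical(nrow(cand)))
  present <- matrix(present, nrow = nrow(cand))

  keep <- if (cfg$mode == "any") rowSums(present) > 0 else rowSums(present) == nrow(tracks)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  pres <- present[keep, , drop = FALSE]
  cand$provenance <- purrr::map(seq_len(nrow(cand)), function(i) {
    sort(paste(dataset, tracks$tissue[pres[i, ]], sep = "|"))
  })
  arrange(cand, .data$chrom, .data$start, .data$end)
}

#' Run a full regulatory-region search
#'
#' Executes the search protocol over every enabled dataset and the
#' optional miRNA branch, then merges and collapses all selected regions
#' into a single sorted, disjoint result whose intervals carry the union
#' of their (dataset, tissue) provenance. Deterministic for a fixed store.
#'
#' @param store Track store.
#' @param registry Transcript registry.
#' @param query A `search_query`.
#' @param interactions,mirna_loci Required when the query enables the
#'   miRNA branch.
#' @return A `search_result`: list with `intervals` (merged annotated
#'   tibble), `per_dataset` (pre-merge region lists, for traceability),
#'   `stats` (`region_count`, `total_span_bp`) and the `query`.
#' @export
run_search <- function(store, registry, query, interactions = NULL,
                       mirna_loci = NULL) {
  stopifnot(inherits(query, "search_query"))
  if (query$build != store$build) abort("query build does not match store build")
  tx <- transcripts_for(registry, query$genes)
  if (nrow(tx) == 0) {
    abort(sprintf("no query gene is known: %s", paste(query$genes, collapse = ", ")))
  }
  any_track <- nrow(store$tracks[store$tracks$tissue %in% query$tissues, ]) > 0
  if (!any_track) {
    abort(sprintf("no track in the store for any queried tissue (%s)",
                  paste(query$tissues, collapse = ", ")))
  }
  per_dataset <- list()
  for (ds in query$datasets$dataset) {
    per_dataset[[ds]] <- search_cis(store, registry, ds, query)
  }
  if (!is.null(query$mirna)) {
    if (is.null(interactions) || is.null(mirna_loci)) {
      abort("query enables the miRNA branch but interactions/mirna_loci were not supplied")
    }
    m <- query$mirna
    per_dataset[["mirna"]] <- active_mirna_loci(
      interactions, mirna_loci, genes = query$genes, tissues = query$tissues,
      store = store, source = m$source %||% "both",
      evidence = m$evidence, chromatin_datasets = m$chromatin_datasets
    )
  }
  all_regions <- bind_rows(purrr::map(per_dataset, \(x) x[, c("chrom", "start", "end", "build", "provenance")]))
  merged <- merge_collapse(all_regions)
  structure(list(
    intervals = merged,
    per_dataset = per_dataset,
    stats = tibble(region_count = nrow(merged),
                   total_span_bp = sum(merged$end - merged$start)),
    query = query
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d region(s), %d bp, genes: %s, tissues: %s\n",
              x$stats$region_count, x$stats$total_span_bp,
              paste(x$query$genes, collapse = ","),
              paste(x$query$tissues, collapse = ",")))
  invisible(x)
}

#' Tidy a search result
#'
#' One row per (interval, provenance pair): the traceability table showing
#' which dataset and tissue support each merged region.
#' @param x A `search_result`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `start`, `end`, `build`, `dataset`, `tissue`.
#' @method tidy search_result
#' @export
tidy.search_result <- function(x, ...) {
  iv <- x$intervals
  if (nrow(iv) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  build = character(0), dataset = character(0), tissue = character(0)))
  }
  iv |>
    mutate(.row = seq_len(nrow(iv))) |>
    tidyr::unnest_longer("provenance") |>
    tidyr::separate_wider_delim("provenance", "|", names = c("dataset", "tissue")) |>
    select("chrom", "start", "end", "build", "dataset", "tissue") |>
    arrange(.data$chrom, .data$start, .data$end, .data$dataset, .data$tissue)
}

#' One-line summary of a search result
#' @param x A `search_result`.
#' @param ... Unused.
#' @return One-row tibble: `region_count`, `total_span_bp`, `n_datasets`,
#'   `n_tissues`.
#' @method glance search_result
#' @export
glance.search_result <- function(x, ...) {
  td <- tidy(x)
  tibble(region_count = x$stats$region_count,
         total_span_bp = x$stats$total_span_bp,
         n_datasets = length(unique(td$dataset)),
         n_tissues = length(unique(td$tissue)))
}

#' Plot a search result
#'
#' Segment plot of the merged regions per chromosome, coloured by the
#' number of supporting (dataset, tissue) pairs.
#' @param object A `search_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot search_result
#' @export
autoplot.search_result <- function(object, ...) {
  iv <- object$intervals
  iv$support <- lengths(iv$provenance)
  ggplot2::ggplot(iv, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$chrom, yend = .data$chrom,
                                   colour = .data$support)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "supporting\ntracks") +
    ggplot2::theme_minimal()
}

#' Export a search result
#'
#' Produces the three downstream representations of a result: a sorted BED
#' file with provenance in column 4, the per-(interval, provenance) table,
#' and a UCSC Genome Browser payload (1-based display position string of
#' the result's spanning range plus custom-track lines). An empty result
#' yields valid empty outputs.
#'
#' @param result A `search_result`.
#' @param bed_path Optional path; when given, the BED is written there.
#' @param track_name Name for the UCSC custom-track header.
#' @return List with `table`, `ucsc` (`position`, `track_lines`) and
#'   `bed_path` (NULL if not written).
#' @export
result_to_outputs <- function(result, bed_path = NULL, track_name = "regusearch") {
  stopifnot(inherits(result, "search_result"))
  iv <- result$intervals
  tab <- tidy(result)
  if (nrow(iv) == 0) {
    ucsc <- list(position = NA_character_,
                 track_lines = sprintf('track name="%s"', track_name))
  } else {
    first_chrom <- sort(unique(iv$chrom))[1]
    on_chrom <- iv[iv$chrom == first_chrom, ]
    position <- sprintf("%s:%d-%d", first_chrom, as.integer(min(on_chrom$start)) + 1L,
                        as.integer(max(on_chrom$end)))
    track_lines <- c(sprintf('track name="%s"', track_name),
                     sprintf("%s\t%d\t%d\t%s", iv$chrom, as.integer(iv$start),
                             as.integer(iv$end), serialize_provenance(iv$provenance)))
    ucsc <- list(position = position, track_lines = track_lines)
  }
  if (!is.null(bed_path)) {
    write_bed(iv, bed_path, ucsc_track_header = track_name)
  }
  list(table = tab, ucsc = ucsc, bed_path = bed_path)
}
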