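#' Regulator classes
#'
#' The closed set of functional categories a regulatory track can carry:
#' promoters, DNA-binding sites (enhancers, repressors, insulators / TFBS)
#' and accessible chromatin.
#' @return Character vector of valid class labels.
#' @export
regulator_classes <- function() {
  c("promoter", "enhancer", "tfbs", "repressor", "insulator", "accessible_chromatin")
}

#' Create an empty track store
#'
#' A track store is the registry of regulatory tracks for one genome build.
#' Each track is keyed by (dataset, tissue, class) and holds sorted,
#' disjoint intervals; registration collapses overlapping records.
#'
#' @param build Genome build tag ("hg19" or "hg38").
#' @return A `track_store` object.
#' @export
track_store <- function(build) {
  if (!build %in% genome_builds()) abort(sprintf("unsupported genome build: %s", build))
  structure(
    list(build = build,
         tracks = tibble(dataset = character(0), tissue = character(0),
                         cls = character(0), build = character(0),
                         intervals = list())),
    class = "track_store"
  )
}

#' @export
print.track_store <- function(x, ...) {
  cat(sprintf("<track_store> build %s: %d track(s), %d dataset(s), %d tissue(s)\n",
              x$build, nrow(x$tracks), length(unique(x$tracks$dataset)),
              length(unique(x$tracks$tissue))))
  invisible(x)
}

#' Register a regulatory track
#'
#' Ingests a BED file (or an interval tibble) as the track for one
#' (dataset, tissue, class) key. Intervals are collapsed on ingest and each
#' stored interval is stamped with `dataset|tissue` provenance. Registering
#' an existing key errors unless `replace = TRUE`. Passing several paths
#' collapses them as biological replicates (see [collapse_replicates()]).
#'
#' @param store A `track_store`.
#' @param x BED path(s) or an interval tibble.
#' @param dataset Source dataset id (e.g. `"FANTOM_enh"`).
#' @param tissue Tissue / primary-cell label.
#' @param cls Regulator class, one of [regulator_classes()].
#' @param replace Overwrite an existing (dataset, tissue, class) entry.
#' @param normalize_chrom Passed to [read_bed()] for path input.
#' @return The updated store.
#' @export
register_track <- function(store, x, dataset, tissue, cls, replace = FALSE,
                           normalize_chrom = TRUE) {
  stopifnot(inherits(store, "track_store"))
  if (!cls %in% regulator_classes()) {
    abort(sprintf("unknown regulator class '%s'; valid: %s", cls,
                  paste(regulator_classes(), collapse = ", ")))
  }
  if (is.character(x)) {
    x <- purrr::map(x, read_bed, build = store$build, normalize_chrom = normalize_chrom) |>
      bind_rows()
  }
  x <- validate_intervals(x, sprintf("track %s/%s", dataset, tissue))
  if (nrow(x) > 0 && any(x$build != store$build)) {
    abort(sprintf("track build does not match store build (%s)", store$build))
  }
  x$build <- store$build
  x$provenance <- rep(list(paste(dataset, tissue, sep = "|")), nrow(x))
  x <- merge_collapse(x)
  key <- store$tracks$dataset == dataset & store$tracks$tissue == tissue &
    store$tracks$cls == cls
  if (any(key)) {
    if (!replace) {
      abort(sprintf("track (%s, %s, %s) already registered; use replace = TRUE",
                    dataset, tissue, cls))
    }
    store$tracks <- store$tracks[!key, ]
  }
  store$tracks <- bind_rows(
    store$tracks,
    tibble(dataset = dataset, tissue = tissue, cls = cls,
           build = store$build, intervals = list(x))
  )
  store
}

#' Tissue availability by regulator class
#'
#' Lists which tissues have data, grouped by the regulator classes and
#' datasets covering them — the availability view a user consults before
#' choosing target tissues.
#'
#' @param store A `track_store`.
#' @param cls Optional regulator class filter.
#' @param dataset Optional dataset filter.
#' @return Tibble with one row per tissue: `tissue`, `classes`, `datasets`,
#'   `n_tracks`.
#' @export
available_tissues <- function(store, cls = NULL, dataset = NULL) {
  tr <- store$tracks
  if (!is.null(cls)) tr <- tr[tr$cls %in% cls, ]
  if (!is.null(dataset)) tr <- tr[tr$dataset %in% dataset, ]
  tr |>
    group_by(.data$tissue) |>
    summarise(classes = paste(sort(unique(.data$cls)), collapse = ","),
              datasets = paste(sort(unique(.data$dataset)), collapse = ","),
              n_tracks = n(), .groups = "drop") |>
    arrange(.data$tissue)
}

#' Collapse biological replicates into one track
#'
#' Merges tracks with identical (dataset, tissue, class, build) keys —
#' biological replicates, including pre-lifted data — into a single track
#' whose per-base coverage is the union of the inputs.
#'
#' @param tracks A tracks tibble (rows of `store$tracks`) sharing one key.
#' @return A one-row tracks tibble with merged intervals.
#' @export
collapse_replicates <- function(tracks) {
  stopifnot(nrow(tracks) >= 1)
  key <- distinct(tracks[, c("dataset", "tissue", "cls", "build")])
  if (nrow(key) > 1) abort("collapse_replicates: tracks have mixed (dataset, tissue, class, build) keys")
  merged <- merge_collapse(bind_rows(tracks$intervals))
  key$intervals <- list(merged)
  key
}

#' Derive promoter intervals from CAGE peaks
#'
#' Implements the CAGE promoter-track derivation: peaks with normalized
#' TPM expression strictly below `tpm_threshold` are filtered out (a peak
#' at exactly the threshold survives), and each surviving peak — marking a
#' transcription start site — is expanded `upstream_extension_bp` upstream
#' in the direction of transcription to cover the promoter, clamped at 0.
#' The result is collapsed. Peak tables are expected to be split per tissue
#' before filtering.
#'
#' @param peaks Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `tpm`, `build` (and optionally `sample`).
#' @param tpm_threshold Minimum TPM retained (default 10).
#' @param upstream_extension_bp Upstream promoter extension (default 200).
#' @param strand_aware If `FALSE`, the extension is always genomic-left.
#' @return Collapsed interval tibble of promoter regions.
#' @export
promoters_from_cage <- function(peaks, tpm_threshold = 10,
                                upstream_extension_bp = 200,
                                strand_aware = TRUE) {
  req <- c("chrom", "start", "end", "strand", "tpm", "build")
  miss <- setdiff(req, names(peaks))
  if (length(miss) > 0) abort(sprintf("CAGE peaks missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(peaks) > 0 && (any(is.na(peaks$strand)) || !all(peaks$strand %in% c("+", "-")))) {
    abort("CAGE peaks must carry strand ('+'/'-') for upstream extension")
  }
  if (any(peaks$tpm < 0)) abort("CAGE peak TPM must be >= 0")
  kept <- peaks[peaks$tpm >= tpm_threshold, ]
  if (nrow(kept) == 0) {
    return(merge_collapse(genome_intervals(character(0), numeric(0), numeric(0), character(0))))
  }
  if (strand_aware) {
    start <- ifelse(kept$strand == "+", kept$start - upstream_extension_bp, kept$start)
    end <- ifelse(kept$strand == "+", kept$end, kept$end + upstream_extension_bp)
  } else {
    start <- kept$start - upstream_extension_bp
    end <- kept$end
  }
  out <- tibble(chrom = kept$chrom, start = pmax(0, start), end = end,
                build = kept$build, provenance = rep(list(character(0)), nrow(kept)))
  merge_collapse(out)
}

#' Read a CAGE peak expression table
#'
#' TSV with columns `chrom`, `start`, `end`, `strand`, `tpm`, `sample`.
#' @param path TSV path.
#' @param build Genome build of the coordinates.
#' @return Tibble of CAGE peaks.
#' @export
read_cage_peaks <- function(path, build) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "start", "end", "strand", "tpm", "sample")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) abort(sprintf("CAGE table %s missing column(s): %s", path, paste(miss, collapse = ", ")))
  tab$build <- build
  as_tibble(tab)
}

ccre_class_from_token <- function(token) {
  t <- tolower(token)
  dplyr::case_when(
    grepl("prom|pls", t) ~ "promoter",
    grepl("enh|els", t) ~ "enhancer",
    grepl("ctcf|insul", t) ~ "insulator",
    grepl("dnase|access|chromatin", t) ~ "accessible_chromatin",
    TRUE ~ NA_character_
  )
}

#' Split class-annotated ccRE records into per-class tracks
#'
#' Candidate cis-regulatory elements come as one BED with a class token per
#' record (e.g. "promoter-like", "dELS", "CTCF-only", "DNase-H3K4me3").
#' Records are divided into promoter, enhancer, insulator and accessible
#' chromatin tracks according to that annotation; records with unrecognized
#' tokens are skipped and their count reported.
#'
#' @param x BED path or interval tibble; the class token is taken from
#'   `class_col` (default the BED `name` column).
#' @param build Genome build (required for path input).
#' @param class_col Column holding the class token.
#' @return Tibble with one row per class present: `cls`, `n_records`,
#'   `intervals` (pre-collapse record counts in `n_records`);
#'   `attr(, "skipped")` gives the number of unrecognized records.
#' @export
split_ccres <- function(x, build = NULL, class_col = "name") {
  if (is.character(x)) {
    stopifnot(!is.null(build))
    x <- read_bed(x, build = build)
  }
  if (nrow(x) == 0) abort("ccRE input is empty")
  if (!class_col %in% names(x)) abort(sprintf("ccRE input lacks class column '%s'", class_col))
  cls <- ccre_class_from_token(x[[class_col]])
  skipped <- sum(is.na(cls))
  if (skipped == nrow(x)) abort("no ccRE record carries a recognizable class token")
  if (skipped > 0) {
    message(sprintf("split_ccres: skipped %d record(s) with unrecognized class tokens", skipped))
  }
  keep <- x[!is.na(cls), ]
  keep$cls <- cls[!is.na(cls)]
  out <- keep |>
    tidyr::nest(intervals = -"cls") |>
    mutate(n_records = vapply(.data$intervals, nrow, integer(1))) |>
    select("cls", "n_records", "intervals") |>
    arrange(.data$cls)
  attr(out, "skipped") <- skipped
  out
}

#' Summary statistics of a track
#'
#' Region count, mean region size and total span, computed on the collapsed
#' intervals — the per-track feature-density statistics used to contrast
#' datasets.
#'
#' @param x Interval tibble, or a one-row tracks tibble with an
#'   `intervals` list column.
#' @return Tibble with `region_count`, `mean_size_bp`, `total_span_bp`.
#' @export
summarize_track <- function(x) {
  if (is.data.frame(x) && "intervals" %in% names(x) && is.list(x$intervals)) {
    stopifnot(nrow(x) == 1)
    x <- x$intervals[[1]]
  }
  x <- merge_collapse(x)
  widths <- x$end - x$start
  tibble(region_count = nrow(x),
         mean_size_bp = if (nrow(x) == 0) NA_real_ else mean(widths),
         total_span_bp = sum(widths))
}

#' Build a track store from a YAML manifest
#'
#' The manifest lists `build` and a `tracks` sequence of
#' `{dataset, tissue, class, path}` entries; paths are resolved relative to
#' the manifest file.
#'
#' @param path Manifest YAML path.
#' @return A populated `track_store`.
#' @export
build_store <- function(path) {
  if (!file.exists(path)) abort(sprintf("store manifest not found: %s", path))
  man <- yaml::read_yaml(path)
  if (is.null(man$build) || is.null(man$tracks)) {
    abort("store manifest must provide 'build' and 'tracks'")
  }
  store <- track_store(man$build)
  base <- dirname(normalizePath(path))
  for (tr in man$tracks) {
    p <- tr$path
    if (!grepl("^/", p)) p <- file.path(base, p)
    store <- register_track(store, p, dataset = tr$dataset, tissue = tr$tissue,
                            cls = tr$class)
  }
  store
}

#' Tidy a track store into per-track summaries
#'
#' @param x A `track_store`.
#' @param ... Unused.
#' @return Tibble with one row per track: key columns plus
#'   `region_count`, `mean_size_bp`, `total_span_bp`.
#' @method tidy track_store
#' @export
tidy.track_store <- function(x, ...) {
  if (nrow(x$tracks) == 0) {
    return(tibble(dataset = character(0), tissue = character(0), cls = character(0),
                  build = character(0), region_count = integer(0),
                  mean_size_bp = numeric(0), total_span_bp = numeric(0)))
  }
  stats <- purrr::map(x$tracks$intervals, summarize_track) |> bind_rows()
  bind_cols(x$tracks |> select("dataset", "tissue", "cls", "build"), stats)
}

#' One-line overview of a track store
#' @param x A `track_store`.
#' @param ... Unused.
#' @return One-row tibble: `n_tracks`, `n_datasets`, `n_tissues`,
#'   `total_span_bp`.
#' @method glance track_store
#' @export
glance.track_store <- function(x, ...) {
  td <- tidy(x)
  tibble(n_tracks = nrow(td),
         n_datasets = length(unique(td$dataset)),
         n_tissues = length(unique(td$tissue)),
         total_span_bp = sum(td$total_span_bp))
}

#' Plot per-track summary statistics
#'
#' Bar panel of region counts per dataset and tissue — a quick look at how
#' datasets differ in feature density.
#'
#' @param object A `track_store`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot track_store
#' @export
autoplot.track_store <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$tissue, y = .data$region_count,
                                   fill = .data$cls)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(x = "tissue", y = "regions", fill = "class") +
    ggplot2::theme_minimal()
}
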