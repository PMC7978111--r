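#' Load a miRNA–gene interaction table
#'
#' TSV with columns `mirna_id`, `gene`, `evidence` and — required for the
#' predicted source — `region`. Predicted interactions are retained only
#' when they target the 3′-UTR of the gene; dropped records are counted and
#' reported. Duplicate (mirna, gene) rows are deduplicated keeping the
#' strongest evidence tag.
#'
#' @param path TSV path.
#' @param source `"experimental"` (e.g. miRTarBase-shaped) or `"predicted"`
#'   (miRWalk-shaped; 3′-UTR filter applies).
#' @param evidence_levels Optional character vector ranking evidence tags
#'   from strongest to weakest, used for deduplication. Tags absent from
#'   the ranking sort after ranked ones; with no ranking, ties are broken
#'   alphabetically for determinism.
#' @return Interaction tibble (`mirna_id`, `gene`, `source`, `evidence`,
#'   `region`); `attr(, "dropped_non_3utr")` counts the filtered records.
#' @export
load_interactions <- function(path, source = c("experimental", "predicted"),
                              evidence_levels = NULL) {
  source <- match.arg(source)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("mirna_id", "gene", "evidence")
  if (source == "predicted") req <- c(req, "region")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("interaction table %s missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (!"region" %in% names(tab)) tab$region <- NA_character_
  dropped <- 0L
  if (source == "predicted") {
    is_3utr <- !is.na(tab$region) & gsub("[^0-9A-Za-z]", "", toupper(tab$region)) == "3UTR"
    dropped <- sum(!is_3utr)
    if (dropped > 0) {
      message(sprintf("load_interactions: dropped %d predicted record(s) not targeting the 3'-UTR", dropped))
    }
    tab <- tab[is_3utr, ]
  }
  rank <- if (is.null(evidence_levels)) {
    match(tab$evidence, sort(unique(tab$evidence)))
  } else {
    r <- match(tab$evidence, evidence_levels)
    ifelse(is.na(r), length(evidence_levels) + 1L, r)
  }
  out <- tibble(mirna_id = as.character(tab$mirna_id),
                gene = as.character(tab$gene),
                source = source,
                evidence = as.character(tab$evidence),
                region = as.character(tab$region),
                .rank = rank) |>
    arrange(.data$mirna_id, .data$gene, .data$.rank, .data$evidence) |>
    distinct(.data$mirna_id, .data$gene, .keep_all = TRUE) |>
    select(-".rank")
  attr(out, "dropped_non_3utr") <- dropped
  out
}

#' Read miRNA transcript loci from a BED file
#'
#' Column 4 is the miRBase-style miRNA name.
#' @param path BED path.
#' @param build Genome build of the coordinates.
#' @return Tibble with `mirna_id` plus interval columns.
#' @export
read_mirna_loci <- function(path, build) {
  x <- read_bed(path, build = build)
  if (!"name" %in% names(x)) abort(sprintf("miRNA locus BED %s needs a name column (miRNA id)", path))
  x$mirna_id <- x$name
  x$provenance <- rep(list(character(0)), nrow(x))
  x
}

#' Loci of miRNAs active in the target tissues
#'
#' Selects the genomic loci of miRNAs that (1) interact with at least one
#' target gene in the chosen interaction source(s), under the optional
#' evidence whitelist, and (2) whose transcript overlaps (>= 1 bp) an
#' accessible-chromatin track for any of the target tissues — the proxy by
#' which tissue-agnostic interaction databases are restricted to tissues.
#' Provenance records the interaction source and the tissue of each
#' supporting chromatin track.
#'
#' @param interactions Interaction tibble from [load_interactions()] (or
#'   several row-bound ones).
#' @param loci miRNA locus tibble from [read_mirna_loci()].
#' @param genes Target gene symbols (case-insensitive).
#' @param tissues Target tissue labels.
#' @param store Track store providing accessible-chromatin tracks.
#' @param source Interaction source filter: `"experimental"`, `"predicted"`
#'   or `"both"`.
#' @param evidence Optional whitelist of evidence tags.
#' @param chromatin_datasets Optional restriction of which datasets'
#'   accessible-chromatin tracks qualify (default: any).
#' @return Annotated interval tibble of qualifying miRNA loci.
#' @export
active_mirna_loci <- function(interactions, loci, genes, tissues, store,
                              source = c("both", "experimental", "predicted"),
                              evidence = NULL, chromatin_datasets = NULL) {
  source <- match.arg(source)
  ia <- interactions
  if (source != "both") ia <- ia[ia$source == source, ]
  if (!is.null(evidence)) ia <- ia[ia$evidence %in% evidence, ]
  ia <- ia[toupper(ia$gene) %in% toupper(genes), ]
  empty <- genome_intervals(character(0), numeric(0), numeric(0), character(0))
  empty$mirna_id <- character(0)
  if (nrow(ia) == 0) return(empty)

  chrom_tracks <- store$tracks[store$tracks$cls == "accessible_chromatin" &
                                 store$tracks$tissue %in% tissues, ]
  if (!is.null(chromatin_datasets)) {
    chrom_tracks <- chrom_tracks[chrom_tracks$dataset %in% chromatin_datasets, ]
  }
  if (nrow(chrom_tracks) == 0) {
    warn("no accessible-chromatin track available for the target tissues; miRNA branch returns nothing")
    return(empty)
  }

  ids <- unique(ia$mirna_id)
  no_locus <- setdiff(ids, loci$mirna_id)
  if (length(no_locus) > 0) {
    warn(sprintf("no locus for interacting miRNA(s): %s; skipped",
                 paste(no_locus, collapse = ", ")))
  }
  cand <- loci[loci$mirna_id %in% ids, ]
  if (nrow(cand) == 0) return(empty)

  src_tag <- paste(sort(unique(ia$source)), collapse = "+")
  support_mat <- vapply(seq_len(nrow(chrom_tracks)), function(j) {
    overlaps_any_collapsed(cand, chrom_tracks$intervals[[j]])
  }, logical(nrow(cand)))
  support_mat <- matrix(support_mat, nrow = nrow(cand))
  out <- purrr::map(seq_len(nrow(cand)), function(i) {
    locus <- cand[i, ]
    support <- support_mat[i, ]
    if (!any(support)) return(NULL)
    prov <- paste(paste0("mirna_", src_tag), chrom_tracks$tissue[support], sep = "|")
    tibble(chrom = locus$chrom, start = locus$start, end = locus$end,
           build = locus$build, provenance = list(sort(unique(prov))),
           mirna_id = locus$mirna_id)
  }) |> purrr::compact() |> bind_rows()
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$start, .data$end)
}
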