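#' Load a genePred-style transcript table
#'
#' Reads a tab-separated UCSC-style refSeq dump (ncbiRefSeq shape). The
#' columns `name` (transcript accession), `chrom`, `strand`, `txStart`,
#' `txEnd` and `name2` (HGNC gene symbol) are required; any others are
#' ignored. All transcripts of a gene are retained — downstream searches
#' use every transcription start site, not just a canonical one.
#'
#' @param path TSV path; a leading `#` on the header line is tolerated.
#' @param build Genome build of the coordinates ("hg19" or "hg38").
#' @return A transcript registry: a tibble with columns `gene`, `tx_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `build` (0-based half-open
#'   spans), queryable case-insensitively with [transcripts_for()].
#' @export
load_gene_table <- function(path, build) {
  if (!file.exists(path)) abort(sprintf("gene table not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  req <- c("name", "chrom", "strand", "txStart", "txEnd", "name2")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("gene table %s is missing required column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  if (nrow(tab) == 0) abort(sprintf("gene table %s has zero rows", path))
  if (!all(tab$strand %in% c("+", "-"))) abort("gene table strand must be '+' or '-'")
  reg <- tibble(
    gene = as.character(tab$name2),
    tx_id = as.character(tab$name),
    chrom = as.character(tab$chrom),
    strand = as.character(tab$strand),
    tx_start = as.numeric(tab$txStart),
    tx_end = as.numeric(tab$txEnd),
    build = build
  )
  if (any(reg$tx_start >= reg$tx_end)) abort("gene table has txStart >= txEnd")
  class(reg) <- c("transcript_registry", class(reg))
  reg
}

#' Look up transcripts by gene symbol
#'
#' Symbols are matched case-insensitively; aliases are not resolved.
#' Unknown symbols are reported in the `unknown` attribute of the result.
#'
#' @param registry Transcript registry from [load_gene_table()].
#' @param symbols Character vector of HGNC gene symbols.
#' @return Tibble of matching transcripts; `attr(, "unknown")` lists the
#'   symbols that did not resolve.
#' @export
transcripts_for <- function(registry, symbols) {
  key <- toupper(registry$gene)
  want <- toupper(symbols)
  hit <- registry[key %in% want, ]
  unknown <- symbols[!want %in% key]
  attr(hit, "unknown") <- unknown
  hit
}

#' TSS windows for transcripts
#'
#' Builds the search window around each transcript's transcription start
#' site. The TSS is the first transcribed base: `tx_start` on the "+"
#' strand and `tx_end - 1` on the "-" strand. With `strand_aware = TRUE`
#' (default) "upstream" is taken in the direction of transcription; the
#' window always contains the TSS base itself, so a 0/0 window is still a
#' searchable 1-bp interval. Windows are clamped at position 0.
#'
#' @param transcripts Tibble of transcripts (rows of a registry).
#' @param upstream_bp,downstream_bp Non-negative window spans in bp.
#' @param strand_aware If `FALSE`, "upstream" means genomic-left for every
#'   transcript regardless of strand (comparability option).
#' @return Interval tibble with one window per transcript row, carrying
#'   `gene`, `tx_id` and `strand`.
#' @examples
#' tx <- tibble::tibble(gene = "BLK", tx_id = "NM_1", chrom = "chr8",
#'                      strand = "+", tx_start = 1000, tx_end = 2000,
#'                      build = "hg38")
#' tss_window(tx, 500, 100)
#' @export
tss_window <- function(transcripts, upstream_bp, downstream_bp, strand_aware = TRUE) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  tx <- transcripts
  tss <- ifelse(tx$strand == "+", tx$tx_start, tx$tx_end - 1)
  if (strand_aware) {
    left <- ifelse(tx$strand == "+", tss - upstream_bp, tss - downstream_bp)
    right <- ifelse(tx$strand == "+", tss + downstream_bp + 1, tss + upstream_bp + 1)
  } else {
    left <- tss - upstream_bp
    right <- tss + downstream_bp + 1
  }
  out <- tibble(
    chrom = tx$chrom,
    start = pmax(0, left),
    end = right,
    build = tx$build,
    provenance = rep(list(character(0)), nrow(tx)),
    gene = tx$gene,
    tx_id = tx$tx_id,
    strand = tx$strand
  )
  validate_intervals(out, "TSS windows")
}

#' TSS windows for a set of gene symbols
#'
#' One window per transcript of each resolved gene (union over all
#' transcripts). Errors when no symbol resolves; warns listing the unknown
#' symbols when only some do.
#'
#' @inheritParams tss_window
#' @param registry Transcript registry.
#' @param symbols HGNC gene symbols (case-insensitive).
#' @return Interval tibble of windows.
#' @export
tss_windows_for_genes <- function(registry, symbols, upstream_bp, downstream_bp,
                                  strand_aware = TRUE) {
  stopifnot(length(symbols) >= 1)
  tx <- transcripts_for(registry, symbols)
  unknown <- attr(tx, "unknown")
  if (nrow(tx) == 0) {
    abort(sprintf("no gene symbol resolved; unknown: %s", paste(unknown, collapse = ", ")))
  }
  if (length(unknown) > 0) {
    warn(sprintf("unknown gene symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  tss_window(tx, upstream_bp, downstream_bp, strand_aware = strand_aware)
}
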