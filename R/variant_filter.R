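#' Parse a VCF into header and record tables
#'
#' Lines are kept verbatim so filtered output can be byte-identical to the
#' input; only CHROM/POS/REF/ALT are parsed, as that is all region overlap
#' needs. Plain and gzip/bgzip input accepted.
#' @keywords internal
read_vcf_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_header <- grepl("^#", lines)
  records <- lines[!is_header]
  if (length(records) > 0) {
    f <- strsplit(records, "\t", fixed = TRUE)
    short <- which(lengths(f) < 5)
    if (length(short) > 0) {
      abort(sprintf("%s line %d: fewer than 5 VCF columns", path,
                    which(!is_header)[short[1]]))
    }
    chrom <- vapply(f, `[[`, character(1), 1)
    pos <- suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 2)))
    bad <- which(is.na(pos) | pos < 1)
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: unparseable POS", path, which(!is_header)[bad[1]]))
    }
    ref <- vapply(f, `[[`, character(1), 4)
    alt <- vapply(f, `[[`, character(1), 5)
  } else {
    chrom <- character(0); pos <- numeric(0); ref <- character(0); alt <- character(0)
  }
  list(header = lines[is_header],
       records = tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        raw_line = records))
}

# 0-based half-open span occupied by a variant's REF allele; symbolic
# alleles fall back to the single POS base (with a warning upstream)
variant_spans <- function(records) {
  symbolic <- grepl("^<", records$alt) | grepl("\\[|\\]", records$alt)
  width <- ifelse(symbolic, 1L, nchar(records$ref))
  tibble(chrom = records$chrom, start = records$pos - 1,
         end = records$pos - 1 + width, symbolic = symbolic)
}

variant_hits_regions <- function(spans, regions) {
  # overlap with the union equals overlap with any region
  overlaps_any_collapsed(spans, merge_collapse(regions))
}

#' Filter a VCF by regulatory regions
#'
#' Writes a VCF containing the original header verbatim plus, in original
#' order, exactly the records whose REF span (0-based
#' `[POS-1, POS-1+len(REF))`) overlaps at least one region — so deletions
#' and MNVs straddling a region edge are kept even when POS itself lies
#' outside. Symbolic alleles (`<DEL>`, breakends) are matched on the POS
#' base only, with a warning. Records pass through without
#' re-normalization; kept lines are byte-identical to the input.
#'
#' @param vcf_path Input VCF (plain or gzip/bgzip).
#' @param regions Interval tibble (e.g. a search result's intervals) or a
#'   `search_result`.
#' @param out_path Output VCF path (written uncompressed).
#' @param build Genome build of the VCF coordinates; must be stated
#'   explicitly (it cannot be inferred) and must match the regions' build.
#' @return One-row tibble with `kept` and `dropped` record counts
#'   (`kept + dropped` equals the input record count).
#' @export
filter_vcf <- function(vcf_path, regions, out_path, build) {
  if (missing(build) || is.null(build)) {
    abort("the VCF genome build must be stated explicitly (build = ...)")
  }
  if (inherits(regions, "search_result")) regions <- regions$intervals
  regions <- validate_intervals(regions, "regions")
  if (nrow(regions) > 0 && any(regions$build != build)) {
    abort(sprintf("regions build does not match the declared VCF build (%s)", build))
  }
  vcf <- read_vcf_lines(vcf_path)
  spans <- variant_spans(vcf$records)
  if (any(spans$symbolic)) {
    warn(sprintf("%d symbolic-allele record(s) matched on the POS base only",
                 sum(spans$symbolic)))
  }
  hit <- variant_hits_regions(spans, regions)
  writeLines(c(vcf$header, vcf$records$raw_line[hit]), out_path)
  tibble(kept = sum(hit), dropped = sum(!hit))
}

#' Annotate variants with the regions they overlap
#'
#' Traceability companion to [filter_vcf()]: one row per
#' (variant, overlapping merged interval) pair, with the interval's
#' provenance serialized as `dataset|tissue` tokens. Variants overlapping
#' no interval produce no row; a variant straddling two merged intervals
#' produces two.
#'
#' @inheritParams filter_vcf
#' @param result A `search_result` or interval tibble.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `region_start`,
#'   `region_end`, `provenance`.
#' @export
annotate_hits <- function(vcf_path, result, build) {
  if (missing(build) || is.null(build)) {
    abort("the VCF genome build must be stated explicitly (build = ...)")
  }
  regions <- if (inherits(result, "search_result")) result$intervals else result
  regions <- validate_intervals(regions, "regions")
  if (nrow(regions) > 0 && any(regions$build != build)) {
    abort(sprintf("regions build does not match the declared VCF build (%s)", build))
  }
  vcf <- read_vcf_lines(vcf_path)
  spans <- variant_spans(vcf$records)
  rows <- purrr::map(seq_len(nrow(spans)), function(i) {
    r <- regions[regions$chrom == spans$chrom[i] &
                   pmax(regions$start, spans$start[i]) < pmin(regions$end, spans$end[i]), ]
    if (nrow(r) == 0) return(NULL)
    tibble(chrom = spans$chrom[i], pos = vcf$records$pos[i],
           ref = vcf$records$ref[i], alt = vcf$records$alt[i],
           region_start = r$start, region_end = r$end,
           provenance = serialize_provenance(r$provenance))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(0), pos = numeric(0), ref = character(0),
                  alt = character(0), region_start = numeric(0),
                  region_end = numeric(0), provenance = character(0))
  }
  out
}
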