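#' @importFrom rlang abort warn %||%
#' @importFrom dplyr arrange group_by mutate summarise ungroup filter select
#'   bind_rows left_join inner_join distinct lag n
#' @importFrom tibble tibble as_tibble
NULL

#' Supported genome build tags
#' @keywords internal
genome_builds <- function() c("hg19", "hg38")

#' Construct a genome-interval tibble
#'
#' Intervals are BED-style: 0-based, half-open `[start, end)`. This is the
#' single coordinate convention used throughout the package; conversions to
#' and from 1-based systems happen only at the VCF and display boundaries.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; `0 <= start < end`, `end` exclusive.
#' @param build Genome build tag, `"hg19"` or `"hg38"` (scalar or vector).
#' @param provenance Optional list of character vectors; each element holds
#'   `"dataset|tissue"` tokens recording where the interval came from.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `build`,
#'   `provenance` (list column), one row per interval.
#' @examples
#' genome_intervals("chr1", 100, 200, "hg38")
#' @export
genome_intervals <- function(chrom, start, end, build, provenance = NULL) {
  n <- max(length(chrom), length(start), length(end))
  x <- tibble(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end   = rep_len(as.numeric(end), n),
    build = rep_len(as.character(build), n)
  )
  x$provenance <- if (is.null(provenance)) {
    rep(list(character(0)), n)
  } else if (is.character(provenance)) {
    rep(list(provenance), n)
  } else {
    rep_len(provenance, n)
  }
  validate_intervals(x)
}

#' Validate an interval tibble
#' @keywords internal
validate_intervals <- function(x, what = "interval table") {
  req <- c("chrom", "start", "end", "build")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing columns: %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$start) | is.na(x$end))) abort(sprintf("%s has NA coordinates", what))
    if (any(x$start < 0)) abort(sprintf("%s has negative start coordinates", what))
    if (any(x$start >= x$end)) abort(sprintf("%s has start >= end (half-open intervals must be non-empty)", what))
    if (any(is.na(x$chrom) | x$chrom == "")) abort(sprintf("%s has empty chromosome names", what))
    bad <- setdiff(unique(x$build), genome_builds())
    if (length(bad) > 0) {
      abort(sprintf("%s has unsupported genome build(s): %s", what, paste(bad, collapse = ", ")))
    }
  }
  if (!"provenance" %in% names(x)) x$provenance <- rep(list(character(0)), nrow(x))
  as_tibble(x)
}

check_single_build <- function(x, what = "intervals") {
  b <- unique(x$build)
  if (length(b) > 1) {
    abort(sprintf("%s mix genome builds (%s); lift over before combining", what, paste(b, collapse = ", ")))
  }
  invisible(b)
}

#' Pairwise overlap of genome intervals
#'
#' Half-open convention: two intervals overlap iff they are on the same
#' chromosome and share at least one base, i.e. `max(starts) < min(ends)`.
#' Bookended intervals (`end == start`) do not overlap.
#'
#' @param a,b Interval tibbles (see [genome_intervals()]); rows are compared
#'   pairwise, recycling a single row against the other table.
#' @return Logical vector.
#' @examples
#' a <- genome_intervals("chr1", 0, 10, "hg38")
#' b <- genome_intervals("chr1", 9, 20, "hg38")
#' interval_overlaps(a, b)
#' @export
interval_overlaps <- function(a, b) {
  a <- validate_intervals(a, "first interval set")
  b <- validate_intervals(b, "second interval set")
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), ]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), ]
  if (nrow(a) != nrow(b)) abort("interval tables must have equal row counts (or one must be a single row)")
  if (nrow(a) == 0) return(logical(0))
  if (any(a$build != b$build)) {
    abort("cannot compare intervals from different genome builds")
  }
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Merge and collapse overlapping intervals
#'
#' Sorts intervals and collapses runs that overlap or (at `gap = 0`) are
#' bookended, matching the `bedtools merge` default. The provenance of a
#' merged interval is the union of the provenance of its inputs, so every
#' collapsed region can still be traced back to the dataset and tissue it
#' came from. Per-base coverage of the output equals that of the input.
#'
#' @param x Interval tibble.
#' @param gap Non-negative integer; intervals separated by at most `gap`
#'   bases are collapsed together.
#' @return Sorted, pairwise-disjoint interval tibble with unioned provenance.
#' @examples
#' x <- genome_intervals("chr1", c(1, 50), c(100, 150), "hg38")
#' merge_collapse(x)
#' @export
merge_collapse <- function(x, gap = 0) {
  x <- validate_intervals(x)
  stopifnot(gap >= 0)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  build = character(0), provenance = list()))
  }
  check_single_build(x)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  x <- x |>
    group_by(.data$chrom) |>
    mutate(.cluster = cumsum(.data$start > lag(cummax(.data$end), default = -Inf) + gap)) |>
    group_by(.data$chrom, .data$.cluster) |>
    summarise(
      build = .data$build[1],
      provenance = list(sort(unique(unlist(.data$provenance)))),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "build", "provenance") |>
    arrange(.data$chrom, .data$start, .data$end)
  x
}

#' Total span of an interval set in base pairs
#'
#' Collapses first, so overlapping bases are counted once.
#' @param x Interval tibble.
#' @return Numeric scalar, base pairs.
#' @export
total_span <- function(x) {
  x <- merge_collapse(x)
  sum(x$end - x$start)
}

#' Intersection of two interval sets
#'
#' Returns the per-base intersection of two sets (each collapsed first),
#' used e.g. to compute span-based specificity.
#' @param a,b Interval tibbles of the same build.
#' @return Collapsed interval tibble covering exactly the shared bases.
#' @export
interval_intersect <- function(a, b) {
  a <- merge_collapse(a)
  b <- merge_collapse(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(a[0, ])
  }
  if (unique(a$build) != unique(b$build)) abort("cannot intersect intervals from different genome builds")
  hits <- inner_join(
    a |> select("chrom", a_start = "start", a_end = "end", "build"),
    b |> select("chrom", b_start = "start", b_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(start = pmax(.data$a_start, .data$b_start),
           end = pmin(.data$a_end, .data$b_end)) |>
    filter(.data$start < .data$end) |>
    select("chrom", "start", "end", "build")
  hits$provenance <- rep(list(character(0)), nrow(hits))
  merge_collapse(hits)
}

# TRUE per query row iff it overlaps any subject interval; subject must be
# sorted and pairwise disjoint per chromosome (a collapsed set), which lets
# a findInterval binary search replace the pairwise scan
overlaps_any_collapsed <- function(query, subject) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  for (cc in unique(query$chrom)) {
    qi <- which(query$chrom == cc)
    s <- subject[subject$chrom == cc, ]
    if (nrow(s) == 0) next
    qs <- query$start[qi]; qe <- query$end[qi]
    k <- findInterval(qs, s$start)
    hit_left <- k >= 1 & s$end[pmax(k, 1)] > qs
    nxt <- pmin(k + 1, nrow(s))
    hit_right <- k < nrow(s) & s$start[nxt] < qe
    out[qi] <- hit_left | hit_right
  }
  out
}

normalize_chrom_names <- function(chrom) {
  ifelse(grepl("^(chr|Chr)", chrom), sub("^Chr", "chr", chrom), paste0("chr", chrom))
}

serialize_provenance <- function(p) {
  vapply(p, function(v) if (length(v) == 0) "." else paste(sort(unique(v)), collapse = ";"),
         character(1))
}

#' Read a BED file into an interval tibble
#'
#' Accepts BED3+, plain or gzip/bgzip-compressed. `track`/`browser`/`#`
#' header lines are skipped. Column 4 is parsed as provenance when it holds
#' `dataset|tissue` tokens joined by `;`; otherwise it is kept as `name`.
#' Further columns are preserved as `score` and `strand` where present.
#'
#' @param path BED file path.
#' @param build Genome build tag of the file ("hg19" or "hg38"); never inferred.
#' @param normalize_chrom Map bare names like `"1"` to `"chr1"` at load time
#'   (default `TRUE`), smoothing over mixed-source BED dialects.
#' @return Interval tibble; provenance list column populated from column 4.
#' @export
read_bed <- function(path, build, normalize_chrom = TRUE) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- genome_intervals(character(0), numeric(0), numeric(0), character(0))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s line %d: fewer than 3 BED columns", path, line_no[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: non-integer coordinates", path, line_no[bad[1]]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: start >= end", path, line_no[bad[1]]))
  }
  if (normalize_chrom) chrom <- normalize_chrom_names(chrom)
  col <- function(i) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
                           character(1)), NA_character_)
  }
  name <- col(4)
  prov <- lapply(name, function(nm) {
    if (is.na(nm) || nm == "." || !grepl("|", nm, fixed = TRUE)) character(0)
    else strsplit(nm, ";", fixed = TRUE)[[1]]
  })
  out <- tibble(chrom = chrom, start = start, end = end,
                build = build, provenance = prov)
  if (any(nf >= 4)) out$name <- name
  if (any(nf >= 5)) out$score <- col(5)
  if (any(nf >= 6)) out$strand <- col(6)
  validate_intervals(out, path)
}

#' Write an interval tibble as BED
#'
#' Emits sorted BED with provenance serialized into column 4 as
#' `dataset|tissue` tokens joined by `;` (a `.` when empty). An optional
#' UCSC custom-track header line can be prepended so the file can be pasted
#' straight into a genome browser.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param ucsc_track_header Optional track name; writes a
#'   `track name="..."` header line.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, ucsc_track_header = NULL) {
  x <- validate_intervals(x)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  lines <- character(0)
  if (!is.null(ucsc_track_header)) {
    lines <- sprintf('track name="%s"', ucsc_track_header)
  }
  if (nrow(x) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                              as.integer(x$end), serialize_provenance(x$provenance)))
  }
  writeLines(lines, path)
  invisible(path)
}
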