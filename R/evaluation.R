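#' Categorize a variant relative to its gene's transcripts
#'
#' Pathogenic regulatory variants are divided into three groups:
#' `"promoter"` — located 1–100 bp upstream of a transcript start of the
#' gene; `"intragenic"` — within a transcript of the gene but not a
#' promoter variant; `"distal"` — more than 100 bp from the closest
#' transcript start. "Upstream" is strand-aware, consistent with TSS
#' window construction, and the promoter test considers every transcript
#' (precedence promoter > intragenic > distal).
#'
#' @param pos 1-based variant position.
#' @param transcripts Transcripts of the affected gene (>= 1 row).
#' @return `"promoter"`, `"intragenic"` or `"distal"`.
#' @export
categorize_variant <- function(pos, transcripts) {
  if (nrow(transcripts) == 0) abort("categorize_variant: gene has no transcripts")
  p <- pos - 1  # 0-based base
  tss <- ifelse(transcripts$strand == "+", transcripts$tx_start,
                transcripts$tx_end - 1)
  updist <- ifelse(transcripts$strand == "+", tss - p, p - tss)
  if (any(updist >= 1 & updist <= 100)) return("promoter")
  inside <- transcripts$tx_start <= p & p < transcripts$tx_end
  if (any(inside)) return("intragenic")
  "distal"
}

#' Span-based specificity of a tissue-restricted search
#'
#' The fraction of the tissue-unselected result excluded by performing the
#' tissue-specific query, measured on base-pair span:
#' `1 - span(selected intersect unselected) / span(unselected)`. With
#' nested tissue sets the selected result is contained in the unselected
#' one, so this reduces to one minus the span ratio.
#'
#' @param selected `search_result` (or interval tibble) of the
#'   tissue-specific query.
#' @param unselected `search_result` (or interval tibble) of the same
#'   query without tissue restriction; must be non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
compute_specificity <- function(selected, unselected) {
  sel <- if (inherits(selected, "search_result")) selected$intervals else selected
  uns <- if (inherits(unselected, "search_result")) unselected$intervals else unselected
  uns_span <- total_span(uns)
  if (uns_span == 0) abort("compute_specificity: the unselected result is empty")
  shared <- total_span(interval_intersect(sel, uns))
  1 - shared / uns_span
}

read_case_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "pos", "ref", "gene", "best_tissue", "related_tissues", "build")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("case table %s missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  as_tibble(tab)
}

dist_summary <- function(x, prefix) {
  out <- tibble(min = ifelse(length(x) == 0, NA_real_, min(x)),
                mean = ifelse(length(x) == 0, NA_real_, mean(x)),
                median = ifelse(length(x) == 0, NA_real_, median(x)),
                max = ifelse(length(x) == 0, NA_real_, max(x)))
  names(out) <- paste(prefix, names(out), sep = "_")
  out
}

#' Evaluate search performance on a table of variant cases
#'
#' For each case (a known regulatory variant with its affected gene, a
#' best-matching tissue and a wider set of related tissues) three searches
#' are run: single-tissue (best tissue only), multi-tissue (best plus
#' related) and the tissue-unselected control (all tissues in the store).
#' Per category (promoter / intragenic / distal) and scope the harness
#' reports recall (fraction of variants overlapped by the identified
#' regulators), region-count and span distributions, and the span-based
#' specificity of the tissue-restricted searches relative to the
#' unselected control (count-based specificity is emitted alongside).
#' Cases naming tissues absent from the store are flagged, excluded from
#' denominators and reported.
#'
#' @param cases Case tibble or CSV path with columns `chrom`, `pos`, `ref`,
#'   `gene`, `best_tissue`, `related_tissues` (`;`-separated), `build`.
#' @param store Track store.
#' @param registry Transcript registry.
#' @param query_template Tibble of [dataset_config()] rows used for every
#'   search.
#' @param interactions,mirna_loci Optional miRNA branch inputs.
#' @param mirna Optional miRNA configuration list (as in [search_query()]).
#' @return A `regu_evaluation` object: `per_case` (one row per evaluated
#'   case with category, per-scope hit flags, counts, spans and
#'   specificities), `metrics` (per scope x category summary), `flagged`
#'   (excluded cases).
#' @export
evaluate_cases <- function(cases, store, registry, query_template,
                           interactions = NULL, mirna_loci = NULL,
                           mirna = NULL) {
  if (is.character(cases)) cases <- read_case_table(cases)
  if (nrow(cases) == 0) abort("evaluate_cases: empty case list")
  all_tissues <- sort(unique(store$tracks$tissue))

  per_case <- list()
  flagged <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    related <- if (is.na(cs$related_tissues) || cs$related_tissues == "") character(0)
      else strsplit(cs$related_tissues, ";", fixed = TRUE)[[1]]
    case_tissues <- unique(c(cs$best_tissue, related))
    missing <- setdiff(case_tissues, all_tissues)
    if (length(missing) > 0) {
      message(sprintf("evaluate_cases: case %d (%s) names tissue(s) absent from the store (%s); excluded",
                      i, cs$gene, paste(missing, collapse = ", ")))
      flagged[[length(flagged) + 1]] <- cs
      next
    }
    tx <- transcripts_for(registry, cs$gene)
    if (nrow(tx) == 0) {
      message(sprintf("evaluate_cases: case %d gene %s unknown; excluded", i, cs$gene))
      flagged[[length(flagged) + 1]] <- cs
      next
    }
    category <- categorize_variant(cs$pos, tx)
    scopes <- list(single = cs$best_tissue,
                   multi = unique(c(cs$best_tissue, related)),
                   unselected = all_tissues)
    var_iv <- genome_intervals(cs$chrom, cs$pos - 1, cs$pos - 1 + nchar(cs$ref),
                               store$build)
    res <- purrr::map(scopes, function(tis) {
      q <- search_query(store$build, genes = cs$gene, tissues = tis,
                        datasets = query_template, mirna = mirna)
      suppressWarnings(run_search(store, registry, q,
                                  interactions = interactions,
                                  mirna_loci = mirna_loci))
    })
    hit <- purrr::map_lgl(res, function(r) {
      iv <- r$intervals
      any(iv$chrom == var_iv$chrom & pmax(iv$start, var_iv$start) < pmin(iv$end, var_iv$end))
    })
    uns_span <- res$unselected$stats$total_span_bp
    uns_count <- res$unselected$stats$region_count
    spec_span <- purrr::map_dbl(res, function(r) {
      if (uns_span == 0) NA_real_
      else compute_specificity(r, res$unselected)
    })
    spec_count <- purrr::map_dbl(res, function(r) {
      if (uns_count == 0) NA_real_ else 1 - r$stats$region_count / uns_count
    })
    per_case[[length(per_case) + 1]] <- tibble(
      case = i, gene = cs$gene, chrom = cs$chrom, pos = cs$pos,
      category = category,
      hit_single = hit[["single"]], hit_multi = hit[["multi"]],
      hit_unselected = hit[["unselected"]],
      regions_single = res$single$stats$region_count,
      regions_multi = res$multi$stats$region_count,
      regions_unselected = uns_count,
      span_single = res$single$stats$total_span_bp,
      span_multi = res$multi$stats$total_span_bp,
      span_unselected = uns_span,
      specificity_single = spec_span[["single"]],
      specificity_multi = spec_span[["multi"]],
      specificity_count_single = spec_count[["single"]],
      specificity_count_multi = spec_count[["multi"]]
    )
  }
  per_case <- bind_rows(per_case)
  if (nrow(per_case) == 0) abort("evaluate_cases: every case was flagged; nothing to evaluate")

  cell <- function(df, scope) {
    hits <- df[[paste0("hit_", scope)]]
    out <- tibble(scope = scope, n_cases = nrow(df), n_identified = sum(hits),
                  recall = mean(hits))
    out <- bind_cols(out,
                     dist_summary(df[[paste0("regions_", scope)]], "regions"),
                     dist_summary(df[[paste0("span_", scope)]], "span_bp"))
    out$specificity <- if (scope == "unselected") 0 else
      median(df[[paste0("specificity_", scope)]], na.rm = TRUE)
    out$specificity_count <- if (scope == "unselected") 0 else
      median(df[[paste0("specificity_count_", scope)]], na.rm = TRUE)
    out
  }
  groups <- c(list(overall = per_case),
              split(per_case, per_case$category))
  metrics <- purrr::imap(groups, function(df, nm) {
    bind_rows(cell(df, "single"), cell(df, "multi"), cell(df, "unselected")) |>
      mutate(category = nm, .before = 1)
  }) |> bind_rows()

  structure(list(per_case = per_case, metrics = metrics,
                 flagged = bind_rows(flagged)),
            class = "regu_evaluation")
}

#' @export
print.regu_evaluation <- function(x, ...) {
  ov <- x$metrics[x$metrics$category == "overall", ]
  cat(sprintf("<regu_evaluation> %d case(s); recall single/multi/unselected: %.3f/%.3f/%.3f\n",
              nrow(x$per_case),
              ov$recall[ov$scope == "single"], ov$recall[ov$scope == "multi"],
              ov$recall[ov$scope == "unselected"]))
  invisible(x)
}

#' Tidy evaluation metrics
#' @param x A `regu_evaluation`.
#' @param ... Unused.
#' @return The per-(category, scope) metrics tibble.
#' @method tidy regu_evaluation
#' @export
tidy.regu_evaluation <- function(x, ...) x$metrics

#' Overall evaluation summary
#' @param x A `regu_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with overall recalls and median specificities.
#' @method glance regu_evaluation
#' @export
glance.regu_evaluation <- function(x, ...) {
  ov <- x$metrics[x$metrics$category == "overall", ]
  g <- function(scope, colnm) ov[[colnm]][ov$scope == scope]
  tibble(n_cases = nrow(x$per_case),
         recall_single = g("single", "recall"),
         recall_multi = g("multi", "recall"),
         recall_unselected = g("unselected", "recall"),
         specificity_single = g("single", "specificity"),
         specificity_multi = g("multi", "specificity"),
         n_flagged = nrow(x$flagged))
}

#' Plot evaluation recall by scope and category
#' @param object A `regu_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regu_evaluation
#' @export
autoplot.regu_evaluation <- function(object, ...) {
  m <- object$metrics
  m$scope <- factor(m$scope, levels = c("single", "multi", "unselected"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$scope, y = .data$recall,
                                  fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "tissue scope", y = "recall", fill = "variant category") +
    ggplot2::theme_minimal()
}

#' Write a Table-1-style evaluation report
#'
#' @param x A `regu_evaluation`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(x, path) {
  readr::write_csv(x$metrics, path)
  invisible(path)
}
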