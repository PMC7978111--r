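---
title: "Searching tissue-specific regulatory regions and filtering noncoding variants"
author: "regusearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching tissue-specific regulatory regions and filtering noncoding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regusearch)
library(dplyr)
```

## The problem

Most known disease mutations sit in coding sequence, but a substantial
fraction of unsolved monogenic cases are expected to carry causative
variants in *regulatory* DNA: promoters, enhancers and other
transcription-factor binding sites, accessible chromatin, and miRNA genes
whose products repress the disease gene. Genome-wide catalogues of such
elements exist (ChIP-seq and DNase-seq tracks, CAGE-derived promoters,
candidate cis-regulatory elements, miRNA–target databases), but they are
tissue-resolved and enormous; the practical question for a diagnostic
analyst is: *which regulatory regions plausibly control my genes of
interest in the tissues affected by this disorder?* Once that region set is
in hand, a patient's VCF can be reduced to the handful of variants falling
inside it.

`regusearch` implements this workflow as a library plus a small CLI:
a track store for tissue-labelled regulatory datasets, a TSS-anchored
search protocol with *active-in-any* / *active-in-all* tissue semantics, a
miRNA branch gated by accessible chromatin, VCF filtering, and an
evaluation harness that measures recall on known regulatory variants and
the specificity gained by restricting the search to relevant tissues.

## Coordinate model

All intervals are BED-style, 0-based, half-open `[start, end)`, tagged with
a genome build (`hg19`/`hg38`); mixing builds in one operation is an error,
never a silent mismatch. Conversion to 1-based coordinates happens only at
two boundaries: VCF positions on input and UCSC position strings on
display. Two intervals overlap iff they share at least one base
(`max(starts) < min(ends)`), so bookended intervals do not overlap — but
`merge_collapse()` *does* merge bookended intervals at `gap = 0`, matching
the `bedtools merge` default used to collapse biological replicates.
Every merged interval carries the union of its inputs' `dataset|tissue`
provenance tokens, so a collapsed result can always be traced back to its
supporting experiments.

## The search protocol

A query names a build, target genes (HGNC symbols, matched
case-insensitively, aliases not resolved), target tissues, and per-dataset
configuration. For each enabled dataset:

1. A TSS window is built around the first transcribed base of **every**
   transcript of each target gene: `[TSS - upstream, TSS + downstream]`,
   taken in the direction of transcription and always containing the TSS
   base itself (a 0/0 window is still a searchable 1-bp interval). The
   window is clamped at position 0.
2. A region of the dataset is selected if it overlaps any TSS window
   **and** the tissue condition holds: under *active-in-any*, the region
   must be present (≥ 1 bp overlap) in at least one target-tissue track of
   the dataset; under *active-in-all*, in every **available** target-tissue
   track — a queried tissue with no track in that dataset does not veto.

Presence is defined by ≥ 1 bp overlap rather than coordinate identity
because peak boundaries differ between tissue tracks of the same assay.
The miRNA branch adds the transcript loci of miRNAs that (a) interact with
a target gene in the chosen interaction source and (b) overlap an
accessible-chromatin track of a target tissue — the mechanism by which
tissue-agnostic interaction databases are restricted to the tissues of
interest. Finally all selected regions are merged and collapsed into one
sorted, disjoint result with full provenance.

Two design points were genuinely open and are resolved as follows. First,
"upstream" of a TSS is taken strand-aware (the biological meaning of
upstream); a `strand_aware = FALSE` switch provides the genomic-left
alternative for comparability. Second, any accessible-chromatin track may
support the miRNA condition, with an optional `chromatin_datasets`
restriction, since the gating logic does not depend on which assay produced
the open-chromatin call.

## Data preparation

* **CAGE promoters** (`promoters_from_cage()`): peaks with normalized TPM
  expression *strictly below* 10 are dropped (a peak at exactly 10
  survives); each surviving peak, which marks a TSS, is extended 200 bp
  upstream in the direction of transcription, clamped at 0, and the result
  collapsed. Peak tables are split per tissue before filtering, so the
  threshold applies within each tissue track.
* **ccRE splitting** (`split_ccres()`): class-annotated records are divided
  into promoter / enhancer / insulator / accessible-chromatin tracks by
  token matching (`PLS`, `*ELS`, `CTCF`, `DNase`, ...); unrecognized tokens
  are skipped and counted, and an input with no recognizable token at all
  is an error.
* **Replicates** (`collapse_replicates()`, or multiple paths passed to
  `register_track()`): tracks sharing a (dataset, tissue, class, build) key
  — including pre-lifted data; liftOver itself is external preprocessing —
  are merged so the per-base coverage is the union of the inputs.
* **miRNA interactions** (`load_interactions()`): predicted interactions
  are kept only when they target the 3′-UTR; duplicates keep the strongest
  evidence tag under an optional user ranking, with an alphabetical
  tie-break for determinism since evidence vocabularies differ between
  sources.

## Variant filtering and categories

`filter_vcf()` keeps records whose REF span — 0-based
`[POS-1, POS-1+len(REF))` — overlaps at least one region, so a deletion
straddling a region edge is kept even when POS lies outside it: a
regulatory deletion's effect is its span, not its anchor base. Symbolic
alleles are matched on the POS base only, with a warning. The output
preserves the header and kept record lines byte-for-byte, in input order;
no re-normalization is performed.

For evaluation, variants are categorized relative to the affected gene's
transcripts with precedence promoter > intragenic > distal: *promoter* if
1–100 bp upstream (strand-aware) of any transcript start, *intragenic* if
within any transcript but not promoter, otherwise *distal*.

## Evaluation harness

Each case (variant, gene, best-matching tissue, wider related-tissue list)
is searched three ways: single-tissue, multi-tissue, and the
tissue-unselected control over every tissue in the store. Recall is the
fraction of variants overlapped by the identified regions. Specificity is
span-based: the fraction of the unselected result's base-pair span excluded
by the tissue-restricted query,
`1 − span(selected ∩ unselected) / span(unselected)`; a count-based variant
is emitted alongside. Per-cell summaries report median (plus min/mean/max)
region counts and spans, and the harness aggregates per-case specificities
by their median. With nested tissue sets, recall is monotonically
non-decreasing and specificity non-increasing from single-tissue to
unselected — the qualitative structure the test suite asserts.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` materialises a seeded synthetic study on two 5-Mb
synthetic chromosomes (`chrS1`, `chrS2`), chosen so that no real genomic
coordinate is implied:

* 12 genes with 1–3 transcripts each, on both strands;
* 4 tissues × 3 datasets whose decoy tracks mimic the density contrasts of
  real collections — sparse narrow enhancer-like tracks (40 regions of
  100–600 bp per track), medium promoter-like tracks (80 × 150–350 bp), and
  dense wide accessible-chromatin-like tracks (150 × 200–2000 bp);
* 12 evaluation cases cycling through the promoter / intragenic / distal
  categories: 8 whose planted regulator is active in the best-matching
  tissue, 2 active only in a related tissue, and 2 active only in an
  unrelated tissue — the structural analogue of real benchmark misses where
  a causative enhancer is present only in tracks vaguely related to the
  phenotype, so the tissue-specific search misses it and the unselected
  control finds it;
* a single-sample VCF holding the 12 case SNVs, a deletion straddling a
  planted region's edge, an MNV inside it, a bookended deletion just
  outside it, and 30 decoy variants placed outside every track region;
* a truth table recording, per case, the minimal query that must recover
  the plant and a query that must not.

Decoy intervals avoid planted spans by a 1-kb margin, which is what makes
the truth table exact. The generator emulates the *combinatorial* structure
of the problem (tissue specificity, window anchoring, provenance, category
geometry), not chromatin biology: decoys are uniform, plants are placed
relative to TSSs by construction, and there is no correlation between
datasets. Passing tests therefore demonstrate the correctness of the
search, filtering and evaluation logic under known ground truth — not
biological performance on real ENCODE/FANTOM-scale data, whose recall and
specificity depend on the tracks themselves.

Default search spans are `upstream_bp = downstream_bp = 50000` with
*active-in-any* mode; real tools ship per-dataset defaults that are not
published, so here they are ordinary explicit configuration, used
consistently by the evaluation template and the fixture.

## Numerical and degenerate-input choices

* Merging uses `gap = 0` (bookended inputs merge); a positive gap is
  available but nothing in the pipeline uses one by default.
* Output ordering is deterministic everywhere: lexicographic chromosome,
  then start, then end; provenance tokens are sorted and de-duplicated.
* Chromosome names are compared verbatim; an on-by-default load-time
  normalization maps `1` → `chr1` to absorb mixed BED dialects.
* An empty search result exports valid empty outputs (a header-only BED),
  not an error; an empty *unselected* result makes specificity undefined
  and errors.
* The interval engine is validated against a per-base brute-force oracle
  (coverage vectors over enumerated bases) and cross-checked against
  `IRanges::reduce`; the search engine against a literal re-check of the
  selection conditions with independent window arithmetic. Test problem
  sizes — 1000 random interval instances of up to 200 intervals on 100-kb
  chromosomes, toy stores of 3 datasets × 4 tissues with under 500 regions,
  100 monotonicity queries — were chosen so the whole suite exercises every
  code path at desk scale.

## Known limitations

* The store is in-memory; tracks are desk-scale exports, not the
  multi-gigabyte portal releases, and no tabix indexing is provided.
* Gene symbols are matched without alias resolution; a stale symbol simply
  reports as unknown.
* liftOver is out of scope: pre-lifted BEDs are ingested as ordinary
  replicate tracks.
* Specificity compares a query against its own unselected control; it is
  not an FDR and has no calibration against a null.

## A worked example

```{r example, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 1), tempfile("fx"))

query <- search_query(
  "hg38", genes = "GENE01", tissues = "pancreas",
  datasets = dataset_config("FANTOM_enh", 50000, 50000, "any"))
res <- run_search(fx$store, fx$registry, query)
res
tidy(res)           # one row per (interval, dataset, tissue)
autoplot(res)

filter_vcf(fx$paths$vcf, res, "candidates.vcf", build = "hg38")

template <- dplyr::bind_rows(lapply(fx$spec$datasets$dataset, dataset_config))
ev <- evaluate_cases(fx$cases, fx$store, fx$registry, template)
glance(ev)
```
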