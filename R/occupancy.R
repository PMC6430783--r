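# Peak occupancy classification, promoter factor combinations, TF-overload
# ranking and double-positive SE sets.

#' Classify peaks into cis-regulatory categories
#'
#' Assigns each peak to Promoter, Enhancer_SE, Enhancer_TE or Other by at
#' least one base of overlap, with precedence Promoter > Enhancer_SE >
#' Enhancer_TE > Other. The promoter window is strand-aware: -1000/+200 bp
#' around the TSS in the transcription direction. When an expression matrix
#' is supplied, promoter windows are restricted to active genes (mean FPKM
#' above `active_threshold`); otherwise all promoters are used.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @param se_call An `se_call` object (or enhancer tibble with `chrom`,
#'   `start`, `end`, `is_se`).
#' @param upstream,downstream Promoter window sizes (defaults 1000 / 200).
#' @param expr Optional expression tibble for the active-promoter filter.
#' @param active_threshold Mean-FPKM activity cutoff (default 0.5).
#' @param precedence Category order, highest first.
#' @return List: `peaks` (input with `category` column) and `fractions`
#'   (category counts and fractions; fractions sum to 1).
#' @export
classify_peaks <- function(peaks, genes, se_call,
                           upstream = 1000, downstream = 200,
                           expr = NULL, active_threshold = 0.5,
                           precedence = c("Promoter", "Enhancer_SE",
                                          "Enhancer_TE")) {
  enh <- if (inherits(se_call, "se_call")) se_call$enhancers else se_call
  if (!is.null(expr)) {
    active <- filter_active(expr, threshold = active_threshold)
    genes <- genes[genes$gene_id %in% active, , drop = FALSE]
  }
  prom <- promoter_windows(genes, upstream = upstream, downstream = downstream)
  overlaps_any <- function(b) {
    if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(peaks)))
    IRanges::overlapsAny(as_granges(peaks), as_granges(b))
  }
  sets <- list(
    Promoter = prom,
    Enhancer_SE = enh[enh$is_se, c("chrom", "start", "end"), drop = FALSE],
    Enhancer_TE = enh[!enh$is_se, c("chrom", "start", "end"), drop = FALSE]
  )
  category <- rep("Other", nrow(peaks))
  for (cat in rev(precedence)) category[overlaps_any(sets[[cat]])] <- cat
  lev <- c(precedence, "Other")
  counts <- table(factor(category, levels = lev))
  fractions <- tibble(category = lev, n = as.integer(counts),
                      fraction = as.integer(counts) / max(nrow(peaks), 1L))
  peaks$category <- category
  list(peaks = peaks, fractions = fractions)
}

#' Promoter occupancy by a set of factors
#'
#' For each gene, the set of factors with at least one peak in the gene's
#' promoter window (-1000/+200, strand-aware), the combination histogram
#' (e.g. BRD4-only, BRD2/4), and the co-occupancy fraction: genes bound by
#' two or more factors among genes bound by at least one. Duplicate peaks
#' within a factor do not change the result.
#'
#' @param genes Gene tibble.
#' @param factor_peaks Named list of peak tibbles, one per factor.
#' @param upstream,downstream Promoter window sizes.
#' @return List: `occupancy` (gene_id, factors list-column, n_factors,
#'   combination label), `histogram` (combination counts over bound genes),
#'   `co_occupancy` fraction (NA with a warning when no gene is bound).
#' @export
promoter_occupancy <- function(genes, factor_peaks,
                               upstream = 1000, downstream = 200) {
  stopifnot(length(factor_peaks) >= 1, !is.null(names(factor_peaks)))
  prom <- promoter_windows(genes, upstream = upstream, downstream = downstream)
  prom_gr <- as_granges(prom)
  bound <- matrix(FALSE, nrow(genes), length(factor_peaks),
                  dimnames = list(genes$gene_id, names(factor_peaks)))
  for (f in names(factor_peaks)) {
    p <- factor_peaks[[f]]
    if (nrow(p) > 0) {
      bound[, f] <- IRanges::overlapsAny(prom_gr, as_granges(p))
    }
  }
  fac_sets <- apply(bound, 1, function(r) names(factor_peaks)[r],
                    simplify = FALSE)
  combo <- vapply(fac_sets, function(s)
    if (length(s) == 0) "none" else paste(sort(s), collapse = "/"), "")
  occ <- tibble(gene_id = genes$gene_id, factors = unname(fac_sets),
                n_factors = unname(lengths(fac_sets)),
                combination = unname(combo))
  pos <- occ[occ$n_factors > 0, , drop = FALSE]
  hist <- pos %>% dplyr::count(.data$combination, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  co <- if (nrow(pos) == 0) {
    warn("promoter_occupancy: no bound genes, co-occupancy undefined")
    NA_real_
  } else {
    sum(pos$n_factors >= 2) / nrow(pos)
  }
  list(occupancy = occ, histogram = hist, co_occupancy = co)
}

#' Rank TF-overloaded enhancers from the TF's own signal
#'
#' Runs the full SE-calling chain (TSS exclusion, stitching,
#' signal ranking, inflection cutoff, gene assignment) on a transcription
#' factor's peaks and signal track: regions above the cutoff are the
#' "TF-overloaded" enhancers. Identical inputs reproduce
#' [call_superenhancers()] exactly (same code path).
#'
#' @param tf_peaks TF peak tibble.
#' @param tf_signal TF signal track.
#' @param genes Gene tibble.
#' @param input Optional input track.
#' @param ... Passed to [call_superenhancers()] (stitch_distance, tss_pad,
#'   flank, sample_id).
#' @return An `se_call` object; `is_se` marks TF-overloaded regions.
#' @export
tf_overload_rank <- function(tf_peaks, tf_signal, genes, input = NULL, ...) {
  call_superenhancers(tf_peaks, tf_signal, genes, input = input, ...)
}

#' Double-positive gene sets (Venn partition)
#'
#' Genes supported by both factors' overloaded enhancers, plus the one-sided
#' differences for Venn output. `|both| + |a_only| = |a|` by construction.
#'
#' @param se_genes_a,se_genes_b Character vectors of gene ids.
#' @return List: `both`, `a_only`, `b_only`, and `counts` tibble.
#' @export
double_positive <- function(se_genes_a, se_genes_b) {
  a <- unique(se_genes_a); b <- unique(se_genes_b)
  both <- intersect(a, b)
  list(both = both, a_only = setdiff(a, b), b_only = setdiff(b, a),
       counts = tibble(set = c("both", "a_only", "b_only"),
                       n = c(length(both), length(setdiff(a, b)),
                             length(setdiff(b, a)))))
}

#' Signal enrichment by enhancer class (SE vs TE)
#'
#' Mean signal density (area / width over the region span) of a factor's
#' track within each stitched enhancer, split by SE/TE class, with class
#' medians. An empty class is flagged instead of tested.
#'
#' @param tf_signal Signal track to quantify.
#' @param se_call An `se_call` object (or enhancer tibble with `is_se`).
#' @return List: `densities` tibble (`region_id`, `is_se`, `density`),
#'   `medians` (named: SE, TE), `flagged` (empty classes), and
#'   `comparison` (unpaired rank test SE vs TE, NULL when flagged).
#' @export
enrichment_by_region_class <- function(tf_signal, se_call) {
  enh <- if (inherits(se_call, "se_call")) se_call$enhancers else se_call
  area <- interval_signal(tf_signal, enh[, c("chrom", "start", "end")])
  d <- tibble(region_id = enh$region_id, is_se = enh$is_se,
              density = area / (enh$end - enh$start))
  med <- c(SE = stats::median(d$density[d$is_se]),
           TE = stats::median(d$density[!d$is_se]))
  flagged <- names(med)[c(sum(d$is_se), sum(!d$is_se)) == 0]
  comparison <- NULL
  if (length(flagged) > 0) {
    warn(paste0("enrichment_by_region_class: empty class ",
                paste(flagged, collapse = ", "), ", no test"))
  } else if (sum(d$is_se) >= 2 && sum(!d$is_se) >= 2) {
    comparison <- rank_test(d$density[d$is_se], d$density[!d$is_se],
                            paired = FALSE, alternative = "greater")
  }
  list(densities = d, medians = med, flagged = flagged,
       comparison = comparison)
}
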