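# ROSE-style super-enhancer calling: TSS exclusion, stitching,
# input-subtracted ranking, geometric inflection cutoff, hockey-stick
# normalization and gene assignment.

#' Remove TSS-proximal bases from peaks
#'
#' Subtracts the union of TSS exclusion zones (`tss - pad` .. `tss + pad`,
#' inclusive on both ends) from every peak. Peaks fully inside an exclusion
#' zone are dropped; straddling peaks are split/truncated into their
#' remaining parts. Original peak extents are retained in `orig_start` /
#' `orig_end` for constituent reporting.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble (needs `chrom`, `tss`).
#' @param pad Exclusion half-width in bases (default 1250).
#' @return Peak tibble of remaining fragments.
#' @export
exclude_tss <- function(peaks, genes, pad = 1250) {
  stopifnot(pad >= 0)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(dplyr::mutate(peaks, orig_start = .data$start, orig_end = .data$end))
  }
  zones <- tibble(chrom = genes$chrom,
                  start = pmax(0, genes$tss - pad),
                  end = genes$tss + pad + 1)
  zones <- merge_intervals(zones)
  out <- vector("list", nrow(peaks))
  zsplit <- split(zones, zones$chrom)
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$start[i]; e <- peaks$end[i]
    z <- zsplit[[peaks$chrom[i]]]
    frags_s <- numeric(0); frags_e <- numeric(0)
    cur <- s
    if (!is.null(z)) {
      z <- z[z$end > s & z$start < e, , drop = FALSE]
      for (j in seq_len(nrow(z))) {
        if (z$start[j] > cur) {
          frags_s <- c(frags_s, cur); frags_e <- c(frags_e, min(z$start[j], e))
        }
        cur <- max(cur, z$end[j])
      }
    }
    if (cur < e) { frags_s <- c(frags_s, cur); frags_e <- c(frags_e, e) }
    if (length(frags_s) > 0) {
      row <- peaks[rep(i, length(frags_s)), , drop = FALSE]
      row$orig_start <- row$start; row$orig_end <- row$end
      row$start <- frags_s; row$end <- frags_e
      out[[i]] <- row
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- dplyr::mutate(peaks[0, , drop = FALSE],
                         orig_start = double(0), orig_end = double(0))
  }
  res
}

# Merge overlapping/touching intervals into a sorted disjoint set.
# Base-R implementation: called once per stitched region in the scoring hot
# path.
merge_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  ord <- order(df$chrom, df$start)
  chrom <- df$chrom[ord]; start <- df$start[ord]; end <- df$end[ord]
  run_end <- cummax_by(end, chrom)
  n <- length(start)
  grp <- cumsum(c(TRUE, chrom[-1] != chrom[-n] |
                    start[-1] > run_end[-n]))
  first <- !duplicated(grp)
  tibble(chrom = chrom[first],
         start = start[first],
         end = as.numeric(tapply(end, grp, max)))
}

# Running max of x restarted at each change of group g (g sorted).
cummax_by <- function(x, g) {
  unlist(lapply(split(x, factor(g, levels = unique(g))), cummax),
         use.names = FALSE)
}

#' Stitch peaks into enhancer regions
#'
#' Merges peaks whose gap (`start_next - end_prev`) is at most `distance`
#' bases, taking the transitive closure per chromosome. The region span is
#' the minimum start to the maximum end of its constituents.
#'
#' @param peaks Peak tibble (any extra columns are kept per constituent).
#' @param distance Maximum stitching gap in bases (default 12500, the
#'   classic ROSE stitching window).
#' @return Region tibble: `region_id`, `chrom`, `start`, `end`,
#'   `n_constituents` and a `constituents` list-column of peak tibbles.
#' @export
stitch <- function(peaks, distance = 12500) {
  if (nrow(peaks) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = double(), end = double(),
                  n_constituents = integer(), constituents = list()))
  }
  stopifnot(distance >= 0)
  peaks <- arrange(peaks, .data$chrom, .data$start, .data$end)
  run_end <- cummax_by(peaks$end, peaks$chrom)
  new_grp <- c(TRUE, peaks$chrom[-1] != peaks$chrom[-nrow(peaks)] |
                 peaks$start[-1] - run_end[-nrow(peaks)] > distance)
  grp <- cumsum(new_grp)
  parts <- split(peaks, grp)
  tibble(
    region_id = vapply(parts, function(p)
      sprintf("%s:%d-%d", p$chrom[1], as.integer(min(p$start)),
              as.integer(max(p$end))), "", USE.NAMES = FALSE),
    chrom = vapply(parts, function(p) p$chrom[1], "", USE.NAMES = FALSE),
    start = vapply(parts, function(p) min(p$start), 0, USE.NAMES = FALSE),
    end = vapply(parts, function(p) max(p$end), 0, USE.NAMES = FALSE),
    n_constituents = vapply(parts, nrow, 0L, USE.NAMES = FALSE),
    constituents = unname(parts)
  )
}

#' Score and rank stitched regions by input-subtracted signal
#'
#' Computes ChIP and input signal areas per region and ranks regions by net
#' signal `max(chip - input, 0)` in descending order. Signal is quantified
#' over the union of constituent intervals when present (so TSS-excluded
#' bases do not contribute), otherwise over the region span. Ties are broken
#' by wider region first, then leftmost coordinate.
#'
#' @param regions Region tibble from [stitch()].
#' @param chip,input Signal-track tibbles; `input` may be NULL (no
#'   subtraction).
#' @return The region tibble sorted by `rank`, with `chip_signal`,
#'   `input_signal`, `net_signal` and `rank` columns.
#' @export
score_and_rank <- function(regions, chip, input = NULL) {
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, chip_signal = double(0),
                         input_signal = double(0), net_signal = double(0),
                         rank = integer(0)))
  }
  quant <- if ("constituents" %in% names(regions)) {
    lapply(regions$constituents, function(p)
      merge_intervals(p[, c("chrom", "start", "end")]))
  } else {
    lapply(seq_len(nrow(regions)), function(i) regions[i, c("chrom", "start", "end")])
  }
  flat <- bind_rows(quant, .id = ".region")
  flat$.region <- as.integer(flat$.region)
  chip_a <- interval_signal(chip, flat)
  inp_a <- if (is.null(input)) rep(0, nrow(flat)) else interval_signal(input, flat)
  regions$chip_signal <- as.numeric(rowsum(chip_a, flat$.region))
  regions$input_signal <- as.numeric(rowsum(inp_a, flat$.region))
  # net signal is reported at 1e-6 precision so that tie-breaking does not
  # depend on the order of floating-point accumulation
  regions$net_signal <- round(pmax(regions$chip_signal - regions$input_signal,
                                   0), 6)
  ord <- order(-regions$net_signal, -(regions$end - regions$start),
               regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  regions
}

#' Geometric inflection cutoff on a ranked signal curve
#'
#' Rescales the ascending signal-vs-rank curve to the unit square and finds
#' the first point where the discrete slope exceeds 1 (the point a diagonal
#' tangent touches). Regions with signal strictly above the cutoff value are
#' super-enhancers. Degenerate inputs (fewer than 3 regions, all-equal or
#' perfectly linear signals) yield zero SEs with a warning.
#'
#' @param net_signals Numeric vector of net signals (any order).
#' @return List with `cutoff_value` (NA when degenerate), `n_se`, and
#'   `is_se`, a logical vector aligned with `net_signals`.
#' @export
find_inflection <- function(net_signals) {
  n <- length(net_signals)
  degenerate <- function(msg) {
    warn(paste0("find_inflection: ", msg, "; calling zero super-enhancers"))
    list(cutoff_value = NA_real_, n_se = 0L, is_se = rep(FALSE, n))
  }
  if (n < 3) return(degenerate("fewer than 3 regions"))
  ys <- sort(net_signals)
  if (diff(range(ys)) == 0) return(degenerate("all signals equal"))
  ysc <- (ys - ys[1]) / (ys[n] - ys[1])
  slopes <- diff(ysc) * (n - 1)  # x-step is 1/(n-1) on the unit square
  k <- which(slopes > 1 + 1e-9)
  if (length(k) == 0) return(degenerate("no slope exceeds the diagonal"))
  cutoff <- ys[k[1]]
  is_se <- net_signals > cutoff
  list(cutoff_value = cutoff, n_se = sum(is_se), is_se = is_se)
}

#' Hockey-stick normalization of an enhancer table
#'
#' Populates `relative_rank = rank / (n_se + n_te)` and
#' `pct_signal = 100 * net / sum(net)` so that every sample's ranked curve
#' lives on comparable axes; `sum(pct_signal)` is 100 by construction.
#'
#' @param enhancers Ranked enhancer tibble with `rank` and `net_signal`.
#' @return The tibble with `relative_rank` and `pct_signal` columns added.
#' @export
hockey_normalize <- function(enhancers) {
  total <- sum(enhancers$net_signal)
  if (!is.finite(total) || total <= 0) {
    abort("hockey_normalize: total net signal is zero")
  }
  enhancers$relative_rank <- enhancers$rank / nrow(enhancers)
  enhancers$pct_signal <- 100 * enhancers$net_signal / total
  enhancers
}

#' Assign genes to enhancer regions
#'
#' Each region is assigned every gene whose TSS lies within
#' `[start - flank, end + flank)`; regions with no such gene fall back to
#' the single nearest-TSS gene. The nearest gene (minimum TSS distance to
#' the region) is always reported.
#'
#' @param regions Region tibble (`region_id`, `chrom`, `start`, `end`).
#' @param genes Gene tibble.
#' @param flank Flanking distance in bases (default 50000).
#' @return The region tibble with `genes` (list of gene_id vectors) and
#'   `nearest_gene` columns.
#' @export
assign_genes <- function(regions, genes, flank = 50000) {
  if (nrow(genes) == 0) {
    warn("assign_genes: empty gene set")
    regions$genes <- rep(list(character(0)), nrow(regions))
    regions$nearest_gene <- NA_character_
    return(regions)
  }
  gsplit <- split(genes, genes$chrom)
  res <- lapply(seq_len(nrow(regions)), function(i) {
    g <- gsplit[[regions$chrom[i]]]
    if (is.null(g)) return(list(genes = character(0), nearest = NA_character_))
    s <- regions$start[i]; e <- regions$end[i]
    dist <- ifelse(g$tss >= s & g$tss < e, 0,
                   pmin(abs(g$tss - s), abs(g$tss - (e - 1))))
    hit <- g$gene_id[g$tss >= s - flank & g$tss < e + flank]
    nearest <- g$gene_id[which.min(dist)]
    if (length(hit) == 0) hit <- nearest
    list(genes = hit, nearest = nearest)
  })
  regions$genes <- lapply(res, `[[`, "genes")
  regions$nearest_gene <- vapply(res, `[[`, "", "nearest")
  regions
}

#' Call super-enhancers from peaks and signal tracks
#'
#' The full ROSE-style chain: TSS exclusion, stitching, input-subtracted
#' scoring and ranking, geometric inflection cutoff, hockey-stick
#' normalization and gene assignment.
#'
#' @param peaks Peak tibble (e.g. H3K27ac constituent peaks).
#' @param chip ChIP signal track.
#' @param genes Gene tibble.
#' @param input Matched input signal track, or NULL.
#' @param stitch_distance Stitching gap in bases (default 12500).
#' @param tss_pad TSS exclusion half-width (default 1250).
#' @param flank Gene-assignment flank (default 50000).
#' @param sample_id Label carried into the result.
#' @return An object of class `se_call`: use [tidy.se_call()] for the
#'   per-enhancer table, [glance.se_call()] for the one-row summary, and
#'   [autoplot.se_call()] for the hockey-stick plot.
#' @export
call_superenhancers <- function(peaks, chip, genes, input = NULL,
                                stitch_distance = 12500, tss_pad = 1250,
                                flank = 50000, sample_id = "sample") {
  frags <- exclude_tss(peaks, genes, pad = tss_pad)
  regions <- stitch(frags, distance = stitch_distance)
  regions <- score_and_rank(regions, chip, input)
  if (nrow(regions) == 0) abort("call_superenhancers: no regions after TSS exclusion")
  cut <- find_inflection(regions$net_signal)
  regions$is_se <- cut$is_se
  regions <- hockey_normalize(regions)
  regions <- assign_genes(regions, genes, flank = flank)
  structure(
    list(enhancers = regions, cutoff_value = cut$cutoff_value,
         n_se = sum(regions$is_se), n_te = sum(!regions$is_se),
         sample_id = sample_id,
         params = list(stitch_distance = stitch_distance, tss_pad = tss_pad,
                       flank = flank)),
    class = "se_call")
}

#' Genes associated with called super-enhancers
#'
#' @param x An `se_call` object.
#' @param se_only Restrict to regions above the inflection cutoff
#'   (default TRUE; FALSE gives all enhancer-associated genes).
#' @return Character vector of gene ids.
#' @export
se_genes <- function(x, se_only = TRUE) {
  stopifnot(inherits(x, "se_call"))
  enh <- x$enhancers
  if (se_only) enh <- enh[enh$is_se, , drop = FALSE]
  unique(unlist(enh$genes))
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("<se_call> sample '%s': %d stitched enhancers (%d SE, %d TE), cutoff %.4g\n",
              x$sample_id, nrow(x$enhancers), x$n_se, x$n_te, x$cutoff_value))
  invisible(x)
}

#' Tidy a super-enhancer call into a per-enhancer tibble
#'
#' @param x An `se_call` object.
#' @param ... Unused.
#' @return Tibble with one row per stitched enhancer: coordinates, signals,
#'   rank, SE label, normalized rank/signal share, assigned genes
#'   (comma-separated) and nearest gene.
#' @export
tidy.se_call <- function(x, ...) {
  enh <- x$enhancers
  tibble(
    sample_id = x$sample_id,
    region_id = enh$region_id, chrom = enh$chrom,
    start = enh$start, end = enh$end,
    n_constituents = enh$n_constituents,
    chip_signal = enh$chip_signal, input_signal = enh$input_signal,
    net_signal = enh$net_signal, rank = enh$rank, is_se = enh$is_se,
    relative_rank = enh$relative_rank, pct_signal = enh$pct_signal,
    genes = vapply(enh$genes, paste, "", collapse = ","),
    nearest_gene = enh$nearest_gene
  )
}

#' One-row summary of a super-enhancer call
#'
#' @param x An `se_call` object.
#' @param ... Unused.
#' @return One-row tibble: sample, enhancer counts, cutoff value and the
#'   share of total signal captured by SEs.
#' @export
glance.se_call <- function(x, ...) {
  enh <- x$enhancers
  tibble(sample_id = x$sample_id, n_enhancers = nrow(enh),
         n_se = x$n_se, n_te = x$n_te, cutoff_value = x$cutoff_value,
         se_pct_signal = sum(enh$pct_signal[enh$is_se]))
}

#' Hockey-stick plot of a super-enhancer call
#'
#' Relative enhancer rank against percentage of total signal, with the SE
#' population highlighted above the inflection cutoff.
#'
#' @param object An `se_call` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_call <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$relative_rank,
                                  y = .data$pct_signal,
                                  colour = .data$is_se)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red"),
                                 name = "Super-enhancer") +
    ggplot2::labs(x = "1 - relative enhancer rank",
                  y = "% of total enhancer signal",
                  title = sprintf("%s: %d SEs / %d enhancers",
                                  object$sample_id, object$n_se,
                                  nrow(d))) +
    ggplot2::theme_classic()
}
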