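# RNA-Pol2 pausing index and strand-oriented metagene profiles.

#' Pausing-index window definition
#'
#' Strand-relative windows for the pausing index: the TSS window spans
#' `tss_upstream` bases upstream through `tss_downstream` bases downstream
#' of the TSS, and the gene body runs from `body_start_offset` past the TSS
#' to the TES. Defaults follow the common traveling-ratio convention
#' (TSS -50/+300, body +300..TES).
#'
#' @param tss_upstream,tss_downstream,body_start_offset Window sizes in
#'   bases.
#' @return A `pausing_windows` list.
#' @export
pausing_windows <- function(tss_upstream = 50, tss_downstream = 300,
                            body_start_offset = 300) {
  stopifnot(tss_upstream >= 0, tss_downstream >= 0, body_start_offset >= 0)
  structure(list(tss_upstream = tss_upstream, tss_downstream = tss_downstream,
                 body_start_offset = body_start_offset),
            class = "pausing_windows")
}

# Strand-relative TSS window in genomic coordinates (0-based half-open).
tss_window <- function(gene, windows) {
  up <- windows$tss_upstream; down <- windows$tss_downstream
  if (gene$strand == "+") {
    tibble(start = max(0, gene$tss - up), end = gene$tss + down)
  } else {
    tibble(start = max(0, gene$tss - down + 1), end = gene$tss + up + 1)
  }
}

# Gene-body window (body_start_offset past the TSS through the TES);
# zero-width when the gene is shorter than the offset.
body_window <- function(gene, windows) {
  off <- windows$body_start_offset
  if (gene$strand == "+") {
    tibble(start = gene$tss + off, end = gene$tes)
  } else {
    tibble(start = gene$tes, end = gene$tss - off + 1)
  }
}

#' RNA-Pol2 pausing index per gene
#'
#' The pausing index is the ratio of mean signal density over the
#' strand-relative TSS window to mean density over the gene body. Densities
#' (area / width), not raw areas, so unequal window lengths cancel. The
#' index is undefined (NA, `defined = FALSE`) when the gene is shorter than
#' the body offset or the body density is zero.
#'
#' @param track Signal-track tibble (e.g. RNA-Pol2 ChIP coverage).
#' @param genes Gene tibble.
#' @param windows A [pausing_windows()].
#' @return Tibble: `gene_id`, `tss_density`, `body_density`,
#'   `pausing_index`, `defined`.
#' @export
pausing_index <- function(track, genes, windows = pausing_windows()) {
  tw <- purrr::map_dfr(seq_len(nrow(genes)), function(i)
    tss_window(genes[i, ], windows))
  bw <- purrr::map_dfr(seq_len(nrow(genes)), function(i)
    body_window(genes[i, ], windows))
  tw$chrom <- genes$chrom; bw$chrom <- genes$chrom
  t_ok <- tw$end > tw$start
  b_ok <- bw$end > bw$start
  t_area <- rep(0, nrow(genes)); b_area <- rep(0, nrow(genes))
  t_area[t_ok] <- interval_signal(track, tw[t_ok, , drop = FALSE])
  b_area[b_ok] <- interval_signal(track, bw[b_ok, , drop = FALSE])
  t_den <- ifelse(t_ok, t_area / (tw$end - tw$start), NA_real_)
  b_den <- ifelse(b_ok, b_area / (bw$end - bw$start), NA_real_)
  defined <- t_ok & b_ok & !is.na(b_den) & b_den > 0
  tibble(gene_id = genes$gene_id,
         tss_density = t_den, body_density = b_den,
         pausing_index = ifelse(defined, t_den / b_den, NA_real_),
         defined = defined)
}

#' Average signal profile around anchor points (metagene)
#'
#' Extracts per-bin mean signal density over `[center - halfwidth,
#' center + halfwidth)` for every anchor and averages across anchors. Bin
#' order is reversed for minus-strand anchors so that profiles are aligned
#' with transcription direction (negative offsets upstream). Bases outside
#' the track quantify as zero.
#'
#' @param track Signal-track tibble.
#' @param anchors Tibble with `chrom` and either `center` or
#'   `start`/`end` (midpoint used); an optional `strand` column orients
#'   each anchor.
#' @param halfwidth Half window in bases (default 2500).
#' @param binsize Bin width in bases (default 25); must divide
#'   `2 * halfwidth`.
#' @return A `metagene_profile`: list with `profile` tibble (`offset` of
#'   bin center relative to anchor, `mean_signal`), the per-anchor `matrix`,
#'   `n_anchors`, `halfwidth`, `binsize`.
#' @export
metagene <- function(track, anchors, halfwidth = 2500, binsize = 25) {
  if (nrow(anchors) == 0) abort("metagene: no anchors")
  if ((2 * halfwidth) %% binsize != 0) {
    abort("metagene: binsize must divide 2 * halfwidth")
  }
  if (!"center" %in% names(anchors)) {
    anchors$center <- floor((anchors$start + anchors$end) / 2)
  }
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep("+", nrow(anchors))
  nb <- as.integer(2 * halfwidth / binsize)
  off <- (seq_len(nb) - 1) * binsize - halfwidth
  q <- tidyr::expand_grid(anchor = seq_len(nrow(anchors)), bin = seq_len(nb))
  q$chrom <- anchors$chrom[q$anchor]
  raw_start <- anchors$center[q$anchor] + off[q$bin]
  raw_end <- raw_start + binsize
  q$start <- pmax(0, raw_start)
  q$end <- pmax(raw_end, q$start + 1e-9)  # clipped bins keep zero area
  area <- interval_signal(track, q[, c("chrom", "start", "end")])
  area[raw_end <= 0] <- 0
  mat <- matrix(area / binsize, nrow = nrow(anchors), ncol = nb, byrow = TRUE)
  for (i in which(strand == "-")) mat[i, ] <- rev(mat[i, ])
  structure(list(
    profile = tibble(offset = off + binsize / 2,
                     mean_signal = colMeans(mat)),
    matrix = mat, n_anchors = nrow(anchors),
    halfwidth = halfwidth, binsize = binsize
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d anchors, %d bins of %d bp (+/- %d bp)\n",
              x$n_anchors, nrow(x$profile), x$binsize, x$halfwidth))
  invisible(x)
}

#' Plot a metagene profile
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from anchor (bp)", y = "Mean signal density",
                  title = sprintf("Average profile over %d anchors",
                                  object$n_anchors)) +
    ggplot2::theme_classic()
}

#' Compare pausing-index distributions between gene groups
#'
#' Splits per-gene pausing indices by a group label and, for two groups,
#' runs an unpaired rank test (see [rank_test()]). Groups with fewer than
#' two defined indices are flagged and excluded from testing.
#'
#' @param pi_tbl Output of [pausing_index()].
#' @param groups Tibble with `gene_id` and `group`.
#' @return List: `values` (named list of PI vectors per group), `flagged`
#'   (groups too small to test), and `comparison` (a `group_comparison`
#'   when exactly two testable groups exist, otherwise NULL).
#' @export
stratify_pausing <- function(pi_tbl, groups) {
  d <- dplyr::inner_join(pi_tbl, groups, by = "gene_id")
  d <- d[d$defined, , drop = FALSE]
  vals <- split(d$pausing_index, d$group)
  small <- names(vals)[vapply(vals, length, 0L) < 2]
  if (length(small) > 0) {
    warn(paste0("stratify_pausing: group(s) with < 2 defined indices: ",
                paste(small, collapse = ", ")))
  }
  testable <- vals[setdiff(names(vals), small)]
  comparison <- NULL
  if (length(testable) == 2) {
    comparison <- rank_test(testable[[1]], testable[[2]], paired = FALSE)
    comparison$groups <- names(testable)
  }
  list(values = vals, flagged = small, comparison = comparison)
}
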