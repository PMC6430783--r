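# Expression-side statistics: activity filtering, fold changes, gene
# grouping, exact rank tests and the SE signal matrix.

#' Filter active genes by mean FPKM
#'
#' Keeps genes whose mean FPKM across samples is strictly greater than the
#' threshold (default 0.5).
#'
#' @param fpkm Expression tibble (`gene_id` + sample columns).
#' @param threshold Mean-FPKM cutoff (default 0.5, strict `>`).
#' @return Character vector of active gene ids.
#' @export
filter_active <- function(fpkm, threshold = 0.5) {
  stopifnot(threshold >= 0)
  if (nrow(fpkm) == 0) return(character(0))
  m <- rowMeans(as.matrix(fpkm[, -1, drop = FALSE]))
  fpkm$gene_id[m > threshold]
}

#' Per-gene log2 fold change between conditions
#'
#' `log2((mean_b + pseudo) / (mean_a + pseudo))` of FPKM means; the
#' pseudocount guards zero expression. Antisymmetric under condition swap.
#'
#' @param fpkm Expression tibble.
#' @param samples Tibble with `sample_id`, `condition`.
#' @param condition_a,condition_b Condition labels (change is b relative
#'   to a).
#' @param pseudo Pseudocount (default 1).
#' @return Tibble: `gene_id`, `mean_a`, `mean_b`, `log2fc`.
#' @export
log2fc <- function(fpkm, samples, condition_a, condition_b, pseudo = 1) {
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% samples$condition) {
      abort(paste0("log2fc: unknown condition label '", cond, "'"))
    }
  }
  cols_a <- samples$sample_id[samples$condition == condition_a]
  cols_b <- samples$sample_id[samples$condition == condition_b]
  ma <- rowMeans(as.matrix(fpkm[, cols_a, drop = FALSE]))
  mb <- rowMeans(as.matrix(fpkm[, cols_b, drop = FALSE]))
  tibble(gene_id = fpkm$gene_id, mean_a = ma, mean_b = mb,
         log2fc = log2((mb + pseudo) / (ma + pseudo)))
}

#' Partition genes into annotation groups
#'
#' Assigns each gene of the universe to the first group (in precedence
#' order) whose gene set contains it, and the remainder to an explicit
#' "none" group. Overlapping definitions are resolved by precedence and
#' logged.
#'
#' @param universe Character vector of gene ids.
#' @param groups Named list of gene-id vectors.
#' @param precedence Group order, highest first (default: list order).
#' @return Tibble `gene_id`, `group`; group sizes sum to the universe size.
#' @export
group_by_annotation <- function(universe, groups,
                                precedence = names(groups)) {
  stopifnot(!is.null(names(groups)), all(precedence %in% names(groups)))
  assigned <- rep("none", length(universe))
  seen <- rep(FALSE, length(universe))
  n_conflict <- 0
  for (g in precedence) {
    hit <- universe %in% groups[[g]]
    n_conflict <- n_conflict + sum(hit & seen)
    assigned[hit & !seen] <- g
    seen <- seen | hit
  }
  if (n_conflict > 0) {
    rlang::inform(sprintf(
      "group_by_annotation: %d overlapping assignment(s) resolved by precedence (%s)",
      n_conflict, paste(precedence, collapse = " > ")))
  }
  tibble(gene_id = universe, group = assigned)
}

# Exact null distribution of a sum of k of the (doubled, integer) ranks,
# by generating-function DP -- equivalent to full enumeration.
rank_sum_dist <- function(r2, k) {
  S <- sum(r2)
  f <- matrix(0, nrow = k + 1, ncol = S + 1)  # f[j+1, s+1]: ways, j picked
  f[1, 1] <- 1
  for (r in r2) {
    for (j in rev(seq_len(k))) {
      shifted <- c(rep(0, r), f[j, seq_len(S + 1 - r)])
      f[j + 1, ] <- f[j + 1, ] + shifted
    }
  }
  f[k + 1, ]  # counts over 2*W = 0..S
}

# Null distribution of the signed-rank sum over all 2^n sign patterns.
signed_rank_dist <- function(r2) {
  S <- sum(r2)
  g <- numeric(S + 1)
  g[1] <- 1
  for (r in r2) {
    g <- g + c(rep(0, r), g[seq_len(S + 1 - r)])
  }
  g
}

two_sided <- function(p_less, p_greater) min(1, 2 * min(p_less, p_greater))

#' Rank-based two-group test (exact under ties)
#'
#' Unpaired: Mann-Whitney/rank-sum on mid-ranked pooled values. Paired:
#' Wilcoxon signed-rank on the differences with zeros dropped and ties
#' mid-ranked. The null distribution is computed exactly (full-enumeration
#' equivalent, valid under ties) for small samples -- up to 25 per group
#' unpaired, up to 25 non-zero differences paired -- and by normal
#' approximation with tie and continuity corrections beyond.
#'
#' @param a,b Numeric vectors. Paired requires equal lengths; unpaired
#'   requires at least 2 values per group.
#' @param paired Use the signed-rank variant (default FALSE: gene-group
#'   comparisons are structurally unpaired).
#' @param alternative "two.sided", "less" (a tends below b) or "greater".
#' @param exact_limit Largest size handled exactly (default 25).
#' @return A `group_comparison` object; `tidy()` gives a one-row tibble.
#' @export
rank_test <- function(a, b, paired = FALSE,
                      alternative = c("two.sided", "less", "greater"),
                      exact_limit = 25) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired) {
    if (length(a) != length(b)) abort("rank_test: paired requires |a| = |b|")
    d <- a[!is.na(a) & !is.na(b)] - b[!is.na(a) & !is.na(b)]
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      warn("rank_test: all paired differences are zero; p = 1")
      return(new_group_comparison("wilcoxon_signed_rank", 0, 1, alternative,
                                  "degenerate", length(a), length(b), 0))
    }
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    r2 <- round(2 * r)
    if (n <= exact_limit) {
      g <- signed_rank_dist(r2)
      probs <- g / 2^n
      v2 <- round(2 * V)
      p_less <- sum(probs[seq_len(v2 + 1)])
      p_greater <- sum(probs[(v2 + 1):length(probs)])
      method <- "exact"
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                      sum(ties^3 - ties) / 48)
      p_less <- stats::pnorm((V - mu + 0.5) / sigma)
      p_greater <- stats::pnorm((V - mu - 0.5) / sigma, lower.tail = FALSE)
      method <- "normal_approximation"
    }
    p <- switch(alternative, less = p_less, greater = p_greater,
                two.sided = two_sided(p_less, p_greater))
    return(new_group_comparison("wilcoxon_signed_rank", V, p, alternative,
                                method, length(a), length(b), n))
  }
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  m <- length(a); nn <- length(b)
  if (m < 2 || nn < 2) abort("rank_test: unpaired requires >= 2 values per group")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  if (max(m, nn) <= exact_limit) {
    r2 <- round(2 * r)
    counts <- rank_sum_dist(r2, m)
    probs <- counts / choose(m + nn, m)
    w2 <- round(2 * W)
    p_less <- sum(probs[seq_len(w2 + 1)])
    p_greater <- sum(probs[(w2 + 1):length(probs)])
    method <- "exact"
  } else {
    N <- m + nn
    ties <- table(r)
    mu <- m * nn / 2
    sigma <- sqrt(m * nn / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    p_less <- stats::pnorm((U - mu + 0.5) / sigma)
    p_greater <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    method <- "normal_approximation"
  }
  p <- switch(alternative, less = p_less, greater = p_greater,
              two.sided = two_sided(p_less, p_greater))
  new_group_comparison("mann_whitney", U, p, alternative, method, m, nn, NA)
}

new_group_comparison <- function(test, statistic, p_value, alternative,
                                 method, n_a, n_b, n_used) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(1, p_value), alternative = alternative,
                 method = method, n_a = n_a, n_b = n_b, n_used = n_used),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s), statistic = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$test, x$method, x$statistic, x$p_value, x$alternative,
              x$n_a, x$n_b))
  invisible(x)
}

#' Tidy a rank-test result
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with test name, statistic, p-value, alternative,
#'   method and group sizes.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         alternative = x$alternative, method = x$method,
         n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' SE signal matrix across samples
#'
#' Merges the SE regions called in each sample into a union set
#' (overlapping SEs merged) and quantifies every sample's ChIP signal over
#' each union region as `log2(area + pseudo)`; the matrix feeds external
#' PCA/clustering.
#'
#' @param calls Named list of `se_call` objects (>= 2 samples).
#' @param tracks Named list of ChIP signal tracks matching `names(calls)`.
#' @param pseudo Pseudocount inside the log (default 1).
#' @return Tibble: `region_id`, `chrom`, `start`, `end`, then one log2
#'   signal column per sample.
#' @export
se_signal_matrix <- function(calls, tracks, pseudo = 1) {
  stopifnot(length(calls) >= 2, !is.null(names(calls)),
            all(names(calls) %in% names(tracks)))
  se_regions <- bind_rows(lapply(calls, function(x) {
    enh <- x$enhancers
    enh[enh$is_se, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (nrow(se_regions) == 0) abort("se_signal_matrix: empty SE union")
  union <- merge_intervals(se_regions)
  out <- tibble(
    region_id = sprintf("%s:%d-%d", union$chrom, as.integer(union$start),
                        as.integer(union$end)),
    chrom = union$chrom, start = union$start, end = union$end)
  for (s in names(calls)) {
    out[[s]] <- log2(interval_signal(tracks[[s]], union) + pseudo)
  }
  out
}

#' Basal expression compared across SE classes
#'
#' Per-gene mean FPKM split by annotation group, with class medians and an
#' unpaired rank test between a designated pair of groups.
#'
#' @param fpkm Expression tibble.
#' @param groups Tibble `gene_id`, `group` (from [group_by_annotation()]).
#' @param compare Character vector of two group labels to test
#'   (first vs second).
#' @param sample_ids Optional subset of sample columns (default all).
#' @param alternative Passed to [rank_test()] ("greater": first group
#'   higher).
#' @return List: `values` (named list per group), `medians`, and
#'   `comparison` (`group_comparison`).
#' @export
basal_expression_by_se_class <- function(fpkm, groups, compare,
                                         sample_ids = NULL,
                                         alternative = "greater") {
  stopifnot(length(compare) == 2)
  cols <- if (is.null(sample_ids)) setdiff(names(fpkm), "gene_id") else sample_ids
  mean_fpkm <- tibble(gene_id = fpkm$gene_id,
                      value = rowMeans(as.matrix(fpkm[, cols, drop = FALSE])))
  d <- dplyr::inner_join(mean_fpkm, groups, by = "gene_id")
  vals <- split(d$value, d$group)
  med <- vapply(vals, stats::median, 0)
  missing <- setdiff(compare, names(vals))
  if (length(missing) > 0) {
    abort(paste0("basal_expression_by_se_class: group(s) absent: ",
                 paste(missing, collapse = ", ")))
  }
  comparison <- rank_test(vals[[compare[1]]], vals[[compare[2]]],
                          paired = FALSE, alternative = alternative)
  list(values = vals, medians = med, comparison = comparison)
}
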