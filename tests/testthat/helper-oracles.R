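# Independent brute-force oracles used to validate the implementation.
# These deliberately use different algorithms (base-level masks, union-find,
# full enumeration) from the package code paths they check.

# Base-level TSS exclusion: mark excluded bases on a genome mask, then read
# off the runs of surviving bases per peak.
oracle_exclude_tss <- function(peaks, genes, pad, genome_length) {
  mask <- rep(FALSE, genome_length)
  for (t in genes$tss) {
    lo <- max(1, t - pad + 1)       # base t-pad .. t+pad, 1-based mask
    hi <- min(genome_length, t + pad + 1)
    mask[lo:hi] <- TRUE
  }
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    bases <- (peaks$start[i] + 1):peaks$end[i]
    keep <- bases[!mask[bases]]
    if (length(keep) == 0) next
    r <- rle(c(TRUE, diff(keep) == 1))
    # reconstruct runs of consecutive kept bases
    idx <- cumsum(c(1, diff(keep) != 1))
    for (g in unique(idx)) {
      b <- keep[idx == g]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = peaks$chrom[i], start = min(b) - 1, end = max(b),
        name = peaks$name[i])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), name = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, end)
}

# Union-find stitching: O(n^2) pairwise merge of peaks with gap <= distance.
oracle_stitch <- function(peaks, distance) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    gap <- pmax(peaks$start[i], peaks$start) - pmin(peaks$end[i], peaks$end)
    hits <- which(gap <= distance & peaks$chrom == peaks$chrom[i])
    for (j in setdiff(hits, i)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  parts <- split(seq_len(n), root)
  out <- lapply(parts, function(idx) {
    tibble::tibble(chrom = peaks$chrom[idx[1]],
                   start = min(peaks$start[idx]),
                   end = max(peaks$end[idx]),
                   n_constituents = length(idx))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Direct per-row overlap sum for signal area (no cumulative sums).
oracle_area <- function(track, chrom, start, end) {
  d <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  ov <- pmin(d$end, end) - pmax(d$start, start)
  sum(d$value[ov > 0] * ov[ov > 0])
}

# First rank position (ascending curve rescaled to the unit square) whose
# discrete slope exceeds the diagonal; SEs sit strictly above that value.
oracle_inflection_se <- function(net) {
  n <- length(net)
  if (n < 3) return(rep(FALSE, n))
  ys <- sort(net)
  if (max(ys) == min(ys)) return(rep(FALSE, n))
  cutoff <- NA_real_
  for (i in seq_len(n - 1)) {
    dy <- (ys[i + 1] - ys[i]) / (max(ys) - min(ys))
    dx <- 1 / (n - 1)
    if (dy / dx > 1 + 1e-9) { cutoff <- ys[i]; break }
  }
  if (is.na(cutoff)) return(rep(FALSE, n))
  net > cutoff
}

# O(n^2) pairwise overlap scan.
oracle_overlap_fraction <- function(a, b, min_bp = 1) {
  hit <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) { hit[i] <- TRUE; break }
    }
  }
  sum(hit) / nrow(a)
}

# Bitmask brute force over all 2^n subsets: maximal fully-connected sets
# under the mutual (undirected) relation.
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  mutual <- adj & t(adj)
  diag(mutual) <- TRUE
  is_clique <- function(members) {
    all(mutual[members, members, drop = FALSE])
  }
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(members)) next
    subsets[[length(subsets) + 1]] <- members
  }
  # keep maximal only
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(seq_along(subsets), function(j)
      j != i && all(subsets[[i]] %in% subsets[[j]]), TRUE))
  }, TRUE)
  cl <- lapply(subsets[keep], function(m) sort(nodes[m]))
  cl[order(-lengths(cl), vapply(cl, paste, "", collapse = ","))]
}

# Per-offset, per-strand nested-loop PWM scan.
oracle_scan <- function(sequence, pwm, threshold) {
  m <- ncol(pwm$mat)
  L <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bases <- strsplit(toupper(sequence), "")[[1]]
  score_word <- function(word, mat, pc, bg) {
    s <- 0
    for (k in seq_along(word)) {
      b <- word[k]
      s <- s + if (b %in% c("A", "C", "G", "T")) {
        log2((mat[b, k] + pc * bg[match(b, c("A", "C", "G", "T"))]) /
               ((1 + pc) * bg[match(b, c("A", "C", "G", "T"))]))
      } else 0
    }
    s
  }
  hits <- list()
  if (m > L) return(tibble::tibble(offset = integer(), strand = character(),
                                   score = double()))
  for (o in 0:(L - m)) {
    word <- bases[(o + 1):(o + m)]
    sf <- score_word(word, pwm$mat, pwm$pseudocount, pwm$background)
    if (sf >= threshold) {
      hits[[length(hits) + 1]] <- tibble::tibble(offset = o, strand = "+",
                                                 score = unname(sf))
    }
    wrc <- rev(unname(comp[word]))
    sr <- score_word(wrc, pwm$mat, pwm$pseudocount, pwm$background)
    if (sr >= threshold) {
      hits[[length(hits) + 1]] <- tibble::tibble(offset = o, strand = "-",
                                                 score = unname(sr))
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          score = double()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), offset, strand)
}

# Full-enumeration null for the unpaired rank-sum test.
enum_rank_test_unpaired <- function(a, b, alternative) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(m + n, m)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_less <- mean(Ws <= W_obs + 1e-9)
  p_greater <- mean(Ws >= W_obs - 1e-9)
  switch(alternative, less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# Full-enumeration null for the paired signed-rank test (2^n sign patterns).
enum_rank_test_paired <- function(a, b, alternative) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_less <- mean(Vs <= V_obs + 1e-9)
  p_greater <- mean(Vs >= V_obs - 1e-9)
  switch(alternative, less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}
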