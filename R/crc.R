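# Core transcriptional regulatory circuitry: PWM scanning of SE sequences,
# auto-/mutual-regulation graph, maximal cliques, per-TF scoring and
# co-expression ranking.

#' Construct a position weight matrix
#'
#' @param tf TF name.
#' @param mat 4 x L matrix of per-position base probabilities, rows A, C,
#'   G, T; each column must sum to 1 (within 1e-6); L >= 4.
#' @param pseudocount Pseudocount mixed with the background when scoring
#'   (default 0.01).
#' @param background Base frequencies (default uniform 0.25).
#' @return A `pwm` object.
#' @export
make_pwm <- function(tf, mat, pseudocount = 0.01,
                     background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("make_pwm: matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) abort("make_pwm: motif length must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    abort("make_pwm: columns must sum to 1")
  }
  rownames(mat) <- c("A", "C", "G", "T")
  stopifnot(pseudocount >= 0, length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  structure(list(tf = tf, mat = mat, pseudocount = pseudocount,
                 background = background), class = "pwm")
}

#' Build a near-one-hot PWM from a consensus sequence
#'
#' @param tf TF name.
#' @param consensus Consensus string over ACGT.
#' @param p Probability mass on the consensus base per position
#'   (default 0.85, remainder spread evenly).
#' @param ... Passed to [make_pwm()].
#' @return A `pwm` object.
#' @export
consensus_pwm <- function(tf, consensus, p = 0.85, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  mat <- matrix((1 - p) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(bases)) mat[bases[k], k] <- p
  make_pwm(tf, mat, ...)
}

# Per-position log-odds score table in bits:
# S[b, k] = log2((p[b,k] + pc * bg[b]) / ((1 + pc) * bg[b])).
pwm_score_table <- function(pwm) {
  pc <- pwm$pseudocount; bg <- pwm$background
  S <- log2((pwm$mat + pc * bg) / ((1 + pc) * bg))
  rbind(S, N = 0)  # ambiguous bases score as background
}

#' Maximum attainable log-odds score of a PWM (bits)
#'
#' @param pwm A `pwm` object.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_score_table(pwm)[1:4, , drop = FALSE], 2, max))
}

#' Consensus sequence of a PWM
#'
#' @param pwm A `pwm` object.
#' @return Character string of per-position argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scoring in bits against the PWM background; both the forward
#' sequence and its reverse complement are scanned (minus-strand hit
#' offsets refer to the forward coordinates of the matched window). `N`
#' bases score as background (0 bits). Hits are all offsets with score at
#' or above the threshold.
#'
#' @param sequence Character string over ACGTN.
#' @param pwm A `pwm` object.
#' @param threshold Score threshold in bits; default 80% of the PWM's
#'   maximum attainable score.
#' @return Tibble: `tf`, `offset` (0-based), `strand`, `score`. Empty when
#'   the motif is longer than the sequence.
#' @export
scan_motifs <- function(sequence, pwm,
                        threshold = 0.8 * pwm_max_score(pwm)) {
  stopifnot(is.finite(threshold))
  m <- ncol(pwm$mat)
  L <- nchar(sequence)
  empty <- tibble(tf = character(), offset = integer(), strand = character(),
                  score = double())
  if (m > L) return(empty)
  code <- match(strsplit(toupper(sequence), "")[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  S <- pwm_score_table(pwm)
  # reverse-complement score table: complement bases, reversed positions
  Src <- S[c(4, 3, 2, 1, 5), rev(seq_len(m)), drop = FALSE]
  n_off <- L - m + 1
  score_with <- function(tab) {
    sc <- numeric(n_off)
    for (k in seq_len(m)) {
      sc <- sc + unname(tab[code[seq_len(n_off) + k - 1L], k])
    }
    sc
  }
  fwd <- score_with(S)
  rev_ <- score_with(Src)
  hits <- bind_rows(
    tibble(tf = pwm$tf, offset = which(fwd >= threshold) - 1L,
           strand = "+", score = fwd[fwd >= threshold]),
    tibble(tf = pwm$tf, offset = which(rev_ >= threshold) - 1L,
           strand = "-", score = rev_[rev_ >= threshold])
  )
  arrange(hits, .data$offset, .data$strand)
}

#' Read JASPAR-style PFM motifs
#'
#' Parses `>name` headers followed by four `A/C/G/T [ counts ]` rows;
#' counts are converted to per-column probabilities.
#'
#' @param path Path to a JASPAR PFM file.
#' @param ... Passed to [make_pwm()] (pseudocount, background).
#' @return Named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, ...) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) abort("read_jaspar_pfm: no '>' headers found")
  out <- list()
  for (i in seq_along(heads)) {
    name <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]][1]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[(heads[i] + 1):to]
    if (length(block) < 4) abort(paste0("read_jaspar_pfm: motif ", name,
                                        " has fewer than 4 base rows"))
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1]]
      as.numeric(nums)
    })
    base_lab <- toupper(substr(trimws(block[1:4]), 1, 1))
    mat <- do.call(rbind, rows)
    if (all(c("A", "C", "G", "T") %in% base_lab)) {
      mat <- mat[match(c("A", "C", "G", "T"), base_lab), , drop = FALSE]
    }
    cs <- colSums(mat)
    if (any(cs <= 0)) abort(paste0("read_jaspar_pfm: zero column in ", name))
    out[[name]] <- make_pwm(name, sweep(mat, 2, cs, "/"), ...)
  }
  out
}

#' Write PWMs in JASPAR PFM format
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @param scale Multiplier turning probabilities into pseudo-counts
#'   (default 100).
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pwms, path, scale = 100) {
  lines <- unlist(lapply(pwms, function(p) {
    m <- round(p$mat * scale, 4)
    c(paste0(">", p$tf),
      vapply(1:4, function(r)
        sprintf("%s [ %s ]", rownames(m)[r],
                paste(m[r, ], collapse = " ")), ""))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (columns A, C, G, T).
#'
#' @param path Path to a MEME minimal motif file.
#' @param ... Passed to [make_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_meme_pwm <- function(path, ...) {
  lines <- readr::read_lines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) abort("read_meme_pwm: no MOTIF blocks found")
  out <- list()
  for (i in seq_along(starts)) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1]][2]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:to]
    hdr <- grep("letter-probability matrix", block)
    if (length(hdr) == 0) abort(paste0("read_meme_pwm: no matrix for ", name))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]]))
    rows <- block[(hdr[1] + 1):(hdr[1] + w)]
    mat <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]), numeric(4)))
    out[[name]] <- make_pwm(name, t(mat), ...)
  }
  out
}

#' Build the TF-to-TF regulatory graph from motif hits in SEs
#'
#' Nodes are auto-regulated, expressed, SE-associated TFs: a TF is kept only
#' if its own motif hits its own SE (a `from == to` edge). A directed edge
#' i -> j means TF i's motif hits at least one SE assigned to TF j.
#'
#' @param edge_hits Tibble with columns `from`, `to` (TF ids) and
#'   optionally `n_hits`; one row per supported edge.
#' @param expressed_tfs Optional character vector restricting nodes to
#'   expressed TFs.
#' @return A `crc_graph`: list with `nodes`, `edges` tibble and logical
#'   `adjacency` matrix (rows = from). Empty node set warns.
#' @export
build_crc_graph <- function(edge_hits, expressed_tfs = NULL) {
  if (!"n_hits" %in% names(edge_hits)) edge_hits$n_hits <- 1L
  edge_hits <- edge_hits %>%
    group_by(.data$from, .data$to) %>%
    summarise(n_hits = sum(.data$n_hits), .groups = "drop")
  auto <- edge_hits$from[edge_hits$from == edge_hits$to]
  nodes <- sort(unique(auto))
  if (!is.null(expressed_tfs)) nodes <- intersect(nodes, expressed_tfs)
  edges <- edge_hits[edge_hits$from %in% nodes & edge_hits$to %in% nodes, ,
                     drop = FALSE]
  if (length(nodes) == 0) {
    warn("build_crc_graph: no auto-regulated TFs, empty graph")
    adj <- matrix(FALSE, 0, 0)
  } else {
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    adj[cbind(edges$from, edges$to)] <- TRUE
  }
  structure(list(nodes = nodes, edges = edges, adjacency = adj),
            class = "crc_graph")
}

#' Enumerate maximal fully-interconnected TF sets
#'
#' Mutual edge pairs (i -> j and j -> i) are treated as undirected edges
#' and maximal cliques enumerated; an isolated auto-regulated TF counts as
#' a singleton clique.
#'
#' @param graph A `crc_graph`.
#' @param max_nodes Refuse graphs larger than this (default 25); filter
#'   the TF set first.
#' @return List of character vectors (each sorted), ordered by decreasing
#'   size.
#' @export
enumerate_cliques <- function(graph, max_nodes = 25) {
  n <- length(graph$nodes)
  if (n == 0) return(list())
  if (n > max_nodes) {
    abort(sprintf("enumerate_cliques: %d nodes exceeds cap %d; filter the TF set",
                  n, max_nodes))
  }
  mutual <- graph$adjacency & t(graph$adjacency)
  diag(mutual) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
  cl <- igraph::max_cliques(g, min = 1)
  cl <- lapply(cl, function(v) sort(graph$nodes[as.integer(v)]))
  cl[order(-lengths(cl), vapply(cl, paste, "", collapse = ","))]
}

#' Clique membership fraction per TF
#'
#' @param cliques List of cliques from [enumerate_cliques()].
#' @param tfs TF ids to score (default: all TFs appearing in cliques).
#' @return Tibble `tf`, `clique_fraction` (share of maximal cliques
#'   containing the TF; NA with a warning when there are no cliques).
#' @export
clique_scores <- function(cliques, tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(unlist(cliques)))
  if (length(cliques) == 0) {
    warn("clique_scores: zero cliques, fractions undefined")
    return(tibble(tf = tfs, clique_fraction = NA_real_))
  }
  frac <- vapply(tfs, function(tf)
    sum(vapply(cliques, function(cl) tf %in% cl, TRUE)) / length(cliques), 0,
    USE.NAMES = FALSE)
  tibble(tf = tfs, clique_fraction = frac)
}

#' Pairwise Pearson co-expression of TFs
#'
#' Pearson correlation of log2(FPKM + 1) across samples; symmetric with
#' unit diagonal. Zero-variance TFs yield NA rows/columns with a warning.
#'
#' @param fpkm Expression tibble (`gene_id` + sample columns).
#' @param tfs Character vector of TF gene ids (rows of `fpkm`).
#' @return Correlation matrix (tfs x tfs).
#' @export
coexpression <- function(fpkm, tfs) {
  missing <- setdiff(tfs, fpkm$gene_id)
  if (length(missing) > 0) {
    abort(paste0("coexpression: TFs absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(fpkm[match(tfs, fpkm$gene_id), -1, drop = FALSE])
  if (ncol(m) < 3) abort("coexpression: need >= 3 samples")
  lm2 <- t(log2(m + 1))
  colnames(lm2) <- tfs
  sds <- apply(lm2, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("coexpression: zero-variance TF(s): ",
                paste(tfs[sds == 0], collapse = ", ")))
  }
  suppressWarnings(stats::cor(lm2, method = "pearson"))
}

#' Rank candidate core TFs
#'
#' Orders TFs by clique membership fraction (descending), then mean
#' pairwise co-expression (descending), then the rank of the TF's own SE
#' (ascending); the components are reported so users can re-rank.
#'
#' @param scores Tibble with `tf`, `clique_fraction`, `mean_coexpr`,
#'   `se_rank` (missing components are treated as neutral).
#' @return The tibble ordered with a `core_rank` column.
#' @export
rank_core_tfs <- function(scores) {
  if (!"mean_coexpr" %in% names(scores)) scores$mean_coexpr <- 0
  if (!"se_rank" %in% names(scores)) scores$se_rank <- NA_real_
  ord <- order(-scores$clique_fraction, -scores$mean_coexpr, scores$se_rank,
               scores$tf)
  scores <- scores[ord, , drop = FALSE]
  scores$core_rank <- seq_len(nrow(scores))
  scores
}

#' Reconstruct the core transcriptional regulatory circuitry
#'
#' Full CRC inference: assign SE regions to candidate TF genes, scan each
#' TF's motif across every TF's SE sequences (both strands), keep
#' auto-regulated TFs, enumerate maximal mutual cliques, and rank TFs by
#' clique membership, co-expression and own-SE rank.
#'
#' @param se_call An `se_call` object (genes must be assigned).
#' @param sequence Genome sequence: character string or named vector by
#'   chromosome.
#' @param pwms Named list of `pwm` objects; names are candidate TF gene
#'   ids.
#' @param fpkm Optional expression tibble: restricts candidates to active
#'   genes (mean FPKM > `active_threshold`) and supplies co-expression.
#' @param threshold_frac Scan threshold as a fraction of each PWM's
#'   maximum score (default 0.8).
#' @param active_threshold Mean-FPKM activity filter (default 0.5).
#' @param max_nodes Clique-enumeration node cap.
#' @return A `crc_result`: graph, cliques, ranked score table,
#'   co-expression matrix and raw hit counts. `tidy()` gives the ranked
#'   TF table, `glance()` the one-row summary.
#' @export
reconstruct_crc <- function(se_call, sequence, pwms, fpkm = NULL,
                            threshold_frac = 0.8, active_threshold = 0.5,
                            max_nodes = 25) {
  stopifnot(inherits(se_call, "se_call"))
  enh <- se_call$enhancers
  se_regions <- enh[enh$is_se, , drop = FALSE]
  tfs <- names(pwms)
  if (!is.null(fpkm)) {
    tfs <- intersect(tfs, filter_active(fpkm, threshold = active_threshold))
  }
  # SEs assigned to each TF gene
  assign_map <- lapply(tfs, function(tf)
    which(vapply(se_regions$genes, function(g) tf %in% g, TRUE)))
  names(assign_map) <- tfs
  tfs <- tfs[lengths(assign_map) > 0]
  assign_map <- assign_map[tfs]
  get_seq <- function(chrom, start, end) {
    s <- if (is.null(names(sequence))) sequence else sequence[[chrom]]
    substr(s, start + 1, end)
  }
  se_seqs <- lapply(tfs, function(tf) {
    idx <- assign_map[[tf]]
    vapply(idx, function(i) get_seq(se_regions$chrom[i], se_regions$start[i],
                                    se_regions$end[i]), "")
  })
  names(se_seqs) <- tfs
  hits <- list()
  for (from in tfs) {
    thr <- threshold_frac * pwm_max_score(pwms[[from]])
    for (to in tfs) {
      n_hits <- sum(vapply(se_seqs[[to]], function(s)
        nrow(scan_motifs(s, pwms[[from]], threshold = thr)), 0L))
      if (n_hits > 0) {
        hits[[length(hits) + 1]] <- tibble(from = from, to = to,
                                           n_hits = n_hits)
      }
    }
  }
  edge_hits <- if (length(hits) > 0) bind_rows(hits) else
    tibble(from = character(), to = character(), n_hits = integer())
  graph <- build_crc_graph(edge_hits, expressed_tfs = tfs)
  cliques <- enumerate_cliques(graph, max_nodes = max_nodes)
  scores <- clique_scores(cliques, tfs = graph$nodes)
  coex <- NULL
  if (!is.null(fpkm) && length(graph$nodes) >= 2 && ncol(fpkm) - 1 >= 3) {
    coex <- coexpression(fpkm, graph$nodes)
    # co-operativity: mean correlation with the TF's clique partners
    # (a TF with no partners scores 0)
    mean_r <- vapply(graph$nodes, function(tf) {
      partners <- setdiff(unique(unlist(cliques[vapply(cliques, function(cl)
        tf %in% cl, TRUE)])), tf)
      if (length(partners) == 0) 0 else
        mean(coex[tf, partners], na.rm = TRUE)
    }, 0)
    scores$mean_coexpr <- mean_r[scores$tf]
  }
  scores$se_rank <- vapply(scores$tf, function(tf)
    min(se_regions$rank[assign_map[[tf]]]), 0)
  scores <- rank_core_tfs(scores)
  structure(list(graph = graph, cliques = cliques, scores = scores,
                 coexpression = coex, edge_hits = edge_hits),
            class = "crc_result")
}

#' @export
print.crc_result <- function(x, ...) {
  cat(sprintf("<crc_result> %d auto-regulated TFs, %d edges, %d maximal cliques\n",
              length(x$graph$nodes), nrow(x$graph$edges), length(x$cliques)))
  if (nrow(x$scores) > 0) {
    cat("top TFs:", paste(utils::head(x$scores$tf, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a CRC reconstruction into the ranked TF table
#'
#' @param x A `crc_result`.
#' @param ... Unused.
#' @return Tibble of TF scores ordered by `core_rank`.
#' @export
tidy.crc_result <- function(x, ...) as_tibble(x$scores)

#' One-row summary of a CRC reconstruction
#'
#' @param x A `crc_result`.
#' @param ... Unused.
#' @return One-row tibble: node/edge/clique counts and largest clique.
#' @export
glance.crc_result <- function(x, ...) {
  tibble(n_tfs = length(x$graph$nodes), n_edges = nrow(x$graph$edges),
         n_cliques = length(x$cliques),
         max_clique_size = if (length(x$cliques) > 0)
           max(lengths(x$cliques)) else 0L)
}

#' Adjacency heat-tile plot of a CRC graph
#'
#' @param object A `crc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crc_result <- function(object, ...) {
  adj <- object$graph$adjacency
  if (length(adj) == 0) abort("autoplot.crc_result: empty graph")
  d <- tidyr::expand_grid(from = rownames(adj), to = colnames(adj))
  d$edge <- adj[cbind(d$from, d$to)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$edge)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "steelblue"),
                               name = "motif support") +
    ggplot2::labs(x = "target TF (SE)", y = "motif of TF",
                  title = "TF-to-TF regulatory graph") +
    ggplot2::theme_minimal()
}
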