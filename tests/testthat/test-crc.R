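one_hot_pwm <- function(consensus, pseudocount = 0) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix(0, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(bases)) mat[bases[k], k] <- 1
  make_pwm("onehot", mat, pseudocount = pseudocount)
}

test_that("PWM construction validates shape and column sums", {
  expect_error(make_pwm("x", matrix(0.25, 4, 3)), "length")
  bad <- matrix(0.3, 4, 5)
  expect_error(make_pwm("x", bad), "sum to 1")
  p <- consensus_pwm("x", "ACGTAC")
  expect_equal(colSums(p$mat), rep(1, 6))
  expect_equal(pwm_consensus(p), "ACGTAC")
})

test_that("one-hot PWM scores its consensus at the information content", {
  p <- one_hot_pwm("ACGT")
  # 4 x log2(1 / 0.25) = 8 bits
  expect_equal(pwm_max_score(p), 8)
  hit <- scan_motifs("ACGT", p, threshold = 8)
  # ACGT is its own reverse complement, so both strands report the hit
  expect_equal(hit$score, c(8, 8))
  expect_equal(hit$offset, c(0, 0))
  expect_setequal(hit$strand, c("+", "-"))
  # mismatching sequence scores -Inf with pseudocount 0 on both strands:
  # no hit even at a very permissive finite threshold
  expect_equal(nrow(scan_motifs("TTTT", p, threshold = -100)), 0)
})

test_that("reverse-complement hits are reported on the minus strand", {
  p <- one_hot_pwm("AACG")
  # CGTT is the reverse complement of AACG
  hits <- scan_motifs("TTCGTTTT", p, threshold = 8)
  expect_equal(hits$strand, "-")
  expect_equal(hits$offset, 2)
  # motif longer than sequence: empty result
  expect_equal(nrow(scan_motifs("ACG", p)), 0)
  # N bases score as background (0 bits)
  pn <- one_hot_pwm("ACGT", pseudocount = 0.01)
  sN <- scan_motifs("ANGT", pn, threshold = -100)
  sA <- scan_motifs("ACGT", pn, threshold = -100)
  fN <- sN$score[sN$strand == "+"]; fA <- sA$score[sA$strand == "+"]
  expect_lt(fN, fA)
})

test_that("motif scan equals the nested-loop both-strand oracle", {
  withr::with_seed(23, {
    for (i in 1:10) {
      pwm <- random_pwm(i, len = 8)
      seqc <- random_seq(i + 100, len = 400)
      # plant the consensus forward and reverse-complemented
      cons <- pwm_consensus(pwm)
      substr(seqc, 51, 58) <- cons
      substr(seqc, 201, 208) <- secircuit:::revcomp(cons)
      thr <- 0.8 * pwm_max_score(pwm)
      got <- scan_motifs(seqc, pwm, threshold = thr)
      want <- oracle_scan(seqc, pwm, threshold = thr)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_true(any(got$offset == 50 & got$strand == "+"))
      expect_true(any(got$offset == 200 & got$strand == "-"))
    }
  })
})

test_that("scan scores are preserved under sequence reverse complement", {
  pwm <- random_pwm(3, len = 8)
  seqc <- random_seq(9, len = 300)
  thr <- 0.75 * pwm_max_score(pwm)
  fwd <- scan_motifs(seqc, pwm, threshold = thr)
  rc <- scan_motifs(secircuit:::revcomp(seqc), pwm, threshold = thr)
  expect_equal(sort(fwd$score), sort(rc$score), tolerance = 1e-9)
  expect_equal(sum(fwd$strand == "+"), sum(rc$strand == "-"))
})

test_that("JASPAR and MEME motif readers round-trip", {
  pwms <- list(TFA = consensus_pwm("TFA", "ACGTACGT"),
               TFB = consensus_pwm("TFB", "GGGTTTAA"))
  f <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(pwms, f)
  back <- read_jaspar_pfm(f)
  expect_equal(names(back), c("TFA", "TFB"))
  expect_equal(back$TFA$mat, pwms$TFA$mat, tolerance = 1e-6)
  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TFC", "letter-probability matrix: alength= 4 w= 4",
               "0.97 0.01 0.01 0.01", "0.01 0.97 0.01 0.01",
               "0.01 0.01 0.97 0.01", "0.01 0.01 0.01 0.97"), meme)
  m <- read_meme_pwm(meme)
  expect_equal(pwm_consensus(m$TFC), "ACGT")
})

test_that("graph construction keeps only auto-regulated TFs", {
  # A hits its own SE only
  g1 <- build_crc_graph(tibble::tibble(from = "A", to = "A"))
  expect_equal(g1$nodes, "A")
  expect_equal(nrow(g1$edges), 1)
  # planted A<->A, A<->B, B<->B: two nodes, bidirectional edge
  g2 <- build_crc_graph(tibble::tibble(from = c("A", "A", "B", "B"),
                                       to = c("A", "B", "A", "B")))
  expect_setequal(g2$nodes, c("A", "B"))
  expect_true(g2$adjacency["A", "B"] && g2$adjacency["B", "A"])
  # a TF without a self-hit is excluded even if others hit it
  g3 <- build_crc_graph(tibble::tibble(from = c("A", "A"), to = c("A", "C")))
  expect_equal(g3$nodes, "A")
  expect_warning(g0 <- build_crc_graph(tibble::tibble(from = "A", to = "B")),
                 "empty graph")
  expect_equal(length(g0$nodes), 0)
})

test_that("clique enumeration matches brute force and handles singletons", {
  # triangle plus isolated node
  eh <- dplyr::bind_rows(
    tidyr::expand_grid(from = c("A", "B", "C"), to = c("A", "B", "C")),
    tibble::tibble(from = "D", to = "D"))
  g <- build_crc_graph(eh)
  cl <- enumerate_cliques(g)
  expect_equal(cl, list(c("A", "B", "C"), "D"))
  # complete mutual graph on 5 nodes: one clique of size 5
  eh5 <- tidyr::expand_grid(from = LETTERS[1:5], to = LETTERS[1:5])
  cl5 <- enumerate_cliques(build_crc_graph(eh5))
  expect_equal(cl5, list(LETTERS[1:5]))
  expect_error(enumerate_cliques(build_crc_graph(eh5), max_nodes = 3), "cap")
  # random directed graphs vs 2^n subset enumeration
  withr::with_seed(37, {
    for (i in 1:25) {
      n <- sample(4:10, 1)
      nodes <- paste0("T", seq_len(n))
      adj <- matrix(stats::runif(n * n) < 0.45, n, n,
                    dimnames = list(nodes, nodes))
      diag(adj) <- TRUE  # all auto-regulated
      eh <- tibble::tibble(from = nodes[row(adj)[adj]],
                           to = nodes[col(adj)[adj]])
      g <- build_crc_graph(eh)
      expect_equal(enumerate_cliques(g), oracle_cliques(g$adjacency))
    }
  })
})

test_that("clique fractions follow the membership recount", {
  cl <- list(c("A", "B", "C"), "D")
  sc <- clique_scores(cl)
  expect_equal(sc$clique_fraction[sc$tf == "A"], 0.5)
  expect_equal(sc$clique_fraction[sc$tf == "D"], 0.5)
  one <- clique_scores(list(c("A", "B")))
  expect_equal(one$clique_fraction, c(1, 1))
  expect_warning(z <- clique_scores(list(), tfs = "A"), "zero cliques")
  expect_true(is.na(z$clique_fraction))
  # invariant: sum over TFs of fraction * n_cliques = sum of clique sizes
  withr::with_seed(4, {
    cl <- lapply(1:6, function(i) sample(LETTERS[1:8], sample(1:4, 1)))
    sc <- clique_scores(cl)
    expect_equal(sum(sc$clique_fraction) * length(cl),
                 sum(lengths(cl)))
  })
})

test_that("co-expression is Pearson on log2(FPKM + 1), symmetric, unit diagonal", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  fpkm <- tibble::tibble(gene_id = c("gx", "gy"),
                         s1 = c(x[1], y[1]), s2 = c(x[2], y[2]),
                         s3 = c(x[3], y[3]))
  cc <- coexpression(fpkm, c("gx", "gy"))
  want <- stats::cor(log2(x + 1), log2(y + 1))
  expect_equal(cc["gx", "gy"], want)
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), c(gx = 1, gy = 1))
  # anti-correlated rows on the log scale
  fpkm2 <- tibble::tibble(gene_id = c("a", "b"),
                          s1 = c(2^1 - 1, 2^3 - 1),
                          s2 = c(2^2 - 1, 2^2 - 1),
                          s3 = c(2^3 - 1, 2^1 - 1))
  cc2 <- coexpression(fpkm2, c("a", "b"))
  expect_equal(cc2["a", "b"], -1)
  # zero-variance row flagged
  fpkm3 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 5), s2 = c(1, 6),
                          s3 = c(1, 7))
  expect_warning(coexpression(fpkm3, c("a", "b")), "zero-variance")
})

test_that("core TF ranking orders by clique fraction, co-expression, SE rank", {
  sc <- tibble::tibble(tf = c("A", "B", "C"),
                       clique_fraction = c(0.9, 0.5, 0.5),
                       mean_coexpr = c(0.2, 0.8, 0.3),
                       se_rank = c(5, 9, 1))
  r <- rank_core_tfs(sc)
  expect_equal(r$tf, c("A", "B", "C"))
  # tie on everything except SE rank
  sc2 <- tibble::tibble(tf = c("A", "B"), clique_fraction = 1,
                        mean_coexpr = 0.5, se_rank = c(7, 2))
  expect_equal(rank_core_tfs(sc2)$tf, c("B", "A"))
})

test_that("end-to-end CRC reconstruction recovers a planted circuit", {
  cfg <- sim_config(genome_length = 1.8e6, n_genes = 60, n_se = 6, n_te = 10,
                    n_crc_tfs = 3, n_decoy_tfs = 3, seed = 71)
  genome <- simulate_genome(cfg)
  h <- simulate_h3k27ac(genome, cfg)
  tf_genes <- h$truth$se_regions$gene_id
  crc_tfs <- tf_genes[1:3]; decoys <- tf_genes[4:6]
  pwms <- withr::with_seed(1234, stats::setNames(lapply(tf_genes, function(g)
    consensus_pwm(g, paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                           collapse = ""))), tf_genes))
  edges <- dplyr::bind_rows(
    tibble::tibble(from = tf_genes, to = tf_genes),
    tidyr::expand_grid(from = crc_tfs, to = crc_tfs) %>%
      dplyr::filter(from != to))
  pm <- plant_motifs(genome$sequence, pwms, edges, h$truth, cfg)
  ex <- simulate_expression(genome, pm$truth, cfg, crc_tfs = crc_tfs)
  call <- call_superenhancers(h$peaks, h$chip, genome$genes, input = h$input)
  res <- reconstruct_crc(call, pm$sequence, pwms, fpkm = ex$fpkm)
  expect_setequal(res$graph$nodes, tf_genes)
  expect_true(list(sort(crc_tfs)) %in% res$cliques ||
                any(vapply(res$cliques, function(cl)
                  setequal(cl, crc_tfs), TRUE)))
  expect_setequal(utils::head(res$scores$tf, 3), crc_tfs)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$max_clique_size, 3)
})
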