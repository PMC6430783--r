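test_that("TSS exclusion removes the +/- pad zone, splitting straddlers", {
  genes <- tbl_genes(tss = 10000)
  # zone covers bases 8750..11250 -> peak [9000,11000) is dropped entirely
  gone <- exclude_tss(tbl_peaks(9000, 11000), genes, pad = 1250)
  expect_equal(nrow(gone), 0)
  # far peak unchanged
  far <- exclude_tss(tbl_peaks(0, 5000), genes, pad = 1250)
  expect_equal(far$start, 0)
  expect_equal(far$end, 5000)
  # pad 0 removes only the single TSS base and splits the peak
  split <- exclude_tss(tbl_peaks(9990, 10010), genes, pad = 0)
  expect_equal(split$start, c(9990, 10001))
  expect_equal(split$end, c(10000, 10010))
  expect_equal(sum(split$end - split$start), 20 - 1)
  # original extents are retained for constituent reporting
  expect_equal(unique(split$orig_start), 9990)
})

test_that("TSS exclusion matches the base-level mask oracle", {
  withr::with_seed(11, {
    for (i in 1:5) {
      genes <- tbl_genes(tss = sort(sample(3000:90000, 6)))
      st <- sort(sample(0:95000, 30))
      peaks <- tbl_peaks(st, st + sample(100:3000, 30, replace = TRUE))
      got <- exclude_tss(peaks, genes, pad = 1250)
      got <- dplyr::arrange(got, chrom, start, end)
      want <- oracle_exclude_tss(peaks, genes, pad = 1250,
                                 genome_length = 2e5)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
})

test_that("stitching merges by gap threshold with transitive closure", {
  p <- tbl_peaks(c(100, 300, 20000), c(200, 400, 20100))
  r <- stitch(p, distance = 12500)
  expect_equal(r$start, c(100, 20000))
  expect_equal(r$end, c(400, 20100))
  expect_equal(r$n_constituents, c(2L, 1L))
  # distance 0: only touching/overlapping peaks merge
  r0 <- stitch(tbl_peaks(c(0, 100, 250), c(100, 200, 300)), distance = 0)
  expect_equal(r0$start, c(0, 250))
  # idempotence: stitching the stitched regions changes nothing
  rr <- stitch(dplyr::mutate(r[, c("chrom", "start", "end")],
                             name = r$region_id, score = 0),
               distance = 12500)
  expect_equal(rr$start, r$start)
  expect_equal(rr$end, r$end)
})

test_that("stitching equals the union-find oracle on random peak sets", {
  withr::with_seed(5, {
    for (d in c(0, 500, 5000)) {
      st <- sort(sample(0:2e5, 200))
      peaks <- tbl_peaks(st, st + sample(50:400, 200, replace = TRUE))
      got <- stitch(peaks, distance = d)
      want <- oracle_stitch(peaks, distance = d)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_constituents, want$n_constituents)
    }
  })
})

test_that("scoring subtracts input, floors at zero and ranks deterministically", {
  regions <- stitch(tbl_peaks(c(0, 50000), c(1000, 51000)), distance = 100)
  chip <- tbl_track(c(0, 50000), c(1000, 51000), c(1, 0.1))
  input <- tbl_track(c(0, 50000), c(1000, 51000), c(0.2, 0.5))
  sc <- score_and_rank(regions, chip, input)
  expect_equal(sc$net_signal[sc$rank == 1], 800)  # 1000 - 200
  expect_equal(sc$net_signal[sc$rank == 2], 0)    # input exceeds chip
  # region retained at bottom rank, not dropped
  expect_equal(nrow(sc), 2)
  # ordering equals an independent recomputation of areas
  cs <- random_callset(21)
  regions <- stitch(cs$peaks, distance = 2000)
  sc <- score_and_rank(regions, cs$chip, cs$input)
  areas <- vapply(seq_len(nrow(sc)), function(i) {
    flat <- sc$constituents[[i]]
    max(sum(vapply(seq_len(nrow(flat)), function(j)
      oracle_area(cs$chip, flat$chrom[j], flat$start[j], flat$end[j]), 0)) -
        sum(vapply(seq_len(nrow(flat)), function(j)
          oracle_area(cs$input, flat$chrom[j], flat$start[j], flat$end[j]), 0)),
      0)
  }, 0)
  expect_equal(sc$net_signal, areas, tolerance = 1e-9)
  expect_true(all(diff(sc$net_signal) <= 1e-9))
})

test_that("inflection cutoff separates the hockey-stick elbow", {
  r <- find_inflection(c(100, 1, 1, 1, 1))
  expect_equal(r$n_se, 1)
  expect_equal(which(r$is_se), 1)
  # perfectly linear ascending signals: slope is 1 everywhere, zero SEs
  expect_warning(lin <- find_inflection(seq(10, 100, 10)), "zero super")
  expect_equal(lin$n_se, 0)
  expect_warning(eq <- find_inflection(c(5, 5, 5, 5)), "equal")
  expect_equal(eq$n_se, 0)
  expect_warning(two <- find_inflection(c(9, 1)), "fewer than 3")
  expect_equal(two$n_se, 0)
  # brute-force slope scan agrees on random curves
  withr::with_seed(9, {
    for (i in 1:20) {
      net <- round(stats::rlnorm(sample(5:60, 1), 3, 1.2), 3)
      expect_equal(find_inflection(net)$is_se, oracle_inflection_se(net))
    }
  })
})

test_that("hockey normalization satisfies the printed identities", {
  enh <- tibble::tibble(rank = 1:500, net_signal = rev(sort(stats::rexp(500))))
  hn <- hockey_normalize(enh)
  expect_equal(hn$relative_rank[hn$rank == 1], 1 / 500)
  expect_equal(sum(hn$pct_signal), 100, tolerance = 1e-6)
  expect_true(all(hn$relative_rank > 0 & hn$relative_rank <= 1))
  # net 50 of total 1000 -> 5%
  h2 <- hockey_normalize(tibble::tibble(rank = 1:3,
                                        net_signal = c(900, 50, 50)))
  expect_equal(h2$pct_signal[2], 5)
  expect_error(hockey_normalize(tibble::tibble(rank = 1, net_signal = 0)),
               "zero")
})

test_that("gene assignment uses TSS-within-flank with nearest fallback", {
  genes <- tbl_genes(tss = c(10000, 200000), strand = c("+", "+"))
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
                            start = 5000, end = 6000)
  a <- assign_genes(regions, genes, flank = 50000)
  expect_equal(a$genes[[1]], "g1")     # TSS within flank
  expect_equal(a$nearest_gene, "g1")
  # nearest-only fallback at 70 kb with 50 kb flank
  far <- tibble::tibble(region_id = "r2", chrom = "chr1",
                        start = 80000, end = 81000)
  b <- assign_genes(far, tbl_genes(tss = 151000), flank = 50000)
  expect_equal(b$genes[[1]], "g1")
  # random layout vs all-pairs distance oracle
  withr::with_seed(31, {
    genes <- tbl_genes(tss = sort(sample(0:5e5, 40)))
    st <- sort(sample(0:5e5, 15))
    regions <- tibble::tibble(region_id = paste0("r", 1:15), chrom = "chr1",
                              start = st, end = st + 2000)
    got <- assign_genes(regions, genes, flank = 50000)
    for (i in 1:15) {
      s <- regions$start[i]; e <- regions$end[i]
      inside <- genes$gene_id[genes$tss >= s - 50000 & genes$tss < e + 50000]
      d <- ifelse(genes$tss >= s & genes$tss < e, 0,
                  pmin(abs(genes$tss - s), abs(genes$tss - (e - 1))))
      expect_equal(got$nearest_gene[i], genes$gene_id[which.min(d)])
      if (length(inside) > 0) expect_setequal(got$genes[[i]], inside)
    }
  })
})

test_that("increasing a region's chip signal never lowers its rank", {
  cs <- random_callset(77, n_peaks = 60)
  call <- call_superenhancers(cs$peaks, cs$chip, cs$genes, input = cs$input,
                              stitch_distance = 3000)
  enh <- call$enhancers
  pick <- enh[which.max(enh$rank), ]  # lowest-ranked region
  boosted <- dplyr::bind_rows(cs$chip, tbl_track(pick$start, pick$end, 50)) %>%
    secircuit:::flatten_segments()
  call2 <- call_superenhancers(cs$peaks, boosted, cs$genes, input = cs$input,
                               stitch_distance = 3000)
  r2 <- call2$enhancers$rank[call2$enhancers$region_id == pick$region_id]
  expect_lt(r2, pick$rank)
})

test_that("every stitched region is exactly one of SE or TE", {
  cs <- random_callset(13)
  call <- call_superenhancers(cs$peaks, cs$chip, cs$genes, input = cs$input)
  expect_equal(call$n_se + call$n_te, nrow(call$enhancers))
  g <- glance(call)
  expect_equal(g$n_enhancers, call$n_se + call$n_te)
  td <- tidy(call)
  expect_equal(nrow(td), nrow(call$enhancers))
  expect_s3_class(autoplot(call), "ggplot")
})
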