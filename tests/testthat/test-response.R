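test_that("active-gene filter uses strict mean FPKM > threshold, monotone", {
  fpkm <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(0.6, 0.5, 0), s2 = c(0.6, 0.5, 0))
  expect_equal(filter_active(fpkm), "a")          # mean 0.6 kept
  expect_false("b" %in% filter_active(fpkm))      # mean exactly 0.5 dropped
  expect_equal(filter_active(fpkm, threshold = 0), c("a", "b"))
  # monotone: raising the threshold never adds genes
  withr::with_seed(2, {
    fpkm <- tibble::tibble(gene_id = paste0("g", 1:50),
                           s1 = stats::rexp(50), s2 = stats::rexp(50))
    thr <- sort(stats::runif(5, 0, 2))
    sets <- lapply(thr, function(t) filter_active(fpkm, t))
    for (i in seq_len(4)) expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  })
  expect_equal(filter_active(tibble::tibble(gene_id = "a", s1 = 0, s2 = 0)),
               character(0))
})

test_that("log2 fold change is pseudocounted and antisymmetric", {
  fpkm <- tibble::tibble(gene_id = c("a", "b"),
                         c1 = c(10, 1), c2 = c(10, 1),
                         t1 = c(10, 7), t2 = c(10, 7))
  samples <- tibble::tibble(sample_id = c("c1", "c2", "t1", "t2"),
                            condition = c("ctrl", "ctrl", "treat", "treat"))
  fc <- log2fc(fpkm, samples, "ctrl", "treat")
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$log2fc[2], 2)  # log2(8/2)
  rev_fc <- log2fc(fpkm, samples, "treat", "ctrl")
  expect_equal(rev_fc$log2fc, -fc$log2fc)
  expect_error(log2fc(fpkm, samples, "ctrl", "nope"), "unknown condition")
})

test_that("annotation grouping partitions the universe with precedence", {
  universe <- paste0("g", 1:6)
  groups <- list(SE = c("g1", "g2"), TE = c("g2", "g3"))
  expect_message(g <- group_by_annotation(universe, groups), "precedence")
  expect_equal(g$group, c("SE", "SE", "TE", "none", "none", "none"))
  expect_equal(nrow(g), length(universe))
  expect_equal(sum(table(g$group)), length(universe))
})

test_that("unpaired rank test matches full enumeration for all sizes <= 8", {
  # printed example: one-sided exact p = 0.05 (1 of 20 rank assignments)
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(rt$p_value, 0.05)
  expect_equal(rt$method, "exact")
  withr::with_seed(41, {
    for (m in 2:8) {
      for (n in c(2, 5, 8)) {
        a <- sample(1:6, m, replace = TRUE)  # ties likely
        b <- sample(1:6, n, replace = TRUE)
        for (alt in c("two.sided", "less", "greater")) {
          expect_equal(rank_test(a, b, alternative = alt)$p_value,
                       enum_rank_test_unpaired(a, b, alt),
                       tolerance = 1e-12,
                       info = sprintf("m=%d n=%d alt=%s", m, n, alt))
        }
      }
    }
  })
  # tie-free case agrees with the standard exact implementation
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.4, 6.3, 7.7, 8.1, 2.9)
  expect_equal(rank_test(a, b, alternative = "two.sided")$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("paired rank test matches sign-pattern enumeration for n <= 8", {
  # differences [1,2,3]: one-sided exact p = 1/8
  rt <- rank_test(c(2, 4, 6), c(1, 2, 3), paired = TRUE,
                  alternative = "greater")
  expect_equal(rt$p_value, 0.125)
  withr::with_seed(43, {
    for (n in 2:8) {
      a <- sample(1:5, n, replace = TRUE)
      b <- sample(1:5, n, replace = TRUE)
      if (all(a == b)) a[1] <- a[1] + 1
      for (alt in c("two.sided", "less", "greater")) {
        expect_equal(rank_test(a, b, paired = TRUE,
                               alternative = alt)$p_value,
                     enum_rank_test_paired(a, b, alt), tolerance = 1e-12,
                     info = sprintf("n=%d alt=%s", n, alt))
      }
    }
  })
  # identical samples: all differences zero, p = 1 with warning
  expect_warning(null <- rank_test(1:5, 1:5, paired = TRUE), "zero")
  expect_equal(null$p_value, 1)
  # tie-free agreement with the standard exact implementation
  a <- c(5.1, 2.2, 8.0, 1.1, 9.4); b <- c(4.0, 2.9, 6.1, 3.3, 4.8)
  expect_equal(rank_test(a, b, paired = TRUE)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("large samples switch to the corrected normal approximation", {
  withr::with_seed(47, {
    a <- stats::rnorm(60); b <- stats::rnorm(60, 0.5)
    rt <- rank_test(a, b, alternative = "less")
    expect_equal(rt$method, "normal_approximation")
    ref <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(rt$p_value, ref, tolerance = 1e-9)
  })
})

test_that("SE signal matrix is log2(area + 1) over the merged SE union", {
  mk_call <- function(start, end, track_value) {
    enh <- tibble::tibble(region_id = "r", chrom = "chr1", start = start,
                          end = end, n_constituents = 1L,
                          chip_signal = 1, input_signal = 0, net_signal = 1,
                          rank = 1L, is_se = TRUE, relative_rank = 1,
                          pct_signal = 100)
    structure(list(enhancers = enh, cutoff_value = 0, n_se = 1, n_te = 0,
                   sample_id = "s", params = list()), class = "se_call")
  }
  calls <- list(s1 = mk_call(0, 1023), s2 = mk_call(512, 1500))
  tracks <- list(s1 = tbl_track(0, 1023, 1), s2 = tbl_track(0, 2000, 0.5))
  m <- se_signal_matrix(calls, tracks)
  # union region is [0,1500): overlapping SEs merged
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0); expect_equal(m$end, 1500)
  expect_equal(m$s1, 10)            # area 1023 -> log2(1024)
  expect_equal(m$s2, log2(751))     # 0.5 * 1500 + 1
  # sample order only permutes columns
  m2 <- se_signal_matrix(rev(calls), tracks)
  expect_equal(m2$s1, m$s1)
  expect_equal(m2$s2, m$s2)
  # zero signal track gives log2(0 + 1) = 0
  tracks0 <- list(s1 = tbl_track(0, 10, 0)[0, ], s2 = tracks$s2)
  expect_equal(se_signal_matrix(calls, tracks0)$s1, 0)
})

test_that("basal expression comparison reports medians and a rank test", {
  withr::with_seed(53, {
    fpkm <- tibble::tibble(gene_id = paste0("g", 1:60),
                           s1 = c(stats::rlnorm(20, 3), stats::rlnorm(40, 1)),
                           s2 = c(stats::rlnorm(20, 3), stats::rlnorm(40, 1)))
    groups <- group_by_annotation(fpkm$gene_id,
                                  list(dp = paste0("g", 1:20)))
    res <- basal_expression_by_se_class(fpkm, groups, c("dp", "none"))
    expect_gt(res$medians["dp"], res$medians["none"])
    expect_lt(res$comparison$p_value, 0.01)
    expect_error(basal_expression_by_se_class(fpkm, groups,
                                              c("dp", "missing")),
                 "absent")
  })
})
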