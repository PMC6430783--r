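# Small constructors for in-code fixtures.

tbl_track <- function(start, end, value, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end, value = value)
}

tbl_peaks <- function(start, end, chrom = "chr1", name = NULL, score = 1) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = if (is.null(name)) paste0("p", seq_along(start)) else name,
                 score = score, summit = NA_real_)
}

tbl_genes <- function(tss, strand = "+", chrom = "chr1", length = 2000) {
  start <- ifelse(strand == "+", tss, tss - length + 1)
  end <- ifelse(strand == "+", tss + length, tss + 1)
  tibble::tibble(gene_id = paste0("g", seq_along(tss)), chrom = chrom,
                 start = start, end = end, strand = strand,
                 name = paste0("g", seq_along(tss)),
                 tss = tss, tes = ifelse(strand == "+", end, start))
}

# Random peak set + signal tracks + genes on a small genome, for oracle runs.
random_callset <- function(seed, n_peaks = 200, genome = 1e6, n_genes = 20) {
  withr::with_seed(seed, {
    # disjoint peaks (grid spacing exceeds the maximum width), as a peak
    # caller would emit
    start <- sort(sample.int(floor(genome / 600) - 1, n_peaks)) * 600
    width <- sample(50:500, n_peaks, replace = TRUE)
    peaks <- tbl_peaks(start, pmin(start + width, genome))
    bin <- 1000
    nb <- genome / bin
    chip <- tbl_track((seq_len(nb) - 1) * bin, seq_len(nb) * bin,
                      round(stats::runif(nb, 0, 10), 3))
    input <- tbl_track((seq_len(nb) - 1) * bin, seq_len(nb) * bin,
                       round(stats::runif(nb, 0, 3), 3))
    genes <- tbl_genes(tss = sort(sample(2000:(genome - 3000), n_genes)),
                       strand = sample(c("+", "-"), n_genes, replace = TRUE))
    list(peaks = peaks, chip = chip, input = input, genes = genes,
         genome = genome)
  })
}

random_pwm <- function(seed, len = 8) {
  withr::with_seed(seed, {
    consensus_pwm(paste0("tf", seed),
                  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
  })
}

random_seq <- function(seed, len = 500) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}
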