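# Synthetic-data generators: toy genome, H3K27ac/TF/Pol2 signal, planted
# motifs and an FPKM matrix, all with recorded ground truth. Every generator
# is a pure function of (inputs, seed): per-stage seeds are derived from the
# global seed by stable hashing of the stage name, so adding a stage never
# perturbs earlier stages' draws.

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Gene slots are laid out on a regular grid; within each slot the gene sits
# near the slot start and planted enhancers live in a window that keeps them
# clear of TSS exclusion zones (offset 6 kb) and of the next slot's
# enhancers (13 kb reserve > the 12.5 kb stitching distance).
ENH_OFFSET <- 6000
ENH_RESERVE <- 13000

#' Simulation configuration with planted ground truth parameters
#'
#' Builds the parameter set for all simulators. Defaults emulate a desk-scale
#' enhancer landscape: 8 clustered super-enhancers against 80 singleton
#' typical enhancers at a 4:1 amplitude ratio with noise at a tenth of the
#' SE amplitude, TF peaks co-localized with 90% of SE constituents,
#' promoter-proximal Pol2 pausing at index 3, and SE-associated genes
#' overexpressed 4-fold (log2FC 2) with a -1 log2FC treatment response.
#' Unknown argument names are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_length = 6e6, chrom = "chrS",
    n_genes = 200, gene_length_range = c(1500, 3000),
    n_se = 8, n_te = 80,
    se_width = 1000, te_width = 1000,
    se_constituents_range = c(2, 6), se_gap_range = c(600, 1000),
    se_slot_min_sep = 3,
    se_amplitude = 20, te_amplitude = 5,
    noise_sd = 2, noise_bin = 100,
    tf_coloc_fraction = 0.9, tf_n_background = 50, tf_amplitude = 15,
    pausing_index_true = 3, pol2_body_density = 2, pol2_noise_sd = 0.3,
    motif_plant_rate = 1, n_crc_tfs = 3, n_decoy_tfs = 10,
    expr_baseline_log2 = 3, expr_se_log2fc = 2, treatment_log2fc = -1,
    expr_noise_sd = 0.5, crc_factor_loading = 1,
    frac_silent = 0.05, silent_log2 = -3,
    n_samples = 3,
    flank = 50000,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("sim_config: unknown parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(genome_length > 0, n_genes >= 0, n_se >= 0, n_te >= 0,
              se_width > 0, te_width > 0, noise_sd >= 0,
              tf_coloc_fraction >= 0, tf_coloc_fraction <= 1,
              pausing_index_true > 0,
              motif_plant_rate >= 0, motif_plant_rate <= 1,
              n_samples >= 2, seed >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a toy genome: gene models and background sequence
#'
#' Places `n_genes` non-overlapping genes on alternating strands on a single
#' chromosome (one gene per regular slot) over an i.i.d. uniform ACGT
#' background sequence. Reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param sequence Generate the DNA sequence (default TRUE; FALSE returns
#'   NULL sequence, for signal-only runs).
#' @return List with `genes` (gene tibble), `sequence` (character string or
#'   NULL) and `config`.
#' @export
simulate_genome <- function(config = sim_config(), sequence = TRUE) {
  cfg <- config
  withr::with_seed(stage_seed(cfg$seed, "genome"), {
    if (cfg$n_genes > 0) {
      slot <- floor(cfg$genome_length / cfg$n_genes)
      if (slot < 1000 + max(cfg$gene_length_range) + 250) {
        abort("simulate_genome: infeasible packing, genome too short for n_genes")
      }
      slot_start <- (seq_len(cfg$n_genes) - 1) * slot
      glen <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                                 cfg$gene_length_range[2]))
      strand <- rep(c("+", "-"), length.out = cfg$n_genes)
      start <- slot_start + 1000
      end <- start + glen
      genes <- tibble(
        gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
        chrom = cfg$chrom, start = start, end = end, strand = strand,
        name = sprintf("gene_%03d", seq_len(cfg$n_genes)),
        tss = ifelse(strand == "+", start, end - 1),
        tes = ifelse(strand == "+", end, start),
        slot_start = slot_start, slot_width = slot
      )
    } else {
      genes <- tibble(gene_id = character(), chrom = character(),
                      start = double(), end = double(), strand = character(),
                      name = character(), tss = double(), tes = double(),
                      slot_start = double(), slot_width = double())
    }
    seq <- NULL
    if (sequence) {
      seq <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                          replace = TRUE), collapse = "")
    }
    list(genes = genes, sequence = seq, config = cfg)
  })
}

# Per-slot window where planted enhancers may live.
enhancer_window <- function(slot_start, slot_width) {
  tibble(win_start = slot_start + ENH_OFFSET,
         win_end = slot_start + slot_width - ENH_RESERVE)
}

#' Simulate an H3K27ac landscape with planted super-enhancers
#'
#' Plants `n_se` clustered super-enhancers (2-6 constituent peaks within
#' stitching range) and `n_te` singleton typical enhancers into distinct
#' gene slots, adds truncated-Gaussian background noise, and emits the ChIP
#' signal track, a matched pure-noise input track, the constituent peak
#' calls, and the ground truth.
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [sim_config()] (defaults to the genome's).
#' @return List: `chip` and `input` signal tracks, `peaks` (constituents),
#'   and `truth` (`sim_truth` list with planted SE/TE regions, constituents
#'   and SE-associated gene labels).
#' @export
simulate_h3k27ac <- function(genome, config = genome$config) {
  cfg <- config
  genes <- genome$genes
  n_slots <- nrow(genes)
  if (cfg$n_se + cfg$n_te > n_slots) {
    abort("simulate_h3k27ac: placement failure, more enhancers than gene slots")
  }
  withr::with_seed(stage_seed(cfg$seed, "h3k27ac"), {
    # SE slots with a minimum separation (greedy, restarted on dead ends),
    # then TE slots from the rest
    se_slots <- NULL
    for (attempt in 1:50) {
      cand <- integer(0)
      avail <- seq_len(n_slots)
      for (i in seq_len(cfg$n_se)) {
        ok <- avail[vapply(avail, function(s)
          all(abs(s - cand) >= cfg$se_slot_min_sep), TRUE)]
        if (length(ok) == 0) break
        pick <- if (length(ok) == 1) ok else sample(ok, 1)
        cand <- c(cand, pick)
        avail <- setdiff(avail, pick)
      }
      if (length(cand) == cfg$n_se) { se_slots <- cand; break }
    }
    if (is.null(se_slots)) {
      abort("simulate_h3k27ac: placement failure for SE slots")
    }
    avail <- setdiff(seq_len(n_slots), se_slots)
    te_slots <- if (cfg$n_te > 0) sample(avail, cfg$n_te) else integer(0)

    place_cluster <- function(slot_idx, n_const, width, gaps) {
      w <- enhancer_window(genes$slot_start[slot_idx], genes$slot_width[slot_idx])
      span <- n_const * width + sum(gaps)
      if (span > w$win_end - w$win_start) {
        abort("simulate_h3k27ac: placement failure, cluster exceeds slot window")
      }
      s0 <- round(stats::runif(1, w$win_start, w$win_end - span))
      starts <- s0 + cumsum(c(0, width + gaps))
      tibble(start = starts, end = starts + width)
    }

    const <- list()
    se_regions <- list()
    for (k in seq_along(se_slots)) {
      n_const <- sample(seq(cfg$se_constituents_range[1],
                            cfg$se_constituents_range[2]), 1)
      gaps <- round(stats::runif(max(n_const - 1, 0), cfg$se_gap_range[1],
                                 cfg$se_gap_range[2]))
      cl <- place_cluster(se_slots[k], n_const, cfg$se_width, gaps)
      cl$chrom <- cfg$chrom
      cl$name <- sprintf("se%02d_c%d", k, seq_len(nrow(cl)))
      cl$class <- "SE"
      cl$planted_id <- sprintf("se%02d", k)
      const[[length(const) + 1]] <- cl
      se_regions[[k]] <- tibble(chrom = cfg$chrom, start = min(cl$start),
                                end = max(cl$end),
                                planted_id = sprintf("se%02d", k),
                                gene_id = genes$gene_id[se_slots[k]])
    }
    te_regions <- list()
    for (k in seq_along(te_slots)) {
      cl <- place_cluster(te_slots[k], 1, cfg$te_width, numeric(0))
      cl$chrom <- cfg$chrom
      cl$name <- sprintf("te%02d", k)
      cl$class <- "TE"
      cl$planted_id <- sprintf("te%02d", k)
      const[[length(const) + 1]] <- cl
      te_regions[[k]] <- tibble(chrom = cfg$chrom, start = cl$start,
                                end = cl$end, planted_id = sprintf("te%02d", k),
                                gene_id = genes$gene_id[te_slots[k]])
    }
    const <- bind_rows(const)
    se_regions <- bind_rows(se_regions)
    te_regions <- bind_rows(te_regions)

    noise_track <- function() {
      nb <- ceiling(cfg$genome_length / cfg$noise_bin)
      s <- (seq_len(nb) - 1) * cfg$noise_bin
      tibble(chrom = cfg$chrom, start = s,
             end = pmin(s + cfg$noise_bin, cfg$genome_length),
             value = pmax(0, stats::rnorm(nb, 0, cfg$noise_sd)))
    }
    amp <- tibble(chrom = const$chrom, start = const$start, end = const$end,
                  value = ifelse(const$class == "SE", cfg$se_amplitude,
                                 cfg$te_amplitude))
    chip <- flatten_segments(bind_rows(noise_track(), amp))
    input <- flatten_segments(noise_track())

    peaks <- tibble(chrom = const$chrom, start = const$start, end = const$end,
                    name = const$name,
                    score = ifelse(const$class == "SE", cfg$se_amplitude,
                                   cfg$te_amplitude),
                    summit = NA_real_)

    # SE-associated genes by the same TSS-within-flank rule the caller uses
    se_gene_ids <- unique(unlist(lapply(seq_len(nrow(se_regions)), function(i) {
      g <- genes
      g$gene_id[g$tss >= se_regions$start[i] - cfg$flank &
                  g$tss < se_regions$end[i] + cfg$flank]
    })))

    truth <- structure(list(
      se_regions = se_regions, te_regions = te_regions,
      constituents = const, se_slots = se_slots, te_slots = te_slots,
      se_genes = se_gene_ids,
      pausing_index_true = cfg$pausing_index_true
    ), class = "sim_truth")
    list(chip = chip, input = input, peaks = peaks, truth = truth)
  })
}

#' Simulate TF ChIP-seq peaks co-localized with planted SEs
#'
#' Each planted SE constituent receives a TF peak with probability
#' `tf_coloc_fraction`; `tf_n_background` further TF peaks are placed in
#' enhancer-free gene slots. A matched TF signal track (amplitude over TF
#' peaks plus background noise) is emitted for TF-overload ranking.
#'
#' @param genome Output of [simulate_genome()].
#' @param truth `sim_truth` from [simulate_h3k27ac()].
#' @param config A [sim_config()].
#' @return List: `peaks`, `signal`, and updated `truth` (with `tf_peaks`
#'   carrying the co-localization labels).
#' @export
simulate_tf_peaks <- function(genome, truth, config = genome$config) {
  cfg <- config
  genes <- genome$genes
  withr::with_seed(stage_seed(cfg$seed, "tf"), {
    se_const <- truth$constituents[truth$constituents$class == "SE", , drop = FALSE]
    coloc <- stats::runif(nrow(se_const)) < cfg$tf_coloc_fraction
    tf1 <- se_const[coloc, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(tf1) > 0) tf1$coloc <- TRUE
    used <- sort(c(truth$se_slots, truth$te_slots))
    free <- setdiff(seq_len(nrow(genes)), used)
    nbg <- min(cfg$tf_n_background, length(free))
    bg_slots <- if (nbg > 0) sample(free, nbg) else integer(0)
    tf2 <- purrr::map_dfr(bg_slots, function(s) {
      w <- enhancer_window(genes$slot_start[s], genes$slot_width[s])
      s0 <- round(stats::runif(1, w$win_start, w$win_end - cfg$te_width))
      tibble(chrom = cfg$chrom, start = s0, end = s0 + cfg$te_width,
             coloc = FALSE)
    })
    tf <- bind_rows(tf1, tf2)
    if (nrow(tf) == 0) {
      tf <- tibble(chrom = character(), start = double(), end = double(),
                   coloc = logical())
    }
    tf <- arrange(tf, .data$chrom, .data$start)
    tf$name <- sprintf("tf_%03d", seq_len(nrow(tf)))
    tf$score <- cfg$tf_amplitude
    tf$summit <- NA_real_

    nb <- ceiling(cfg$genome_length / cfg$noise_bin)
    s <- (seq_len(nb) - 1) * cfg$noise_bin
    noise <- tibble(chrom = cfg$chrom, start = s,
                    end = pmin(s + cfg$noise_bin, cfg$genome_length),
                    value = pmax(0, stats::rnorm(nb, 0, cfg$noise_sd)))
    amp <- tibble(chrom = tf$chrom, start = tf$start, end = tf$end,
                  value = cfg$tf_amplitude)
    signal <- flatten_segments(bind_rows(noise, amp))
    truth$tf_peaks <- tf
    list(peaks = tf[, c("chrom", "start", "end", "name", "score", "summit")],
         signal = signal, truth = truth)
  })
}

#' Simulate RNA-Pol2 coverage with promoter-proximal pausing
#'
#' Per gene, a constant density over the gene-body window and
#' `pausing_index_true` times that density over the strand-relative TSS
#' window (windows as in [pausing_index()]), plus optional truncated
#' Gaussian noise. Noiseless tracks invert the pausing-index estimator
#' exactly.
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param windows A [pausing_windows()] list.
#' @param noise Add background noise at `config$pol2_noise_sd`
#'   (default FALSE).
#' @return A signal-track tibble.
#' @export
simulate_pol2 <- function(genome, config = genome$config,
                          windows = pausing_windows(), noise = FALSE) {
  cfg <- config
  genes <- genome$genes
  withr::with_seed(stage_seed(cfg$seed, "pol2"), {
    d_body <- cfg$pol2_body_density
    d_tss <- cfg$pausing_index_true * d_body
    segs <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      tw <- tss_window(g, windows)
      bw <- body_window(g, windows)
      bind_rows(
        tibble(chrom = g$chrom, start = tw$start, end = tw$end, value = d_tss),
        tibble(chrom = g$chrom, start = bw$start, end = bw$end, value = d_body)
      )
    })
    if (noise && cfg$pol2_noise_sd > 0) {
      nb <- ceiling(cfg$genome_length / cfg$noise_bin)
      s <- (seq_len(nb) - 1) * cfg$noise_bin
      segs <- bind_rows(segs, tibble(
        chrom = cfg$chrom, start = s,
        end = pmin(s + cfg$noise_bin, cfg$genome_length),
        value = pmax(0, stats::rnorm(nb, 0, cfg$pol2_noise_sd))))
    }
    flatten_segments(segs)
  })
}

#' Plant TF motif consensus sequences into SE constituents
#'
#' For every designated regulatory edge (TF i -> TF j), the consensus of
#' PWM i is written (forward or reverse complement, at random) into a
#' random SE constituent of the SE cluster belonging to TF j's gene slot.
#' Collisions with previous placements are re-drawn (bounded retries).
#'
#' @param sequence Genome sequence (character string).
#' @param pwms Named list of PWMs (see [make_pwm()]); names are TF gene ids.
#' @param edges Tibble with columns `from`, `to` (TF gene ids); each row is
#'   a planted regulatory edge.
#' @param truth `sim_truth` carrying planted SE regions (with `gene_id`).
#' @param config A [sim_config()]; `motif_plant_rate` thins the edge list.
#' @return List: modified `sequence`, updated `truth` with
#'   `motif_placements` (tf, position, strand, target gene).
#' @export
plant_motifs <- function(sequence, pwms, edges, truth, config) {
  cfg <- config
  withr::with_seed(stage_seed(cfg$seed, "motifs"), {
    keep <- stats::runif(nrow(edges)) < cfg$motif_plant_rate
    edges <- edges[keep, , drop = FALSE]
    placements <- list()
    occupied <- tibble(start = double(), end = double())
    se_const <- truth$constituents[truth$constituents$class == "SE", , drop = FALSE]
    se_regions <- truth$se_regions
    for (i in seq_len(nrow(edges))) {
      tf_from <- edges$from[i]; tf_to <- edges$to[i]
      cons <- pwm_consensus(pwms[[tf_from]])
      target_se <- se_regions$planted_id[se_regions$gene_id == tf_to]
      if (length(target_se) == 0) {
        abort(paste0("plant_motifs: no planted SE for target TF ", tf_to))
      }
      cand <- se_const[se_const$planted_id %in% target_se, , drop = FALSE]
      placed <- FALSE
      for (try in 1:50) {
        ci <- sample(nrow(cand), 1)
        pos <- round(stats::runif(1, cand$start[ci],
                                  cand$end[ci] - nchar(cons)))
        if (any(pos < occupied$end & pos + nchar(cons) > occupied$start)) next
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") cons else revcomp(cons)
        substr(sequence, pos + 1, pos + nchar(cons)) <- ins
        occupied <- bind_rows(occupied,
                              tibble(start = pos, end = pos + nchar(cons)))
        placements[[length(placements) + 1]] <-
          tibble(tf = tf_from, target = tf_to, position = pos,
                 strand = strand, consensus = cons)
        placed <- TRUE
        break
      }
      if (!placed) abort("plant_motifs: placement failed after bounded retries")
    }
    truth$motif_placements <- bind_rows(placements)
    list(sequence = sequence, truth = truth)
  })
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Simulate an FPKM expression matrix with planted effects
#'
#' log2 expression = baseline + `expr_se_log2fc` for SE-associated genes +
#' a shared latent factor for designated CRC TF genes (giving pairwise
#' Pearson r around 0.8 at the default loading) + Gaussian noise; under
#' treatment, SE-associated genes shift by `treatment_log2fc`. Values are
#' exponentiated to the FPKM scale. A small fraction of genes is silent
#' (below the mean FPKM > 0.5 activity filter).
#'
#' @param genome Output of [simulate_genome()].
#' @param truth `sim_truth` with `se_genes` labels.
#' @param config A [sim_config()].
#' @param crc_tfs Character vector of gene ids sharing the latent factor
#'   (default none).
#' @return List: `fpkm` tibble (`gene_id` + one column per sample),
#'   `samples` tibble (`sample_id`, `condition`), updated `truth` with
#'   per-gene effect labels.
#' @export
simulate_expression <- function(genome, truth, config = genome$config,
                                crc_tfs = character(0)) {
  cfg <- config
  genes <- genome$genes
  stopifnot(cfg$n_samples >= 2)
  withr::with_seed(stage_seed(cfg$seed, "expression"), {
    n <- nrow(genes)
    ids <- genes$gene_id
    is_se <- ids %in% truth$se_genes
    non_se <- which(!is_se)
    n_silent <- round(cfg$frac_silent * length(non_se))
    silent <- if (n_silent > 0) sample(non_se, n_silent) else integer(0)
    base <- rep(cfg$expr_baseline_log2, n)
    base[silent] <- cfg$silent_log2
    base <- base + cfg$expr_se_log2fc * is_se

    samples <- tibble(
      sample_id = c(sprintf("ctrl_%d", seq_len(cfg$n_samples)),
                    sprintf("treat_%d", seq_len(cfg$n_samples))),
      condition = rep(c("control", "treatment"), each = cfg$n_samples)
    )
    z <- stats::rnorm(nrow(samples))  # latent factor shared by CRC TFs
    is_crc <- ids %in% crc_tfs
    mat <- matrix(0, n, nrow(samples), dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base
      if (samples$condition[j] == "treatment") {
        mu <- mu + cfg$treatment_log2fc * is_se
      }
      mu <- mu + cfg$crc_factor_loading * z[j] * is_crc
      mat[, j] <- 2^(mu + stats::rnorm(n, 0, cfg$expr_noise_sd))
    }
    truth$expr_effects <- tibble(gene_id = ids, se_associated = is_se,
                                 silent = seq_len(n) %in% silent,
                                 crc_tf = is_crc)
    list(fpkm = bind_cols(tibble(gene_id = ids), as_tibble(mat)),
         samples = samples, truth = truth)
  })
}

#' Write an expression matrix as TSV
#'
#' @param fpkm Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(fpkm, path) {
  readr::write_tsv(fpkm, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with a `gene_id` column and one numeric column per sample.
#' @return Expression tibble.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "gene_id") names(df)[1] <- "gene_id"
  if (any(duplicated(df$gene_id))) abort("read_expression: duplicate gene ids")
  if (any(as.matrix(df[, -1]) < 0)) abort("read_expression: negative FPKM values")
  df
}

#' Write a genome sequence as FASTA
#'
#' @param sequence Character string (single chromosome) or named character
#'   vector.
#' @param path Output path.
#' @param name Sequence name used when `sequence` is unnamed.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequence, path, name = "chrS") {
  if (is.null(names(sequence))) names(sequence) <- name
  x <- Biostrings::DNAStringSet(sequence)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
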