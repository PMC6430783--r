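# Orchestration: configuration, stage ordering, logging and the end-to-end
# synthetic demonstration run.

#' Pipeline configuration
#'
#' Flat, typed configuration for [run_pipeline()]. Unknown keys are
#' rejected before any stage runs. `seed`, when given, overrides the
#' simulation seed so one global seed drives every stage (per-stage seeds
#' are derived by stable hashing of stage names).
#'
#' @param ... Named overrides: `sim` (a [sim_config()]; the demo default
#'   plants 13 SEs so the CRC stage has 3 core TFs plus 10 decoys),
#'   `stitch_distance`, `tss_pad`, `flank`, `pausing` (a
#'   [pausing_windows()]), `scan_threshold_frac`, `test_variant`
#'   ("unpaired"/"paired"), `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sim = sim_config(n_se = 13, n_te = 60),
    stitch_distance = 12500,
    tss_pad = 1250,
    flank = 50000,
    pausing = pausing_windows(),
    scan_threshold_frac = 0.8,
    test_variant = "unpaired",
    seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("pipeline_config: unknown key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (!inherits(cfg$sim, "sim_config")) {
    cfg$sim <- do.call(sim_config, as.list(cfg$sim))
  }
  if (!is.null(cfg$seed)) cfg$sim$seed <- cfg$seed
  cfg$sim$flank <- cfg$flank
  if (!cfg$test_variant %in% c("unpaired", "paired")) {
    abort("pipeline_config: test_variant must be 'unpaired' or 'paired'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Precision and recall of called SEs against planted truth
#'
#' A called SE region is a true positive when it overlaps a planted SE
#' span by at least one base; a planted SE is recovered when at least one
#' called SE overlaps it.
#'
#' @param se_call An `se_call` object.
#' @param truth A `sim_truth` (needs `se_regions`).
#' @return One-row tibble: `n_called`, `n_planted`, `precision`, `recall`.
#' @export
se_recovery <- function(se_call, truth) {
  called <- se_call$enhancers[se_call$enhancers$is_se, , drop = FALSE]
  planted <- truth$se_regions
  if (nrow(called) == 0 || nrow(planted) == 0) {
    return(tibble(n_called = nrow(called), n_planted = nrow(planted),
                  precision = ifelse(nrow(called) == 0, NA_real_, 0),
                  recall = ifelse(nrow(planted) == 0, NA_real_, 0)))
  }
  ov_called <- overlap_stats(called[, c("chrom", "start", "end")],
                             planted[, c("chrom", "start", "end")])$fraction
  ov_planted <- overlap_stats(planted[, c("chrom", "start", "end")],
                              called[, c("chrom", "start", "end")])$fraction
  tibble(n_called = nrow(called), n_planted = nrow(planted),
         precision = ov_called, recall = ov_planted)
}

log_stage <- function(log_path, stage, params, files) {
  sums <- if (length(files) > 0) {
    paste(sprintf("%s=%s", basename(files), unname(tools::md5sum(files))),
          collapse = " ")
  } else ""
  line <- sprintf("stage=%s params={%s} checksums: %s", stage,
                  paste(sprintf("%s=%s", names(params),
                                vapply(params, function(v)
                                  paste(format(v), collapse = ","), "")),
                        collapse = ", "),
                  sums)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes the stages in dependency order -- simulate, call-se, annotate,
#' pol2, crc, respond -- writing each stage's outputs plus a plain-text log
#' (parameters and md5 checksums per stage) and a machine-readable JSON
#' summary to `out_dir`. Reruns with identical config and seed are
#' byte-identical. Stage failures abort with the stage name; partial
#' outputs are retained.
#'
#' @param config A [pipeline_config()] (or a named list of its keys).
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_run` list: `summary`, per-stage results and output
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_path)) unlink(log_path)
  pth <- function(f) file.path(out_dir, f)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  cfg <- config$sim

  ## stage: simulate --------------------------------------------------------
  sim <- run_stage("simulate", {
    genome <- simulate_genome(cfg)
    h3k <- simulate_h3k27ac(genome, cfg)
    tf <- simulate_tf_peaks(genome, h3k$truth, cfg)
    pol2 <- simulate_pol2(genome, cfg, windows = config$pausing, noise = TRUE)
    # CRC TFs and decoys get the planted SE-slot genes (one SE each)
    se_slot_genes <- h3k$truth$se_regions$gene_id
    n_crc <- min(cfg$n_crc_tfs, length(se_slot_genes))
    n_dec <- min(cfg$n_decoy_tfs, length(se_slot_genes) - n_crc)
    crc_tfs <- se_slot_genes[seq_len(n_crc)]
    decoys <- se_slot_genes[n_crc + seq_len(n_dec)]
    tf_genes <- c(crc_tfs, decoys)
    pwms <- withr::with_seed(stage_seed(cfg$seed, "pwms"), {
      stats::setNames(lapply(tf_genes, function(tf_id)
        consensus_pwm(tf_id, paste(sample(c("A", "C", "G", "T"), 10,
                                          replace = TRUE), collapse = ""))),
        tf_genes)
    })
    edges <- bind_rows(
      tibble(from = tf_genes, to = tf_genes),                       # self
      tidyr::expand_grid(from = crc_tfs, to = crc_tfs) %>%
        filter(.data$from != .data$to)                              # mutual
    )
    pm <- plant_motifs(genome$sequence, pwms, edges, tf$truth, cfg)
    expr <- simulate_expression(genome, pm$truth, cfg, crc_tfs = crc_tfs)
    files <- c(
      write_peaks(h3k$peaks, pth("h3k27ac_peaks.narrowPeak"), "narrowPeak"),
      write_bedgraph(h3k$chip, pth("h3k27ac.bedGraph")),
      write_bedgraph(h3k$input, pth("input.bedGraph")),
      write_peaks(tf$peaks, pth("tf_peaks.narrowPeak"), "narrowPeak"),
      write_bedgraph(tf$signal, pth("tf.bedGraph")),
      write_bedgraph(pol2, pth("pol2.bedGraph")),
      write_gtf(genome$genes, pth("genes.gtf")),
      write_fasta(pm$sequence, pth("genome.fa"), name = cfg$chrom),
      write_jaspar_pfm(pwms, pth("motifs.pfm")),
      write_expression(expr$fpkm, pth("expression.tsv"))
    )
    readr::write_tsv(expr$samples, pth("samples.tsv"))
    truth_json <- list(
      se_regions = pm$truth$se_regions, te_regions = pm$truth$te_regions,
      se_genes = pm$truth$se_genes, crc_tfs = crc_tfs, decoy_tfs = decoys,
      pausing_index_true = cfg$pausing_index_true)
    jsonlite::write_json(truth_json, pth("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    log_stage(log_path, "simulate",
              list(seed = cfg$seed, n_se = cfg$n_se, n_te = cfg$n_te),
              c(files, pth("samples.tsv"), pth("truth.json")))
    list(genome = genome, h3k = h3k, tf = tf, pol2 = pol2,
         sequence = pm$sequence, pwms = pwms, truth = expr$truth,
         fpkm = expr$fpkm, samples = expr$samples,
         crc_tfs = crc_tfs, decoys = decoys)
  })

  ## stage: call-se (from the files the simulator wrote) --------------------
  se <- run_stage("call-se", {
    peaks <- read_peaks(pth("h3k27ac_peaks.narrowPeak"))
    chip <- read_bedgraph(pth("h3k27ac.bedGraph"))
    input <- read_bedgraph(pth("input.bedGraph"))
    genes <- read_genes(pth("genes.gtf"))
    call <- call_superenhancers(peaks, chip, genes, input = input,
                                stitch_distance = config$stitch_distance,
                                tss_pad = config$tss_pad,
                                flank = config$flank, sample_id = "demo")
    readr::write_tsv(tidy(call), pth("enhancer_table.tsv"))
    log_stage(log_path, "call-se",
              list(stitch = config$stitch_distance, tss_pad = config$tss_pad,
                   flank = config$flank),
              pth("enhancer_table.tsv"))
    list(call = call, genes = genes)
  })

  ## stage: annotate --------------------------------------------------------
  ann <- run_stage("annotate", {
    cls <- classify_peaks(sim$tf$peaks, se$genes, se$call, expr = sim$fpkm)
    overload <- tf_overload_rank(sim$tf$peaks, sim$tf$signal, se$genes,
                                 stitch_distance = config$stitch_distance,
                                 tss_pad = config$tss_pad,
                                 flank = config$flank, sample_id = "tf")
    dp <- double_positive(se_genes(se$call), se_genes(overload))
    enr <- enrichment_by_region_class(sim$tf$signal, se$call)
    readr::write_tsv(cls$fractions, pth("peak_categories.tsv"))
    readr::write_tsv(dp$counts, pth("double_positive_venn.tsv"))
    log_stage(log_path, "annotate", list(),
              c(pth("peak_categories.tsv"), pth("double_positive_venn.tsv")))
    list(classes = cls, overload = overload, double_positive = dp,
         enrichment = enr)
  })

  ## stage: pol2 ------------------------------------------------------------
  pol2_res <- run_stage("pol2", {
    pi_tbl <- pausing_index(sim$pol2, se$genes, windows = config$pausing)
    grp <- group_by_annotation(se$genes$gene_id,
                               list(SE = se_genes(se$call)))
    strat <- stratify_pausing(pi_tbl, grp)
    readr::write_tsv(pi_tbl, pth("pausing_index.tsv"))
    log_stage(log_path, "pol2",
              list(tss_up = config$pausing$tss_upstream,
                   tss_down = config$pausing$tss_downstream,
                   body_offset = config$pausing$body_start_offset),
              pth("pausing_index.tsv"))
    list(pi = pi_tbl, stratified = strat)
  })

  ## stage: crc -------------------------------------------------------------
  crc <- run_stage("crc", {
    res <- reconstruct_crc(se$call, sim$sequence, sim$pwms, fpkm = sim$fpkm,
                           threshold_frac = config$scan_threshold_frac)
    readr::write_tsv(tidy(res), pth("crc_scores.tsv"))
    readr::write_tsv(res$graph$edges, pth("crc_edges.tsv"))
    log_stage(log_path, "crc",
              list(threshold_frac = config$scan_threshold_frac),
              c(pth("crc_scores.tsv"), pth("crc_edges.tsv")))
    res
  })

  ## stage: respond ---------------------------------------------------------
  resp <- run_stage("respond", {
    lfc <- log2fc(sim$fpkm, sim$samples, "control", "treatment")
    grp <- group_by_annotation(sim$fpkm$gene_id,
                               list(SE = se_genes(se$call)))
    a <- lfc$log2fc[lfc$gene_id %in% grp$gene_id[grp$group == "SE"]]
    b <- lfc$log2fc[lfc$gene_id %in% grp$gene_id[grp$group == "none"]]
    test <- rank_test(a, b, paired = config$test_variant == "paired",
                      alternative = "less")
    basal <- basal_expression_by_se_class(
      sim$fpkm, group_by_annotation(sim$fpkm$gene_id,
                                    list(double_positive = ann$double_positive$both)),
      compare = c("double_positive", "none"),
      sample_ids = sim$samples$sample_id[sim$samples$condition == "control"])
    readr::write_tsv(lfc, pth("log2fc.tsv"))
    log_stage(log_path, "respond", list(test = config$test_variant),
              pth("log2fc.tsv"))
    list(lfc = lfc, groups = grp, test = test, basal = basal)
  })

  rec <- se_recovery(se$call, sim$truth)
  summary <- list(
    seed = cfg$seed,
    n_enhancers = nrow(se$call$enhancers),
    n_se = se$call$n_se, n_te = se$call$n_te,
    se_precision = rec$precision, se_recall = rec$recall,
    median_pausing_index = stats::median(pol2_res$pi$pausing_index,
                                         na.rm = TRUE),
    crc_top_tfs = utils::head(crc$scores$tf, 3),
    crc_n_cliques = length(crc$cliques),
    response_p_value = resp$test$p_value,
    response_median_se = stats::median(
      resp$lfc$log2fc[resp$lfc$gene_id %in%
                        resp$groups$gene_id[resp$groups$group == "SE"]]),
    response_median_other = stats::median(
      resp$lfc$log2fc[resp$lfc$gene_id %in%
                        resp$groups$gene_id[resp$groups$group == "none"]])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(summary = summary, out_dir = out_dir,
                 se_call = se$call, annotate = ann, pol2 = pol2_res,
                 crc = crc, respond = resp, truth = sim$truth,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<pipeline_run> %d enhancers (%d SE); planted-SE ",
                     "precision %.2f recall %.2f; CRC top: %s; response p = %.3g\n"),
              s$n_enhancers, s$n_se, s$se_precision, s$se_recall,
              paste(s$crc_top_tfs, collapse = ","), s$response_p_value))
  invisible(x)
}
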