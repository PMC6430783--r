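#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>% arrange bind_rows bind_cols filter group_by ungroup
#'   mutate summarise select left_join n row_number distinct pull across
#' @importFrom tibble tibble as_tibble
NULL

# All coordinates in this package are 0-based, half-open [start, end) (BED
# convention). GTF input (1-based closed) is converted at the reader boundary.

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    abort(paste0(what, " table must have chrom/start/end columns"))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("%s %d has start >= end (%g >= %g)",
                  what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(df$start < 0)) abort(paste0(what, " has negative start coordinate"))
  invisible(df)
}

#' Read peak calls from BED or narrowPeak files
#'
#' Parses BED3/BED5/BED6 or ENCODE narrowPeak (10 column) files into a peak
#' tibble. Coordinates are kept 0-based half-open. For narrowPeak input the
#' summit is `start + offset` (column 10); an offset of -1 means no summit.
#'
#' @param path Path to a tab-separated peak file.
#' @param format One of "auto", "bed", "narrowPeak". "auto" chooses
#'   narrowPeak when the file has 10 columns or a `.narrowPeak` extension.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`
#'   and `summit` (NA when absent).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), summit = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (all(ncols == 10) || grepl("narrowPeak$", path)) "narrowPeak" else "bed"
  }
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(ncols < need)
  if (length(bad) > 0) {
    abort(sprintf("parse error at line %d of %s: expected >= %d fields, got %d",
                  bad[1], path, need, ncols[bad[1]]))
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  num <- function(i, line_required = TRUE) {
    x <- suppressWarnings(as.numeric(get(i)))
    bad <- which(is.na(x) & !is.na(get(i)) & line_required)
    if (length(bad) > 0) {
      abort(sprintf("parse error at line %d of %s: non-numeric field %d", bad[1], path, i))
    }
    x
  }
  start <- num(2); end <- num(3)
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("validation error at line %d of %s: invalid interval [%s, %s)",
                  bad[1], path, get(2)[bad[1]], get(3)[bad[1]]))
  }
  name <- if (max(ncols) >= 4) get(4) else NA_character_
  name <- ifelse(is.na(name), paste0("peak_", seq_along(lines)), name)
  score <- if (max(ncols) >= 5) suppressWarnings(as.numeric(get(5))) else NA_real_
  score[is.na(score)] <- 0
  if (any(score < 0)) abort(paste0("validation error: negative peak score in ", path))
  summit <- rep(NA_real_, length(lines))
  if (format == "narrowPeak") {
    off <- num(10)
    summit <- ifelse(off < 0, NA_real_, start + off)
    bad <- which(!is.na(summit) & (summit < start | summit >= end))
    if (length(bad) > 0) {
      abort(sprintf("validation error at line %d of %s: summit outside peak", bad[1], path))
    }
  }
  tibble(chrom = get(1), start = start, end = end,
         name = name, score = score, summit = summit)
}

#' Write peaks as BED or narrowPeak
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `summit`).
#' @param path Output path.
#' @param format "bed" (5 columns) or "narrowPeak" (10 columns).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  validate_intervals(peaks, "peak")
  name <- if ("name" %in% names(peaks)) peaks$name else paste0("peak_", seq_len(nrow(peaks)))
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g", peaks$chrom, as.integer(peaks$start),
                     as.integer(peaks$end), name, score)
  } else {
    summit <- if ("summit" %in% names(peaks)) peaks$summit else NA_real_
    off <- ifelse(is.na(summit), -1L, as.integer(summit - peaks$start))
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.\t%g\t-1\t-1\t%d",
                     peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                     name, score, score, off)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Reads 4-column bedGraph into a signal-track tibble (sorted, disjoint,
#' non-negative piecewise-constant coverage; gaps read as zero). Overlapping
#' records and negative values are rejected.
#'
#' @param path Path to a bedGraph file.
#' @return A signal-track tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(as_signal_track(tibble(chrom = character(), start = double(),
                                  end = double(), value = double())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad) > 0) {
    abort(sprintf("parse error at line %d of %s: expected 4 fields", bad[1], path))
  }
  df <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3))),
    value = suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad) > 0) {
    abort(sprintf("parse error at line %d of %s: non-numeric coordinates or value",
                  bad[1], path))
  }
  as_signal_track(df)
}

#' Validate a data frame as a signal track
#'
#' Checks the signal-track invariants: per-chromosome sorted, disjoint
#' intervals with non-negative values. Zero-width rows are dropped.
#'
#' @param df Data frame with `chrom`, `start`, `end`, `value`.
#' @return The validated, sorted track tibble.
#' @export
as_signal_track <- function(df) {
  df <- as_tibble(df)[, c("chrom", "start", "end", "value")]
  df <- df[df$end > df$start, , drop = FALSE]
  if (nrow(df) > 0) validate_intervals(df, "signal record")
  if (any(df$value < 0)) abort("validation error: negative signal value")
  df <- arrange(df, .data$chrom, .data$start)
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    ovl <- which(same & df$start[-1] < df$end[-nrow(df)])
    if (length(ovl) > 0) {
      abort(sprintf("validation error: overlapping signal records %d and %d on %s",
                    ovl[1], ovl[1] + 1L, df$chrom[ovl[1]]))
    }
  }
  df
}

#' Write a signal track as bedGraph
#'
#' @param track Signal-track tibble.
#' @param path Output path.
#' @param drop_zero Drop zero-valued rows (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  track <- as_signal_track(track)
  if (drop_zero) track <- track[track$value > 0, , drop = FALSE]
  readr::write_lines(sprintf("%s\t%d\t%d\t%g", track$chrom,
                             as.integer(track$start), as.integer(track$end),
                             track$value), path)
  invisible(path)
}

# Sum possibly-overlapping weighted segments into a disjoint track.
flatten_segments <- function(df) {
  df <- as_tibble(df)[, c("chrom", "start", "end", "value")]
  df <- df[df$end > df$start, , drop = FALSE]
  if (nrow(df) == 0) return(as_signal_track(df))
  out <- lapply(split(df, df$chrom), function(d) {
    b <- sort(unique(c(d$start, d$end)))
    s <- b[-length(b)]; e <- b[-1]
    v <- numeric(length(s))
    # event-based accumulation: +value at start, -value at end
    idx_s <- findInterval(d$start, s)
    idx_e <- findInterval(d$end - 1e-9, s)  # last segment covered by the record
    delta <- numeric(length(s) + 1)
    add <- rowsum(d$value, idx_s)
    delta[as.integer(rownames(add))] <- delta[as.integer(rownames(add))] + add[, 1]
    sub <- rowsum(d$value, idx_e + 1L)
    delta[as.integer(rownames(sub))] <- delta[as.integer(rownames(sub))] - sub[, 1]
    v <- cumsum(delta[seq_along(s)])
    v[abs(v) < 1e-9] <- 0  # cancel floating-point residue from the cumsum
    keep <- v > 0
    tibble(chrom = d$chrom[1], start = s[keep], end = e[keep], value = v[keep])
  })
  as_signal_track(bind_rows(out))
}

#' Quantify signal area over genomic regions
#'
#' Area under a signal track over each query region: the sum over overlapped
#' track segments of value times overlap width (signal is density per base,
#' so area = value x width). Regions on chromosomes absent from the track
#' quantify to zero.
#'
#' @param track Signal-track tibble.
#' @param regions Data frame of query regions (`chrom`, `start`, `end`), or a
#'   single region given as `list(chrom=, start=, end=)`.
#' @return Numeric vector of areas, one per region row.
#' @export
interval_signal <- function(track, regions) {
  regions <- as_tibble(as.list(regions)[c("chrom", "start", "end")])
  if (nrow(regions) == 0) return(numeric(0))
  validate_intervals(regions, "query region")
  track <- as_signal_track(track)
  out <- numeric(nrow(regions))
  if (nrow(track) == 0) return(out)
  for (ch in unique(regions$chrom)) {
    qi <- which(regions$chrom == ch)
    d <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    cum <- c(0, cumsum(d$value * (d$end - d$start)))
    F <- function(x) {
      idx <- findInterval(x, d$start)
      ifelse(idx == 0, 0,
             cum[pmax(idx, 1)] +
               d$value[pmax(idx, 1)] *
               pmax(0, pmin(x, d$end[pmax(idx, 1)]) - d$start[pmax(idx, 1)]))
    }
    out[qi] <- F(regions$end[qi]) - F(regions$start[qi])
  }
  out
}

# Convert an interval tibble to GRanges (0-based half-open -> 1-based closed).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Overlap statistics between two peak sets
#'
#' Counts peaks of `a` that share at least `min_bp` bases with any peak of
#' `b`. Each `a` peak is counted once regardless of how many `b` partners it
#' has.
#'
#' @param a,b Peak tibbles (`chrom`, `start`, `end`, ...).
#' @param min_bp Minimum shared bases to call two peaks co-localized
#'   (default 1).
#' @return A list with `pairs` (tibble of overlapping index pairs
#'   `a_idx`/`b_idx` and shared `bp`), `n_overlapped`, and `fraction` of `a`
#'   overlapped (`NA` with a warning when `a` is empty).
#' @export
overlap_stats <- function(a, b, min_bp = 1) {
  stopifnot(min_bp >= 1)
  if (nrow(a) == 0) {
    warn("overlap_stats: empty `a` collection, fraction undefined")
    return(list(pairs = tibble(a_idx = integer(), b_idx = integer(), bp = double()),
                n_overlapped = 0L, fraction = NA_real_))
  }
  if (nrow(b) == 0) {
    return(list(pairs = tibble(a_idx = integer(), b_idx = integer(), bp = double()),
                n_overlapped = 0L, fraction = 0))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = min_bp)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  bp <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  pairs <- tibble(a_idx = ai, b_idx = bi, bp = bp)
  n_ov <- length(unique(ai))
  list(pairs = pairs, n_overlapped = n_ov, fraction = n_ov / nrow(a))
}

#' Read gene models from GTF or BED12
#'
#' GTF input (1-based closed) is converted to 0-based half-open at this
#' boundary; only `gene` features are kept (or all features collapsed by
#' `gene_id` when no `gene` feature is present). The TSS is the start for
#' `+` strand genes and `end - 1` for `-` strand genes.
#'
#' @param path Path to a `.gtf`/`.gff` or BED12 file.
#' @param format "auto", "gtf" or "bed12".
#' @return Gene tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `name`, `tss`, `tes`.
#' @export
read_genes <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.g[tf]f[23]?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- as.data.frame(S4Vectors::mcols(gr))
    df <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(md$type),
      gene_id = as.character(md$gene_id),
      name = if ("gene_name" %in% names(md)) as.character(md$gene_name) else NA_character_
    )
    if (any(df$type == "gene")) df <- df[df$type == "gene", , drop = FALSE]
    df <- df %>%
      group_by(.data$gene_id) %>%
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), strand = .data$strand[1],
                name = .data$name[1], .groups = "drop")
  } else {
    raw <- read_peaks(path, format = "bed")
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
    strand <- vapply(strsplit(lines, "\t"), function(f)
      if (length(f) >= 6) f[6] else "+", "")
    df <- tibble(gene_id = raw$name, chrom = raw$chrom, start = raw$start,
                 end = raw$end, strand = strand, name = raw$name)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort("validation error: gene strand must be '+' or '-'")
  }
  df %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
           tes = ifelse(.data$strand == "+", .data$end, .data$start)) %>%
    select("gene_id", "chrom", "start", "end", "strand", "name", "tss", "tes")
}

#' Write gene models as GTF
#'
#' @param genes Gene tibble as returned by [read_genes()] or
#'   [simulate_genome()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "secircuit") {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', genes$gene_id, genes$name)
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, source, as.integer(genes$start + 1),
                   as.integer(genes$end), genes$strand, attrs)
  readr::write_lines(lines, path)
  invisible(path)
}

# Strand-aware promoter windows in genomic coordinates.
# + strand: [tss - upstream, tss + downstream); - strand mirrored.
promoter_windows <- function(genes, upstream = 1000, downstream = 200) {
  tibble(
    chrom = genes$chrom,
    start = pmax(0, ifelse(genes$strand == "+",
                           genes$tss - upstream,
                           genes$tss - downstream + 1)),
    end = ifelse(genes$strand == "+",
                 genes$tss + downstream,
                 genes$tss + upstream + 1),
    gene_id = genes$gene_id
  )
}
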