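#' Anchored gene-body regions
#'
#' The unit of aggregation is a gene body carrying one anchor point: a
#' replication origin inside the gene body (`origin_in_gene_body`), the gene
#' midpoint (`gene_body_center`), or a random genomic position (`random`).
#' Transcription strand orients the analysis window so that negative offsets
#' always point upstream of the anchor in the transcription direction, which
#' for an internal replication origin is where head-on (HO) collisions occur.
#'
#' `load_regions` reads and validates a 6-column tab-separated BED-like table
#' (chrom, gene_start, gene_end, anchor, strand, region_class; no header) and
#' reports per-class counts.
#'
#' @param x Path to a region table, or a data.frame with the six columns.
#' @param genome A `genome_layout`; all regions must lie on known chromosomes.
#' @param quiet Suppress the load summary message.
#'
#' @return A validated data.frame of regions with a `region_id` column and a
#'   `class_counts` attribute (named integer vector).
#' @export
load_regions <- function(x, genome, quiet = FALSE) {
  stopifnot(inherits(genome, "genome_layout"))
  cols <- c("chrom", "gene_start", "gene_end", "anchor", "strand", "region_class")
  if (is.character(x) && length(x) == 1L) {
    df <- utils::read.table(x, sep = "\t", header = FALSE, col.names = cols,
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric", "character", "character"))
  } else if (is.data.frame(x)) {
    if (!all(cols %in% names(x))) {
      stop("region table must have columns: ", paste(cols, collapse = ", "))
    }
    df <- as.data.frame(x)[cols]
  } else {
    stop("x must be a file path or a data.frame")
  }
  df <- validate_regions(df, genome)
  counts <- table(factor(df$region_class, levels = region_classes()))
  attr(df, "class_counts") <- stats::setNames(as.integer(counts), names(counts))
  if (!quiet) {
    message("loaded ", nrow(df), " regions (",
            paste(names(counts), as.integer(counts), sep = " = ", collapse = ", "), ")")
  }
  df
}

region_classes <- function() c("origin_in_gene_body", "gene_body_center", "random")

validate_regions <- function(df, genome) {
  n <- nrow(df)
  if (n == 0L) stop("region table is empty")
  bad_chrom <- which(!(df$chrom %in% genome$chrom_names))
  if (length(bad_chrom)) {
    stop("unknown chromosome '", df$chrom[bad_chrom[1L]],
         "' in region row ", bad_chrom[1L])
  }
  bad_cls <- which(!(df$region_class %in% region_classes()))
  if (length(bad_cls)) {
    stop("unknown region_class '", df$region_class[bad_cls[1L]],
         "' in region row ", bad_cls[1L])
  }
  bad_iv <- which(!(df$gene_start < df$gene_end) | df$gene_start < 0)
  if (length(bad_iv)) {
    stop("invalid gene interval in region row ", bad_iv[1L],
         " (need 0 <= gene_start < gene_end)")
  }
  ends <- genome$chrom_lengths[df$chrom]
  bad_end <- which(df$gene_end > ends)
  if (length(bad_end)) {
    stop("gene interval exceeds chromosome length in region row ", bad_end[1L])
  }
  # anchor must fall inside the gene body (half-open) for anchored classes
  anchored <- df$region_class != "random"
  bad_anchor <- which(anchored &
                        (df$anchor < df$gene_start | df$anchor >= df$gene_end))
  if (length(bad_anchor)) {
    stop("anchor outside gene body (half-open) in region row ", bad_anchor[1L])
  }
  bad_strand <- which(anchored & !(df$strand %in% c("+", "-")))
  if (length(bad_strand)) {
    stop("malformed strand '", df$strand[bad_strand[1L]],
         "' in region row ", bad_strand[1L])
  }
  # random regions carry no transcription direction; fixed to "+"
  df$strand[!anchored] <- "+"
  if (is.null(df$region_id)) {
    df$region_id <- sprintf("region_%05d", seq_len(n))
  }
  rownames(df) <- NULL
  df
}

#' Serialize a region table
#'
#' Writes the 6-column tab-separated BED-like dialect read by
#' [load_regions()] (no header).
#'
#' @param regions Validated region data.frame.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  cols <- c("chrom", "gene_start", "gene_end", "anchor", "strand", "region_class")
  out <- regions[cols]
  for (cc in c("gene_start", "gene_end", "anchor")) {
    out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Analysis window specification
#'
#' A window of `2 * half_width` bp centred on the (bin-snapped) anchor, tiled
#' by `bin_width`-bp bins and expressed in transcription-oriented offsets:
#' negative offsets are upstream of the anchor in the transcription direction.
#'
#' @param half_width Half window width in bp (default 12,000, i.e. the 24-kb
#'   window used for origin-anchored metaprofiles).
#' @param bin_width Bin width in bp (default 100).
#' @return A `window_spec` with the bin-start `offsets` precomputed.
#' @export
window_spec <- function(half_width = 12000, bin_width = 100) {
  half_width <- as.numeric(half_width)
  bin_width <- as.numeric(bin_width)
  if (bin_width < 1) stop("bin_width must be >= 1")
  if (half_width < bin_width) stop("half_width must be >= bin_width")
  if (half_width %% bin_width != 0) {
    stop("half_width must be divisible by bin_width")
  }
  n_bins <- as.integer(2 * half_width / bin_width)
  structure(
    list(half_width = half_width, bin_width = bin_width, n_bins = n_bins,
         offsets = seq(-half_width, half_width - bin_width, by = bin_width)),
    class = "window_spec"
  )
}

# Snap a position to the start of its containing bin.
snap_to_bin <- function(pos, bin_width) (pos %/% bin_width) * bin_width

#' Build the oriented bin coordinates of one region's window
#'
#' Returns the genomic bins covering `[anchor - half_width, anchor + half_width)`
#' (anchor snapped to the containing bin start), ordered so that increasing
#' offset always points in the transcription direction: for minus-strand gene
#' bodies the bin order is inverted, so head-on collision territory keeps a
#' negative offset from the origin.
#'
#' @param region One region: a one-row data.frame or list with `chrom`,
#'   `anchor`, `strand`.
#' @param spec A [window_spec()].
#' @param genome A `genome_layout`.
#'
#' @return A data.frame with columns `offset` (oriented bin-start offset),
#'   `start`, `end` (genomic, 0-based half-open), plus attribute
#'   `out_of_bounds` (TRUE if the window overruns the chromosome and the
#'   region should be dropped from aggregation).
#' @export
build_window <- function(region, spec, genome) {
  stopifnot(inherits(spec, "window_spec"), inherits(genome, "genome_layout"))
  chrom <- as.character(region$chrom)
  if (!(chrom %in% genome$chrom_names)) stop("unknown chromosome: ", chrom)
  a0 <- snap_to_bin(as.numeric(region$anchor), spec$bin_width)
  lo <- a0 - spec$half_width
  hi <- a0 + spec$half_width
  oob <- lo < 0 || hi > genome$chrom_lengths[[chrom]]
  if (identical(as.character(region$strand), "-")) {
    starts <- a0 + spec$half_width - spec$bin_width * seq_len(spec$n_bins)
  } else {
    starts <- a0 + spec$offsets
  }
  out <- data.frame(offset = spec$offsets, start = starts,
                    end = starts + spec$bin_width)
  attr(out, "out_of_bounds") <- oob
  out
}

#' Sub-window within the oriented analysis window
#'
#' Offsets are transcription-oriented base pairs relative to the anchor,
#' half-open `[offset_start, offset_end)`.
#'
#' @param label Sub-window label (e.g. `"HO"`, `"CD"`, `"full_quant"`).
#' @param offset_start,offset_end Half-open oriented offsets in bp.
#' @return A `sub_window` object.
#' @export
sub_window <- function(label, offset_start, offset_end) {
  if (!(offset_start < offset_end)) stop("offset_start must be < offset_end")
  structure(list(label = as.character(label),
                 offset_start = as.numeric(offset_start),
                 offset_end = as.numeric(offset_end)),
            class = "sub_window")
}

#' Head-on / co-directional sub-windows
#'
#' Splits the quantification window around the anchor into the head-on (HO)
#' collision sub-window (6 kb upstream of the origin in the transcription
#' frame, `[-quant_half_width, 0)`), the co-directional (CD) sub-window
#' (`[0, +quant_half_width)`), and their union `full_quant`
#' (`[-quant_half_width, +quant_half_width)`, the 12-kb quantification window
#' at the default).
#'
#' @param spec A [window_spec()]; its half width must cover the sub-windows.
#' @param quant_half_width Half width of the quantification window (default
#'   6,000 bp).
#' @return Named list of three `sub_window`s: `HO`, `CD`, `full_quant`.
#' @export
split_sub_windows <- function(spec, quant_half_width = 6000) {
  stopifnot(inherits(spec, "window_spec"))
  if (spec$half_width < quant_half_width) {
    stop("window half_width (", spec$half_width,
         ") must be >= quant_half_width (", quant_half_width, ")")
  }
  if (quant_half_width %% spec$bin_width != 0) {
    stop("quant_half_width must be divisible by bin_width")
  }
  list(HO = sub_window("HO", -quant_half_width, 0),
       CD = sub_window("CD", 0, quant_half_width),
       full_quant = sub_window("full_quant", -quant_half_width, quant_half_width))
}

#' Sample random control windows
#'
#' Draws `n` anchors uniformly over genomic positions where a full window of
#' `width` bp fits inside a chromosome, with per-chromosome probability
#' proportional to the number of usable positions. Returned regions have class
#' `random` and `+` strand (no transcription direction exists), with the
#' window extent recorded as the gene interval. Windows may overlap each
#' other; the nominal genome coverage of the set is `n * width / genome
#' length`, overlap-ignoring.
#'
#' @param genome A `genome_layout`.
#' @param n Number of windows (default 50,000, the study's negative-control
#'   set size).
#' @param width Full window width in bp (default 24,000).
#' @param seed Optional RNG seed for reproducible sampling.
#' @return A validated region data.frame with attribute
#'   `nominal_coverage` (fraction of the genome nominally spanned).
#' @export
sample_random_windows <- function(genome, n = 50000, width = 24000, seed = NULL) {
  stopifnot(inherits(genome, "genome_layout"))
  n <- as.numeric(n)
  if (length(n) != 1L || !is.finite(n) || n <= 0) stop("n must be a positive count")
  half <- width / 2
  usable <- pmax(floor(genome$chrom_lengths) - width + 1, 0)
  if (all(usable == 0)) {
    stop("no chromosome is long enough to hold a window of width ", width)
  }
  df <- with_seed(seed, {
    chrom <- sample(genome$chrom_names, n, replace = TRUE,
                    prob = usable / sum(usable))
    anchor <- half + floor(stats::runif(n) * usable[chrom])
    data.frame(chrom = chrom,
               gene_start = anchor - half,
               gene_end = anchor + half,
               anchor = anchor,
               strand = "+",
               region_class = "random")
  })
  out <- validate_regions(df, genome)
  attr(out, "nominal_coverage") <- n * width / genome_length(genome)
  out
}
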