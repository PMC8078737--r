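#' Binned signal track
#'
#' Per-chromosome fixed-width bin counts plus the library size they were
#' derived from. `signal_track()` is the low-level constructor; most users
#' build tracks with [bin_reads()] and scale them with [normalize_track()].
#'
#' @param genome A `genome_layout`.
#' @param counts Named list of per-chromosome numeric vectors, one value per
#'   bin (`ceiling(chrom_length / bin_width)` bins). Missing chromosomes are
#'   filled with zeros.
#' @param bin_width Bin width in bp (default 100).
#' @param library_size Total mapped, duplicate-removed read count backing the
#'   track.
#' @param normalized Whether counts are on the `norm_target` library scale.
#' @param norm_target Normalization target library size in reads (default
#'   10,000,000).
#' @param sample_id Optional sample label.
#'
#' @return A `signal_track` object.
#' @export
signal_track <- function(genome, counts = NULL, bin_width = 100,
                         library_size = 0, normalized = FALSE,
                         norm_target = 1e7, sample_id = NULL) {
  stopifnot(inherits(genome, "genome_layout"))
  nbins <- n_bins_per_chrom(genome, bin_width)
  full <- lapply(genome$chrom_names, function(ch) {
    v <- counts[[ch]]
    if (is.null(v)) return(numeric(nbins[[ch]]))
    v <- as.numeric(v)
    if (length(v) != nbins[[ch]]) {
      stop("counts for ", ch, " must have ", nbins[[ch]], " bins, got ", length(v))
    }
    if (any(v < 0)) stop("bin counts must be non-negative")
    v
  })
  names(full) <- genome$chrom_names
  structure(
    list(genome = genome, bin_width = as.numeric(bin_width), counts = full,
         library_size = as.numeric(library_size),
         normalized = isTRUE(normalized), norm_target = as.numeric(norm_target),
         sample_id = sample_id, n_skipped = 0L),
    class = "signal_track"
  )
}

n_bins_per_chrom <- function(genome, bin_width) {
  stats::setNames(as.integer(ceiling(genome$chrom_lengths / bin_width)),
                  genome$chrom_names)
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track>", if (!is.null(x$sample_id)) x$sample_id else "",
      "\n  bins: ", x$bin_width, " bp; library_size: ",
      format(x$library_size, big.mark = ","),
      "; normalized: ", x$normalized,
      if (x$normalized) paste0(" (target ", format(x$norm_target, big.mark = ","), ")"),
      "\n  total signal: ", format(sum(track_total(x)), digits = 8), "\n", sep = "")
  invisible(x)
}

track_total <- function(track) sum(vapply(track$counts, sum, numeric(1)))

# Accept a BED path, GRanges, or data.frame and return a 0-based half-open
# read interval data.frame with a strand column.
as_read_intervals <- function(reads) {
  if (is.character(reads) && length(reads) == 1L) {
    gr <- rtracklayer::import(reads, format = "BED")
    reads <- gr
  }
  if (methods::is(reads, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                     start = GenomicRanges::start(reads) - 1,
                     end = GenomicRanges::end(reads),
                     strand = as.character(GenomicRanges::strand(reads)))
    df$strand[df$strand == "*"] <- "+"
    return(df)
  }
  if (!is.data.frame(reads)) stop("reads must be a BED path, GRanges or data.frame")
  if (!all(c("chrom", "start", "end") %in% names(reads))) {
    stop("read table must have columns chrom, start, end")
  }
  df <- as.data.frame(reads)
  if (is.null(df$strand)) df$strand <- rep("+", nrow(df))
  df$strand[!(df$strand %in% c("+", "-"))] <- "+"
  df
}

#' Bin aligned reads into a raw signal track
#'
#' Each read contributes one count to the bin containing its strand-aware
#' 5' end (interval start for `+`, `end - 1` for `-`): single-point
#' assignment keeps count conservation exact. Reads on chromosomes absent
#' from the genome are skipped and counted in the `n_skipped` field.
#'
#' @param reads BED3/BED6 file path, `GRanges`, or data.frame with `chrom`,
#'   `start`, `end` (0-based half-open) and optional `strand`.
#' @param genome A `genome_layout`.
#' @param bin_width Bin width in bp (default 100).
#' @param library_size Total duplicate-removed mapped reads; defaults to the
#'   number of reads supplied (after optional dedup). Override when the read
#'   set is a subset of a larger library.
#' @param dedup Drop exact duplicate intervals before counting (off by
#'   default; upstream processing normally removes duplicates).
#' @param sample_id Optional sample label.
#' @return A raw `signal_track`.
#' @export
bin_reads <- function(reads, genome, bin_width = 100, library_size = NULL,
                      dedup = FALSE, sample_id = NULL) {
  stopifnot(inherits(genome, "genome_layout"))
  if (bin_width < 1) stop("bin_width must be >= 1")
  df <- as_read_intervals(reads)
  if (dedup && nrow(df)) {
    df <- df[!duplicated(df[c("chrom", "start", "end", "strand")]), , drop = FALSE]
  }
  if (nrow(df) && any(df$start < 0)) stop("negative read coordinates")
  known <- df$chrom %in% genome$chrom_names
  n_skipped <- sum(!known)
  if (n_skipped) {
    message("bin_reads: skipped ", n_skipped, " reads on unknown chromosomes")
  }
  kept <- df[known, , drop = FALSE]
  five_prime <- ifelse(kept$strand == "-", kept$end - 1, kept$start)
  nbins <- n_bins_per_chrom(genome, bin_width)
  counts <- lapply(genome$chrom_names, function(ch) {
    sel <- kept$chrom == ch
    if (!any(sel)) return(numeric(nbins[[ch]]))
    idx <- (five_prime[sel] %/% bin_width) + 1
    if (any(idx > nbins[[ch]])) stop("read beyond chromosome end on ", ch)
    as.numeric(tabulate(idx, nbins = nbins[[ch]]))
  })
  names(counts) <- genome$chrom_names
  track <- signal_track(genome, counts, bin_width = bin_width,
                        library_size = if (is.null(library_size)) nrow(df) else library_size,
                        normalized = FALSE, sample_id = sample_id)
  track$n_skipped <- n_skipped
  track
}

#' Normalize a track to a fixed library scale
#'
#' Multiplies every bin by `norm_target / library_size`, putting samples of
#' different sequencing depth on a common reads-per-10M scale. Normalizing an
#' already-normalized track is an error (the operation is not idempotent).
#'
#' @param track A raw `signal_track` with `library_size > 0`.
#' @param norm_target Target library size (default 10,000,000 reads).
#' @return The normalized `signal_track`.
#' @export
normalize_track <- function(track, norm_target = 1e7) {
  stopifnot(inherits(track, "signal_track"))
  if (track$normalized) stop("track is already normalized")
  if (track$library_size <= 0) stop("library_size must be > 0 to normalize")
  scale <- norm_target / track$library_size
  track$counts <- lapply(track$counts, function(v) v * scale)
  track$normalized <- TRUE
  track$norm_target <- as.numeric(norm_target)
  track
}

#' Read / write 100-nt-grid bedGraph tracks
#'
#' `write_bedgraph` emits a UCSC bedGraph whose track line records the
#' library size and normalization state
#' (`description="library_size=... normalized=... bin_width=..."`); zero bins
#' are omitted. `read_bedgraph` parses the file (intervals must lie on the
#' bin grid; multi-bin spans aligned to the grid are expanded) and restores
#' the metadata, which can be overridden.
#'
#' @param track A `signal_track`.
#' @param path File path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  name <- if (is.null(track$sample_id)) "driptrc" else track$sample_id
  header <- sprintf(
    'track type=bedGraph name="%s" description="library_size=%s normalized=%s norm_target=%s bin_width=%s"',
    name, format(track$library_size, scientific = FALSE),
    track$normalized, format(track$norm_target, scientific = FALSE),
    format(track$bin_width, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  for (ch in track$genome$chrom_names) {
    v <- track$counts[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    starts <- (nz - 1) * track$bin_width
    utils::write.table(
      data.frame(ch,
                 format(starts, scientific = FALSE, trim = TRUE),
                 format(starts + track$bin_width, scientific = FALSE, trim = TRUE),
                 format(v[nz], digits = 15, scientific = FALSE, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @param genome A `genome_layout` giving the bin grid for reading.
#' @param bin_width Bin width the file must align to (default 100).
#' @param library_size,normalized Optional overrides for the track-line
#'   metadata (required if the file has no driptrc track line).
#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, genome, bin_width = 100,
                          library_size = NULL, normalized = NULL) {
  stopifnot(inherits(genome, "genome_layout"))
  first <- readLines(path, n = 1L)
  meta <- parse_trackline_meta(first)
  if (is.null(library_size)) library_size <- meta$library_size
  if (is.null(normalized)) normalized <- meta$normalized
  if (is.null(library_size)) library_size <- 0
  if (is.null(normalized)) normalized <- FALSE
  norm_target <- if (is.null(meta$norm_target)) 1e7 else meta$norm_target
  nbins <- n_bins_per_chrom(genome, bin_width)
  counts <- lapply(nbins, numeric)
  info <- file.info(path)
  has_data <- length(first) > 0 &&
    (length(readLines(path, n = 2L)) > 1L || !grepl("^(track|#)", first))
  if (!is.na(info$size) && info$size > 0 && has_data) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
      ch <- as.character(GenomicRanges::seqnames(gr))
      s <- GenomicRanges::start(gr) - 1
      e <- GenomicRanges::end(gr)
      v <- gr$score
      bad_chrom <- which(!(ch %in% genome$chrom_names))
      if (length(bad_chrom)) {
        stop("bedGraph line ", bad_chrom[1L], ": unknown chromosome ", ch[bad_chrom[1L]])
      }
      off_grid <- which(s %% bin_width != 0 | (e - s) %% bin_width != 0 | e <= s)
      if (length(off_grid)) {
        stop("bedGraph interval off the ", bin_width, "-bp bin grid at data line ",
             off_grid[1L], " (", ch[off_grid[1L]], ":", s[off_grid[1L]], "-",
             e[off_grid[1L]], ")")
      }
      for (i in seq_along(ch)) {
        idx <- seq(s[i] %/% bin_width + 1, (e[i] - 1) %/% bin_width + 1)
        if (max(idx) > nbins[[ch[i]]]) {
          stop("bedGraph interval beyond chromosome end at data line ", i)
        }
        counts[[ch[i]]][idx] <- counts[[ch[i]]][idx] + v[i]
      }
    }
  }
  track <- signal_track(genome, counts, bin_width = bin_width,
                        library_size = library_size, normalized = normalized,
                        norm_target = norm_target)
  track
}

parse_trackline_meta <- function(line) {
  out <- list(library_size = NULL, normalized = NULL, norm_target = NULL)
  if (length(line) == 0 || !grepl("^track", line)) return(out)
  m <- regmatches(line, regexec("library_size=([0-9.eE+]+)", line))[[1]]
  if (length(m) == 2) out$library_size <- as.numeric(m[2])
  m <- regmatches(line, regexec("norm_target=([0-9.eE+]+)", line))[[1]]
  if (length(m) == 2) out$norm_target <- as.numeric(m[2])
  m <- regmatches(line, regexec("normalized=(TRUE|FALSE)", line))[[1]]
  if (length(m) == 2) out$normalized <- as.logical(m[2])
  out
}
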