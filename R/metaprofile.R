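#' Aggregate a normalized track over oriented anchored windows
#'
#' Builds the regions-by-bins matrix underlying a metaprofile: row `r`,
#' column `j` holds the track value of the `j`-th transcription-oriented bin
#' of region `r`. Minus-strand rows are orientation-inverted so that negative
#' offsets always point upstream of the anchor in the transcription
#' direction. Regions whose window overruns a chromosome end are dropped (not
#' padded) and counted in `n_dropped`.
#'
#' @param track A normalized `signal_track` whose bin width matches `spec`.
#' @param regions Validated region data.frame (see [load_regions()]).
#' @param spec A [window_spec()].
#' @param sample_id Optional label; defaults to the track's.
#' @return A `meta_profile` object: `sample_id`, `region_ids`, `offsets`,
#'   `matrix` (regions x bins) and `n_dropped`.
#' @export
aggregate_profile <- function(track, regions, spec = window_spec(),
                              sample_id = NULL) {
  stopifnot(inherits(track, "signal_track"), inherits(spec, "window_spec"))
  if (!track$normalized) stop("track must be normalized before aggregation")
  if (track$bin_width != spec$bin_width) {
    stop("track bin_width (", track$bin_width, ") does not match window spec (",
         spec$bin_width, ")")
  }
  if (is.null(regions) || nrow(regions) == 0L) stop("empty region list")
  genome <- track$genome
  bw <- spec$bin_width
  half <- spec$half_width
  nb <- spec$n_bins
  lens <- genome$chrom_lengths
  a0 <- snap_to_bin(regions$anchor, bw)
  oob <- (a0 - half) < 0 | (a0 + half) > lens[regions$chrom]
  keep <- which(!oob)
  if (!length(keep)) stop("all regions fall outside chromosome bounds")
  n_dropped <- sum(oob)
  if (n_dropped) {
    message("aggregate_profile: dropped ", n_dropped,
            " regions at chromosome edges")
  }
  mat <- matrix(0, nrow = length(keep), ncol = nb)
  fwd <- seq_len(nb)
  rev_idx <- rev(fwd)
  for (i in seq_along(keep)) {
    r <- keep[i]
    first_bin <- (a0[r] - half) %/% bw + 1
    vals <- track$counts[[regions$chrom[r]]][first_bin:(first_bin + nb - 1)]
    mat[i, ] <- if (regions$strand[r] == "-") vals[rev_idx] else vals
  }
  ids <- if (!is.null(regions$region_id)) regions$region_id[keep] else as.character(keep)
  rownames(mat) <- ids
  meta_profile(sample_id = if (is.null(sample_id)) track$sample_id else sample_id,
               region_ids = ids, offsets = spec$offsets, matrix = mat,
               n_dropped = n_dropped, spec = spec)
}

#' Metaprofile container
#'
#' Low-level constructor for the regions-by-bins matrix produced by
#' [aggregate_profile()]; exposed so summaries can be computed on matrices
#' built elsewhere (e.g. in simulations).
#'
#' @param sample_id Sample label (may be NULL).
#' @param region_ids Character vector of row identifiers.
#' @param offsets Strictly increasing oriented bin-start offsets (bp).
#' @param matrix Numeric matrix, `length(region_ids)` rows by
#'   `length(offsets)` columns, non-negative.
#' @param n_dropped Number of regions dropped at chromosome edges.
#' @param spec Optional originating [window_spec()].
#' @return A `meta_profile` object.
#' @export
meta_profile <- function(sample_id, region_ids, offsets, matrix,
                         n_dropped = 0L, spec = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(region_ids) || ncol(matrix) != length(offsets)) {
    stop("matrix must be length(region_ids) x length(offsets)")
  }
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  structure(list(sample_id = sample_id, region_ids = as.character(region_ids),
                 offsets = as.numeric(offsets), matrix = matrix,
                 n_dropped = as.integer(n_dropped), spec = spec),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("<meta_profile>", if (!is.null(x$sample_id)) x$sample_id else "",
      "\n  ", nrow(x$matrix), " regions x ", ncol(x$matrix), " bins (",
      x$n_dropped, " dropped at edges)\n", sep = "")
  invisible(x)
}

# Lower-interpolation median: deterministic for even counts.
median_lower <- function(x) sort(x)[ceiling(length(x) / 2)]

profile_statistic <- function(mat, statistic) {
  if (statistic == "mean") .colMeans(mat, nrow(mat), ncol(mat))
  else apply(mat, 2, median_lower)
}

#' Column-wise profile summary with bootstrap confidence bands
#'
#' Per-bin mean (or lower-interpolation median) across regions, with a
#' percentile bootstrap band obtained by resampling regions (rows) with
#' replacement `n_boot` times. The 2.5/97.5 percentiles of the resampled
#' statistic give the band.
#'
#' @param profile A `meta_profile`.
#' @param statistic `"mean"` or `"median"`.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param seed Optional RNG seed for reproducible bands.
#' @return A data.frame with columns `offset`, `point`, `ci_low`, `ci_high`
#'   and attributes `statistic`, `n_boot`, `seed`, `n_regions`.
#' @export
summarize_profile <- function(profile, statistic = c("mean", "median"),
                              n_boot = 10000, seed = NULL) {
  stopifnot(inherits(profile, "meta_profile"))
  statistic <- match.arg(statistic)
  if (n_boot < 1) stop("n_boot must be >= 1")
  mat <- profile$matrix
  n <- nrow(mat)
  if (n == 1L) warning("single-region profile: bootstrap band is degenerate")
  point <- profile_statistic(mat, statistic)
  boots <- with_seed(seed, boot_statistics(mat, statistic, n_boot))
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(offset = profile$offsets, point = point,
                    ci_low = ci[1, ], ci_high = ci[2, ])
  rownames(out) <- NULL
  attr(out, "statistic") <- statistic
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_regions") <- n
  out
}

# n_boot x n_bins matrix of resampled column statistics. Means are computed
# chunk-wise as a resample-count matrix product so large n_boot stays cheap.
boot_statistics <- function(mat, statistic, n_boot) {
  n <- nrow(mat)
  if (statistic == "mean") {
    chunk <- max(1L, min(n_boot, floor(2e7 / n)))
    out <- matrix(0, nrow = n_boot, ncol = ncol(mat))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      idx <- sample.int(n, k * n, replace = TRUE)
      w <- matrix(0, nrow = k, ncol = n)
      # tabulate resample counts per bootstrap replicate
      for (row in seq_len(k)) {
        w[row, ] <- tabulate(idx[((row - 1) * n + 1):(row * n)], nbins = n)
      }
      out[(done + 1):(done + k), ] <- (w %*% mat) / n
      done <- done + k
    }
    out
  } else {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      apply(mat[idx, , drop = FALSE], 2, median_lower)
    }, numeric(ncol(mat))))
  }
}

#' Per-region average over a sub-window
#'
#' Arithmetic mean, per region, of the bins whose oriented offsets fall in
#' the sub-window `[offset_start, offset_end)`.
#'
#' @param profile A `meta_profile`.
#' @param sub A [sub_window()].
#' @return A data.frame with columns `region_id`, `average`, plus attributes
#'   `sample_id` and `window` (the sub-window label).
#' @export
window_average <- function(profile, sub) {
  stopifnot(inherits(profile, "meta_profile"), inherits(sub, "sub_window"))
  sel <- profile$offsets >= sub$offset_start & profile$offsets < sub$offset_end
  if (!any(sel)) stop("sub-window [", sub$offset_start, ", ", sub$offset_end,
                      ") overlaps no bins")
  avg <- rowMeans(profile$matrix[, sel, drop = FALSE])
  out <- data.frame(region_id = profile$region_ids, average = as.numeric(avg))
  rownames(out) <- NULL
  attr(out, "sample_id") <- profile$sample_id
  attr(out, "window") <- sub$label
  out
}

#' Empirical cumulative distribution table
#'
#' Tabulates the right-continuous ECDF of a set of per-region averages at its
#' sorted unique values (ties merged), using [stats::ecdf()].
#'
#' @param values Non-empty numeric vector.
#' @return A data.frame with columns `value` and `cum_freq` (`F(value)`).
#' @export
ecdf_table <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || all(is.na(values))) stop("empty input")
  f <- stats::ecdf(values)
  v <- sort(unique(values))
  data.frame(value = v, cum_freq = f(v))
}
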