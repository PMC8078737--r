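#' Sample-vs-control contingency table over a quantification window
#'
#' Builds the 2x2 table fed to Fisher's exact test: in-window vs rest-of-
#' library normalized read counts for the sample and the control. The
#' in-window cell is the (half-to-even) rounded sum of normalized counts over
#' the sub-window bins of every aggregated region; the out-of-window cell is
#' the remainder of the normalization-target library.
#'
#' Validity note: feeding rounded normalized counts to an exact count test is
#' conservative only when the normalization scale factor is at most 1 (library
#' size >= normalization target); a warning is issued otherwise.
#'
#' @param sample,control Normalized `signal_track`s sharing genome, bin width
#'   and `norm_target`.
#' @param regions Validated region data.frame.
#' @param sub A [sub_window()].
#' @param spec A [window_spec()].
#' @return A `contingency_table` object with integer cells `a`, `b` (sample
#'   in/out) and `c`, `d` (control in/out), and a `degenerate` flag when no
#'   in-window signal exists in either track.
#' @export
build_table <- function(sample, control, regions, sub, spec = window_spec()) {
  stopifnot(inherits(sample, "signal_track"), inherits(control, "signal_track"))
  if (!sample$normalized || !control$normalized) {
    stop("both tracks must be normalized")
  }
  if (sample$norm_target != control$norm_target) {
    stop("tracks are normalized to different targets")
  }
  if (sample$norm_target > sample$library_size ||
      control$norm_target > control$library_size) {
    warning("norm_target exceeds a library size: normalized counts are ",
            "over-dispersed and the exact test may overstate significance",
            call. = FALSE)
  }
  a_raw <- in_window_sum(sample, regions, sub, spec)
  c_raw <- in_window_sum(control, regions, sub, spec)
  contingency_table(a_raw, c_raw, sample$norm_target)
}

in_window_sum <- function(track, regions, sub, spec) {
  prof <- suppressMessages(aggregate_profile(track, regions, spec))
  sel <- prof$offsets >= sub$offset_start & prof$offsets < sub$offset_end
  if (!any(sel)) stop("sub-window overlaps no bins")
  sum(prof$matrix[, sel, drop = FALSE])
}

contingency_table <- function(a_raw, c_raw, norm_target) {
  if (a_raw > norm_target || c_raw > norm_target) {
    stop("in-window normalized count exceeds the normalization target; ",
         "input tracks do not look normalized")
  }
  a <- round(a_raw)
  c_ <- round(c_raw)
  tab <- structure(
    list(a = a, b = round(norm_target) - a,
         c = c_, d = round(norm_target) - c_,
         degenerate = (a == 0 && c_ == 0)),
    class = "contingency_table")
  if (tab$degenerate) warning("degenerate contingency table: no in-window signal",
                              call. = FALSE)
  tab
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  print(matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
               dimnames = list(c("sample", "control"), c("in", "out"))))
  invisible(x)
}

#' Two-sided Fisher's exact test on a contingency table
#'
#' Two-sided p-value by the minimum-likelihood rule (the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's), computed by
#' [stats::fisher.test()]. The odds ratio is the sample cross-product ratio
#' `(a d) / (b c)`; it is `NA` (undefined) when both numerator and
#' denominator vanish. A table with any zero margin carries no information:
#' p = 1 and the odds ratio is undefined.
#'
#' @param table A `contingency_table` from [build_table()], or four
#'   non-negative integers `a, b, c, d` given as a numeric vector.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(table) {
  if (inherits(table, "contingency_table")) {
    cells <- c(table$a, table$b, table$c, table$d)
  } else {
    cells <- as.numeric(table)
  }
  if (length(cells) != 4 || any(cells < 0) || any(cells != round(cells))) {
    stop("table must be four non-negative integers (a, b, c, d)")
  }
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  num <- a * d
  den <- b * c_
  odds_ratio <- if (num == 0 && den == 0) NA_real_ else num / den
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  list(odds_ratio = odds_ratio, p_value = min(1, ft$p.value))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; must be at least `length(p)` (default).
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Batch sample-vs-control enrichment tests
#'
#' One Fisher test per (sample, sub-window), Bonferroni-corrected over the
#' whole batch (family size m = number of samples times number of
#' sub-windows).
#'
#' @param samples Named list of normalized `signal_track`s to test against
#'   the control.
#' @param control Normalized `signal_track`.
#' @param regions Validated region data.frame.
#' @param sub_windows List of [sub_window()]s (default: HO, CD and the full
#'   quantification window from [split_sub_windows()]).
#' @param spec A [window_spec()].
#' @return A data.frame of class `enrichment_results`, one row per sample and
#'   window: `sample`, `window`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_raw`,
#'   `p_adj`, `m`.
#' @export
compare_samples <- function(samples, control, regions,
                            sub_windows = split_sub_windows(spec),
                            spec = window_spec()) {
  if (length(samples) == 0L) stop("empty sample map")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list")
  }
  labels <- vapply(sub_windows, function(s) s$label, character(1))
  m <- length(samples) * length(sub_windows)
  rows <- list()
  libs <- vapply(c(samples, list(.control = control)),
                 function(t) t$library_size, numeric(1))
  if (any(control$norm_target > libs)) {
    warning("norm_target exceeds a library size: normalized counts are ",
            "over-dispersed and the exact test may overstate significance",
            call. = FALSE)
  }
  ctrl_prof <- suppressMessages(aggregate_profile(control, regions, spec))
  for (sn in names(samples)) {
    smp <- samples[[sn]]
    if (!identical(smp$norm_target, control$norm_target)) {
      stop("sample ", sn, " normalized to a different target than the control")
    }
    smp_prof <- suppressMessages(aggregate_profile(smp, regions, spec))
    for (k in seq_along(sub_windows)) {
      sub <- sub_windows[[k]]
      sel <- smp_prof$offsets >= sub$offset_start & smp_prof$offsets < sub$offset_end
      if (!any(sel)) stop("sub-window ", sub$label, " overlaps no bins")
      tab <- suppressWarnings(contingency_table(
        sum(smp_prof$matrix[, sel, drop = FALSE]),
        sum(ctrl_prof$matrix[, sel, drop = FALSE]),
        control$norm_target))
      ft <- fisher_exact(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sn, window = labels[k], a = tab$a, b = tab$b,
        c = tab$c, d = tab$d, odds_ratio = ft$odds_ratio,
        p_raw = ft$p_value, p_adj = NA_real_, m = m)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw, m = m)
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", class(out))
  out
}

#' Write enrichment results as TSV
#'
#' @param results An `enrichment_results` data.frame.
#' @param path Output path.
#' @export
write_enrichment_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
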