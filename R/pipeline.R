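#' Run configuration
#'
#' Collects the analysis parameters shared by the pipeline stages. Defaults
#' are the study's printed parameters: 24-kb windows (half width 12,000 bp),
#' 100-nt bins, 6-kb quantification sub-windows, 10,000 bootstrap resamples,
#' 50,000 random control windows, 10M-read normalization target.
#'
#' @param half_width Window half width in bp.
#' @param bin_width Bin width in bp.
#' @param quant_half_width Quantification sub-window half width in bp.
#' @param n_boot Bootstrap resamples for profile summaries.
#' @param n_random_windows Random control windows to sample.
#' @param norm_target Normalization target library size in reads.
#' @param statistic Profile summary statistic, `"mean"` or `"median"`.
#' @param seed Seed driving random-window sampling and bootstrap resampling.
#' @return A `run_config` list.
#' @export
run_config <- function(half_width = 12000, bin_width = 100,
                       quant_half_width = 6000, n_boot = 10000,
                       n_random_windows = 50000, norm_target = 1e7,
                       statistic = c("mean", "median"), seed = 1) {
  statistic <- match.arg(statistic)
  cfg <- list(half_width = half_width, bin_width = bin_width,
              quant_half_width = quant_half_width, n_boot = n_boot,
              n_random_windows = n_random_windows, norm_target = norm_target,
              statistic = statistic, seed = as.integer(seed))
  # constructing the spec validates the window geometry
  window_spec(cfg$half_width, cfg$bin_width)
  class(cfg) <- "run_config"
  cfg
}

load_run_tracks <- function(sample_beds, genome, config) {
  if (is.null(names(sample_beds)) || any(!nzchar(names(sample_beds)))) {
    stop("sample_beds must be a named vector/list of BED paths")
  }
  tracks <- lapply(names(sample_beds), function(sn) {
    raw <- bin_reads(sample_beds[[sn]], genome, bin_width = config$bin_width,
                     sample_id = sn)
    message("sample ", sn, ": library_size = ", raw$library_size,
            ", skipped = ", raw$n_skipped)
    normalize_track(raw, norm_target = config$norm_target)
  })
  names(tracks) <- names(sample_beds)
  tracks
}

echo_config <- function(config, out_dir, extra = list()) {
  yaml::write_yaml(
    c(unclass(config), extra,
      list(driptrc_version = as.character(utils::packageVersion("driptrc")))),
    file.path(out_dir, "run_config.yaml"))
}

#' Simulate a fixture bundle (pipeline stage)
#'
#' Thin wrapper around [export_fixture()] used by the command-line front-end.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param norm_target Normalization target recorded in the truth table.
#' @return Invisibly, the fixture paths.
#' @export
run_simulate <- function(config, out_dir, norm_target = 1e7) {
  export_fixture(config, out_dir, norm_target = norm_target)
}

#' Metaprofile stage: oriented profiles, bootstrap summaries, ECDFs
#'
#' For every sample, bins and normalizes its reads, aggregates the signal
#' over (i) origin-anchored regions, (ii) center-anchored regions (when
#' present) and (iii) sampled random control windows, writes a per-class
#' bootstrap profile summary TSV (offset, point, ci_low, ci_high), and for
#' the origin class a per-region quantification-window average table and its
#' ECDF.
#'
#' @param sample_beds Named character vector of read BED paths (the control
#'   is just another sample here).
#' @param regions_path Path to the 6-column region table.
#' @param chrom_sizes_path Path to the chrom.sizes file.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return Invisibly, a list of written file paths.
#' @export
run_profile <- function(sample_beds, regions_path, chrom_sizes_path, out_dir,
                        config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  genome <- read_chrom_sizes(chrom_sizes_path)
  regions <- load_regions(regions_path, genome, quiet = TRUE)
  spec <- window_spec(config$half_width, config$bin_width)
  subs <- split_sub_windows(spec, config$quant_half_width)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- load_run_tracks(sample_beds, genome, config)
  random_regions <- sample_random_windows(
    genome, n = config$n_random_windows, width = 2 * config$half_width,
    seed = config$seed)
  class_sets <- list(origin = regions[regions$region_class == "origin_in_gene_body", ],
                     center = regions[regions$region_class == "gene_body_center", ],
                     random = random_regions)
  class_sets <- Filter(function(df) nrow(df) > 0, class_sets)
  written <- character(0)
  for (sn in names(tracks)) {
    for (cls in names(class_sets)) {
      prof <- suppressMessages(aggregate_profile(tracks[[sn]], class_sets[[cls]], spec))
      summ <- summarize_profile(prof, statistic = config$statistic,
                                n_boot = config$n_boot, seed = config$seed)
      p <- file.path(out_dir, paste0("profile_", sn, "_", cls, ".tsv"))
      utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
      if (cls == "origin") {
        wa <- window_average(prof, subs$full_quant)
        p2 <- file.path(out_dir, paste0("window_average_", sn, "_origin.tsv"))
        utils::write.table(wa, p2, sep = "\t", quote = FALSE, row.names = FALSE)
        ec <- ecdf_table(wa$average)
        p3 <- file.path(out_dir, paste0("ecdf_", sn, "_origin.tsv"))
        utils::write.table(ec, p3, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, p2, p3)
      }
    }
  }
  echo_config(config, out_dir,
              extra = list(samples = as.list(sample_beds), stage = "profile"))
  invisible(as.list(written))
}

#' Enrichment stage: Fisher tests over quantification windows
#'
#' Bins and normalizes all samples, then tests every non-control sample
#' against the control over the full quantification window and the HO and CD
#' sub-windows of the origin-anchored regions, Bonferroni-correcting over
#' the batch. Results are written as `enrichment.tsv`.
#'
#' @param sample_beds Named character vector of read BED paths, including the
#'   control.
#' @param control_label Name of the control sample within `sample_beds`.
#' @param regions_path Path to the 6-column region table.
#' @param chrom_sizes_path Path to the chrom.sizes file.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The `enrichment_results` data.frame, invisibly.
#' @export
run_enrichment <- function(sample_beds, control_label, regions_path,
                           chrom_sizes_path, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!(control_label %in% names(sample_beds))) {
    stop("control label '", control_label, "' not among the samples")
  }
  genome <- read_chrom_sizes(chrom_sizes_path)
  regions <- load_regions(regions_path, genome, quiet = TRUE)
  origin <- regions[regions$region_class == "origin_in_gene_body", ]
  if (nrow(origin) == 0L) stop("no origin-class regions to test")
  spec <- window_spec(config$half_width, config$bin_width)
  subs <- split_sub_windows(spec, config$quant_half_width)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- load_run_tracks(sample_beds, genome, config)
  control <- tracks[[control_label]]
  samples <- tracks[names(tracks) != control_label]
  res <- compare_samples(samples, control, origin,
                         sub_windows = subs[c("full_quant", "HO", "CD")],
                         spec = spec)
  write_enrichment_results(res, file.path(out_dir, "enrichment.tsv"))
  echo_config(config, out_dir,
              extra = list(samples = as.list(sample_beds),
                           control = control_label, stage = "test"))
  invisible(res)
}
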