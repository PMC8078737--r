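#' Simulation configuration
#'
#' Parameters of the synthetic DRIP-like dataset: a genome of equal-length
#' chromosomes, non-overlapping transcribed gene bodies split into
#' origin-bearing (anchor = internal replication origin) and origin-free
#' (anchor = gene midpoint) classes, Poisson background coverage per 100-nt
#' bin, and a case sample whose rate is multiplied by `fold_HO` / `fold_CD`
#' in the transcription-oriented head-on / co-directional 6-kb sub-windows of
#' origin-class regions. The control sample is background everywhere.
#'
#' Defaults emulate the study conditions: 727 origin-anchored and 484
#' center-anchored gene bodies, head-on-restricted enrichment in the case
#' sample, and library-size differences between samples handled by
#' normalization. Genome and library sizes are desk-scale (a 320-Mb genome
#' keeps the summed quantification windows a small fraction of the genome,
#' as in the real analysis, while staying fast to simulate).
#'
#' @param n_chroms Number of chromosomes (default 4).
#' @param chrom_length Length of each chromosome in bp (default 8e7).
#' @param n_origin_regions,n_center_regions Region counts per class
#'   (defaults 727 and 484).
#' @param gene_length_range Min/max gene-body length in bp (default
#'   16,000-40,000; must exceed 2 x 6,000 so the sub-windows fit inside the
#'   gene body).
#' @param strand_prob Probability a gene lies on the + strand (default 0.5).
#' @param background_rate Expected reads per 100-nt bin before library
#'   scaling (lambda, default 2).
#' @param fold_HO,fold_CD Multiplicative case-sample enrichment in the HO /
#'   CD sub-window of origin-class regions (defaults 2 and 1: the head-on
#'   significant, co-directional flat contrast).
#' @param sub_half_width Half width of the enriched sub-windows (default
#'   6,000 bp).
#' @param library_size_control,library_size_case Reads per sample after
#'   thinning/inflation (default 5e5 each).
#' @param overdispersion Gamma-mixing shape for an optional negative-
#'   binomial-like noise model; `Inf` (default) gives pure Poisson.
#' @param bin_width Bin width in bp (default 100).
#' @param seed RNG seed for region placement (read seeds are passed to
#'   [simulate_reads()]).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 4, chrom_length = 8e7,
                       n_origin_regions = 727, n_center_regions = 484,
                       gene_length_range = c(16000, 40000),
                       strand_prob = 0.5, background_rate = 2,
                       fold_HO = 2, fold_CD = 1, sub_half_width = 6000,
                       library_size_control = 5e5, library_size_case = 5e5,
                       overdispersion = Inf, bin_width = 100, seed = 1) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_origin_regions = as.integer(n_origin_regions),
              n_center_regions = as.integer(n_center_regions),
              gene_length_range = as.numeric(gene_length_range),
              strand_prob = strand_prob, background_rate = background_rate,
              fold_HO = fold_HO, fold_CD = fold_CD,
              sub_half_width = as.numeric(sub_half_width),
              library_size_control = as.numeric(library_size_control),
              library_size_case = as.numeric(library_size_case),
              overdispersion = overdispersion,
              bin_width = as.numeric(bin_width), seed = as.integer(seed))
  if (cfg$background_rate <= 0) stop("background_rate must be > 0")
  if (cfg$fold_HO < 0 || cfg$fold_CD < 0) stop("folds must be >= 0")
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    stop("gene_length_range must be c(min, max)")
  }
  if (cfg$gene_length_range[1] <= 2 * cfg$sub_half_width) {
    stop("minimum gene length must exceed 2 x sub_half_width (",
         2 * cfg$sub_half_width, " bp) so sub-windows fit inside gene bodies")
  }
  if (cfg$strand_prob < 0 || cfg$strand_prob > 1) stop("strand_prob in [0, 1]")
  if (cfg$library_size_control <= 0 || cfg$library_size_case <= 0) {
    stop("library sizes must be > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome and anchored gene-body regions
#'
#' Places non-overlapping gene bodies uniformly (each chromosome's free space
#' is partitioned into random gaps between the genes assigned to it), assigns
#' strands by `strand_prob`, and anchors: origin-class anchors uniform in the
#' gene interior at least `sub_half_width` bp from both ends, center-class
#' anchors at the midpoint. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (a `genome_layout`), `regions` (a
#'   validated region data.frame) and `config`.
#' @export
simulate_regions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genome <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                            rep(config$chrom_length, config$n_chroms))
    n_total <- config$n_origin_regions + config$n_center_regions
    if (n_total < 1) stop("at least one region is required")
    lens <- round(stats::runif(n_total, config$gene_length_range[1],
                               config$gene_length_range[2]))
    classes <- sample(c(rep("origin_in_gene_body", config$n_origin_regions),
                        rep("gene_body_center", config$n_center_regions)))
    chrom <- sample(genome$chrom_names, n_total, replace = TRUE)
    rows <- vector("list", config$n_chroms)
    for (ci in seq_len(config$n_chroms)) {
      ch <- genome$chrom_names[ci]
      idx <- which(chrom == ch)
      if (!length(idx)) next
      gl <- lens[idx]
      free <- config$chrom_length - sum(gl)
      if (free < length(idx)) {
        stop("genome too small to place ", n_total,
             " non-overlapping gene bodies; increase chrom_length")
      }
      # uniform gaps: break the free space at sorted uniform points
      cuts <- sort(stats::runif(length(idx)))
      gaps <- floor(cuts * free) - c(0, utils::head(floor(cuts * free), -1))
      starts <- cumsum(gaps) + c(0, utils::head(cumsum(gl), -1))
      rows[[ci]] <- data.frame(chrom = ch, gene_start = starts,
                               gene_end = starts + gl,
                               region_class = classes[idx])
    }
    df <- do.call(rbind, rows)
    df$strand <- ifelse(stats::runif(nrow(df)) < config$strand_prob, "+", "-")
    is_origin <- df$region_class == "origin_in_gene_body"
    margin <- config$sub_half_width
    lo <- df$gene_start + margin
    hi <- df$gene_end - margin
    df$anchor <- ifelse(is_origin,
                        lo + floor(stats::runif(nrow(df)) * (hi - lo)),
                        df$gene_start + (df$gene_end - df$gene_start) %/% 2)
    df <- df[c("chrom", "gene_start", "gene_end", "anchor", "strand", "region_class")]
    regions <- validate_regions(df, genome)
    list(genome = genome, regions = regions, config = config)
  })
}

# Per-chromosome expected reads per bin for one sample role, before library
# thinning. This is the generator's ground truth; orientation mirrors the
# pipeline's window convention.
sim_bin_rates <- function(sim, sample_role = c("control", "case")) {
  sample_role <- match.arg(sample_role)
  cfg <- sim$config
  bw <- cfg$bin_width
  nbins <- n_bins_per_chrom(sim$genome, bw)
  rates <- lapply(nbins, function(nb) rep(cfg$background_rate, nb))
  if (sample_role == "case") {
    reg <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ,
                       drop = FALSE]
    q <- cfg$sub_half_width
    for (i in seq_len(nrow(reg))) {
      a0 <- snap_to_bin(reg$anchor[i], bw)
      # oriented [o1, o2) maps to genomic [a0+o1, a0+o2) on "+" and
      # [a0-o2, a0-o1) on "-"
      if (reg$strand[i] == "+") {
        ho <- c(a0 - q, a0); cd <- c(a0, a0 + q)
      } else {
        ho <- c(a0, a0 + q); cd <- c(a0 - q, a0)
      }
      for (blk in list(list(iv = ho, f = cfg$fold_HO),
                       list(iv = cd, f = cfg$fold_CD))) {
        if (blk$f == 1) next
        idx <- seq(blk$iv[1] %/% bw + 1, (blk$iv[2] - 1) %/% bw + 1)
        idx <- idx[idx >= 1 & idx <= nbins[[reg$chrom[i]]]]
        rates[[reg$chrom[i]]][idx] <- cfg$background_rate * blk$f
      }
    }
  }
  rates
}

#' Ground-truth expectations of a simulated dataset
#'
#' Closed-form expected values under the generator: total expected reads per
#' role before thinning, and the expected *normalized* signal per bin in
#' background, HO and CD territory, given a normalization target. After
#' thinning to library size L and normalizing to target T, a bin with Poisson
#' rate r has expected value `r * T / Lambda_total` independent of L.
#'
#' @param sim Output of [simulate_regions()].
#' @param norm_target Normalization target used downstream.
#' @return A list with per-role totals and expected normalized per-bin values.
#' @export
sim_truth <- function(sim, norm_target = 1e7) {
  cfg <- sim$config
  out <- list(config = cfg)
  for (role in c("control", "case")) {
    rates <- sim_bin_rates(sim, role)
    total <- sum(vapply(rates, sum, numeric(1)))
    lam <- cfg$background_rate
    fHO <- if (role == "case") cfg$fold_HO else 1
    fCD <- if (role == "case") cfg$fold_CD else 1
    out[[role]] <- list(
      expected_total_reads = total,
      expected_norm_background = lam * norm_target / total,
      expected_norm_HO = lam * fHO * norm_target / total,
      expected_norm_CD = lam * fCD * norm_target / total)
  }
  out
}

#' Simulate a DRIP-like read set
#'
#' Draws per-bin read counts as Poisson(rate) (optionally gamma-mixed for
#' overdispersion) from the ground-truth rate field of the requested sample
#' role, materializes each read as a `bin_width`-long interval whose 5' end
#' lies in its bin, then thins (sampling without replacement) or inflates
#' (with replacement) the read set to the configured library size.
#'
#' @param sim Output of [simulate_regions()].
#' @param sample_role `"control"` or `"case"`.
#' @param seed RNG seed.
#' @return A read data.frame (`chrom`, `start`, `end`, `strand`) suitable for
#'   [bin_reads()], with attribute `sample_role`.
#' @export
simulate_reads <- function(sim, sample_role = c("control", "case"), seed = NULL) {
  sample_role <- match.arg(sample_role)
  cfg <- sim$config
  lib <- if (sample_role == "case") cfg$library_size_case else cfg$library_size_control
  if (lib <= 0) stop("requested library size must be > 0")
  rates <- sim_bin_rates(sim, sample_role)
  bw <- cfg$bin_width
  with_seed(seed, {
    parts <- lapply(sim$genome$chrom_names, function(ch) {
      r <- rates[[ch]]
      if (is.finite(cfg$overdispersion)) {
        r <- r * stats::rgamma(length(r), shape = cfg$overdispersion,
                               rate = cfg$overdispersion)
      }
      counts <- stats::rpois(length(r), r)
      nz <- which(counts > 0)
      if (!length(nz)) return(NULL)
      data.frame(chrom = ch,
                 bin_start = rep((nz - 1) * bw, counts[nz]))
    })
    df <- do.call(rbind, parts)
    n0 <- if (is.null(df)) 0L else nrow(df)
    if (n0 == 0L) stop("simulation produced no reads; increase background_rate")
    idx <- if (n0 >= lib) sample.int(n0, lib) else sample.int(n0, lib, replace = TRUE)
    df <- df[idx, , drop = FALSE]
    start <- df$bin_start + sample.int(bw, nrow(df), replace = TRUE) - 1
    out <- data.frame(chrom = df$chrom, start = start, end = start + bw,
                      strand = "+")
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sample_role") <- sample_role
    out
  })
}

#' Export a self-contained fixture bundle
#'
#' Writes everything the pipeline consumes into a directory: `chrom.sizes`,
#' the 6-column region table, control and case read BEDs, a ground-truth TSV
#' of expected normalized signal levels, and a YAML echo of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param norm_target Normalization target recorded in the truth table.
#' @return Invisibly, a named list of the file paths plus the simulated
#'   objects (`genome`, `regions`).
#' @export
export_fixture <- function(config, dir, norm_target = 1e7) {
  stopifnot(inherits(config, "sim_config"))
  parent <- dirname(dir)
  if (!dir.exists(parent)) stop("parent of output directory does not exist: ", parent)
  # stage into a scratch directory so a failed run leaves no partial files
  stage <- tempfile("driptrc_fixture_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  sim <- simulate_regions(config)
  reads_control <- simulate_reads(sim, "control", seed = config$seed + 1L)
  reads_case <- simulate_reads(sim, "case", seed = config$seed + 2L)
  files <- c(chrom_sizes = "chrom.sizes", regions = "regions.tsv",
             control = "control.bed", case = "case.bed",
             truth = "truth.tsv", config = "sim_config.yaml")
  paths <- as.list(file.path(stage, files))
  names(paths) <- names(files)
  write_chrom_sizes(sim$genome, paths$chrom_sizes)
  write_regions(sim$regions, paths$regions)
  write_read_bed(reads_control, paths$control)
  write_read_bed(reads_case, paths$case)
  truth <- sim_truth(sim, norm_target = norm_target)
  tt <- do.call(rbind, lapply(c("control", "case"), function(role) {
    tr <- truth[[role]]
    data.frame(sample_role = role,
               expected_total_reads = tr$expected_total_reads,
               expected_norm_background = tr$expected_norm_background,
               expected_norm_HO = tr$expected_norm_HO,
               expected_norm_CD = tr$expected_norm_CD,
               norm_target = norm_target)
  }))
  utils::write.table(tt, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), paths$config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  ok <- file.copy(unlist(paths), file.path(dir, files), overwrite = TRUE)
  if (!all(ok)) stop("failed to move fixture files into ", dir)
  final <- as.list(file.path(dir, files))
  names(final) <- names(files)
  invisible(c(final, list(genome = sim$genome, regions = sim$regions)))
}

write_read_bed <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom,
                    start = format(reads$start, scientific = FALSE, trim = TRUE),
                    end = format(reads$end, scientific = FALSE, trim = TRUE),
                    name = ".", score = 0L, strand = reads$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
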