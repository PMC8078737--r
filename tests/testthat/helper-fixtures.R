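# Shared fixture builders. Everything is generated in code; no data files.

toy_genome <- function(lengths = c(chr1 = 2e6, chr2 = 1.5e6)) {
  genome_layout(names(lengths), lengths)
}

# A valid anchored region row set on toy_genome().
toy_regions <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    gene_start = c(100000, 500000, 200000),
    gene_end = c(140000, 540000, 260000),
    anchor = c(120000, 515000, 230000),
    strand = c("+", "-", "+"),
    region_class = c("origin_in_gene_body", "origin_in_gene_body",
                     "gene_body_center")
  )
}

# Build a normalized track with arbitrary per-chromosome counts; library_size
# chosen so the normalization scale is exactly 1 unless given.
toy_track <- function(genome, counts, norm_target = 1e7,
                      library_size = norm_target) {
  tr <- signal_track(genome, counts, bin_width = 100,
                     library_size = library_size)
  normalize_track(tr, norm_target = norm_target)
}

# Independent brute-force oracle: assign each read 5' end to floor(pos/100).
oracle_bin_counts <- function(reads, genome, bin_width = 100) {
  counts <- lapply(genome$chrom_lengths,
                   function(L) numeric(ceiling(L / bin_width)))
  for (i in seq_len(nrow(reads))) {
    ch <- reads$chrom[i]
    if (!(ch %in% names(counts))) next
    pos <- if (!is.null(reads$strand) && reads$strand[i] == "-") {
      reads$end[i] - 1
    } else {
      reads$start[i]
    }
    idx <- pos %/% bin_width + 1
    counts[[ch]][idx] <- counts[[ch]][idx] + 1
  }
  counts
}

# Independent brute-force oracle for oriented aggregation: a scalar double
# loop over regions and bins, mapping each oriented offset to its genomic bin.
oracle_aggregate <- function(track, regions, half_width = 12000,
                             bin_width = 100) {
  nb <- 2 * half_width / bin_width
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    a0 <- (regions$anchor[r] %/% bin_width) * bin_width
    L <- track$genome$chrom_lengths[[regions$chrom[r]]]
    if (a0 - half_width < 0 || a0 + half_width > L) next
    vals <- numeric(nb)
    for (j in seq_len(nb)) {
      offset <- -half_width + (j - 1) * bin_width
      gstart <- if (regions$strand[r] == "+") {
        a0 + offset
      } else {
        a0 - offset - bin_width
      }
      vals[j] <- track$counts[[regions$chrom[r]]][gstart / bin_width + 1]
    }
    rows[[length(rows) + 1L]] <- vals
  }
  do.call(rbind, rows)
}

# Independent two-sided Fisher oracle: full enumeration of the hypergeometric
# support with the minimum-likelihood rule.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b      # sample row total
  n <- c_ + d     # control row total
  k <- a + c_     # in-window column total
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Small simulated dataset for pipeline-level tests.
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 2, chrom_length = 1e7, n_origin_regions = 60,
         n_center_regions = 40, library_size_control = 1e5,
         library_size_case = 1e5),
    list(...))
  do.call(sim_config, args)
}
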