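test_that("aggregation matches the brute-force loop oracle and inverts minus strands", {
  g <- toy_genome(c(chr1 = 1e5, chr2 = 1e5))
  set.seed(41)
  counts <- list(chr1 = rpois(1000, 3), chr2 = rpois(1000, 3))
  track <- toy_track(g, counts)
  regions <- load_regions(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    gene_start = c(20000, 50000, 30000),
    gene_end = c(45000, 90000, 70000),
    anchor = c(30000, 70000, 50000),
    strand = c("+", "-", "+"),
    region_class = "origin_in_gene_body"), g, quiet = TRUE)
  spec <- window_spec()
  prof <- aggregate_profile(track, regions, spec)
  expect_equal(dim(prof$matrix), c(3L, 240L))
  expect_equal(unname(prof$matrix),
               unname(oracle_aggregate(track, regions)))
  # the minus-strand row is the reversed genomic bin vector
  a0 <- 70000
  genomic <- track$counts$chr1[((a0 - 12000) / 100 + 1):((a0 + 12000) / 100)]
  expect_equal(unname(prof$matrix[2, ]), rev(genomic))
  # a constant field is strand-agnostic
  const <- toy_track(g, list(chr1 = rep(2.5, 1000), chr2 = rep(2.5, 1000)))
  pc <- aggregate_profile(const, regions, spec)
  expect_true(all(pc$matrix == 2.5))
  expect_error(aggregate_profile(track, regions[0, ], spec), "empty region")
})

test_that("out-of-bounds regions are dropped and counted", {
  g <- toy_genome(c(chr1 = 1e6))
  track <- toy_track(g, list(chr1 = rep(1, 10000)))
  regions <- load_regions(data.frame(
    chrom = "chr1", gene_start = c(0, 500000), gene_end = c(30000, 540000),
    anchor = c(5000, 520000), strand = "+",
    region_class = "origin_in_gene_body"), g, quiet = TRUE)
  prof <- suppressMessages(aggregate_profile(track, regions, window_spec()))
  expect_equal(prof$n_dropped, 1L)
  expect_equal(nrow(prof$matrix), 1L)
})

test_that("profile summaries are seeded, degenerate on identical rows, and calibrated", {
  mat <- matrix(rep(c(1, 2, 4), each = 6), nrow = 3, byrow = TRUE)
  prof <- meta_profile("s", paste0("r", 1:3), seq(-300, 200, by = 100), mat)
  s1 <- summarize_profile(prof, n_boot = 200, seed = 7)
  s2 <- summarize_profile(prof, n_boot = 200, seed = 7)
  expect_identical(s1, s2)
  expect_equal(s1$point, rep(mean(c(1, 2, 4)), 6))
  # identical rows -> zero-width band
  same <- meta_profile("s", paste0("r", 1:4), c(-100, 0),
                       matrix(3, nrow = 4, ncol = 2))
  ss <- summarize_profile(same, n_boot = 100, seed = 1)
  expect_true(all(ss$ci_low == 3 & ss$ci_high == 3))
  expect_warning(
    summarize_profile(meta_profile("s", "r1", c(-100, 0),
                                   matrix(1, 1, 2)), n_boot = 10, seed = 1),
    "degenerate")
  # bootstrap band covers the truth (0) at roughly the nominal rate
  set.seed(53)
  noise <- matrix(rnorm(50 * 80), nrow = 50)
  noise_prof <- meta_profile("n", paste0("r", 1:50),
                             seq(-4000, 3900, by = 100), pmax(noise, -1e9))
  sn <- summarize_profile(noise_prof, n_boot = 400, seed = 3)
  coverage <- mean(sn$ci_low <= 0 & sn$ci_high >= 0)
  expect_gt(coverage, 0.85)
  # bands shrink with more regions
  big <- meta_profile("n", paste0("r", 1:200),
                      seq(-4000, 3900, by = 100),
                      matrix(rnorm(200 * 80), nrow = 200))
  sb <- summarize_profile(big, n_boot = 400, seed = 3)
  expect_lt(mean(sb$ci_high - sb$ci_low), mean(sn$ci_high - sn$ci_low))
})

test_that("median summaries use the deterministic lower-interpolation rule", {
  mat <- matrix(c(1, 2, 3, 10,
                  5, 6, 7, 8), ncol = 2)  # columns: (1,2,3,10) and (5,6,7,8)
  prof <- meta_profile("s", paste0("r", 1:4), c(0, 100), mat)
  s <- summarize_profile(prof, statistic = "median", n_boot = 10, seed = 1)
  expect_equal(s$point, c(2, 6))  # lower middle of even-count columns
})

test_that("window averages match the slice-and-mean oracle", {
  offsets <- seq(-12000, 11900, by = 100)
  set.seed(61)
  mat <- matrix(runif(5 * 240, 0, 10), nrow = 5)
  prof <- meta_profile("s", paste0("r", 1:5), offsets, mat)
  subs <- split_sub_windows(window_spec())
  for (lab in names(subs)) {
    sub <- subs[[lab]]
    got <- window_average(prof, sub)$average
    want <- sapply(seq_len(5), function(r) {
      sel <- offsets >= sub$offset_start & offsets < sub$offset_end
      mean(mat[r, sel])
    })
    expect_equal(got, want, info = lab)
  }
  # partition arithmetic: full average is the mean of the two halves
  ho <- window_average(prof, subs$HO)$average
  cd <- window_average(prof, subs$CD)$average
  fq <- window_average(prof, subs$full_quant)$average
  expect_equal(fq, (ho + cd) / 2)
  # constant matrix gives the constant under any sub-window
  cprof <- meta_profile("s", paste0("r", 1:5), offsets,
                        matrix(4.2, nrow = 5, ncol = 240))
  expect_true(all(window_average(cprof, subs$HO)$average == 4.2))
  expect_error(window_average(prof, sub_window("x", 50000, 60000)),
               "overlaps no bins")
})

test_that("mirror-symmetric signal makes mean profiles strand-flip invariant", {
  g <- toy_genome(c(chr1 = 2e5))
  spec <- window_spec(half_width = 2000)
  # signal symmetric about each anchor: value depends on |genomic - anchor|
  anchors <- c(50000, 120000)
  v <- rep(0, 2000)
  for (a in anchors) {
    bins <- ((a - 2000) / 100 + 1):((a + 2000) / 100)
    dist <- abs(seq(-1950, 1950, by = 100))
    v[bins] <- v[bins] + exp(-dist / 500)
  }
  track <- toy_track(g, list(chr1 = v))
  mk_regions <- function(strand) load_regions(data.frame(
    chrom = "chr1", gene_start = anchors - 10000, gene_end = anchors + 10000,
    anchor = anchors, strand = strand,
    region_class = "origin_in_gene_body"), g, quiet = TRUE)
  plus <- aggregate_profile(track, mk_regions("+"), spec)
  minus <- aggregate_profile(track, mk_regions("-"), spec)
  expect_equal(colMeans(plus$matrix), colMeans(minus$matrix))
})

test_that("ecdf tables follow the step-function definition", {
  tab <- ecdf_table(c(1, 2, 3))
  expect_equal(tab$cum_freq[tab$value == 2], 2 / 3)
  expect_equal(max(tab$cum_freq), 1)
  same <- ecdf_table(rep(5, 10))
  expect_equal(nrow(same), 1L)
  expect_equal(same$cum_freq, 1)
  expect_error(ecdf_table(numeric(0)), "empty")
  # uniform draws stay close to the uniform CDF (Kolmogorov distance)
  set.seed(71)
  u <- runif(1000)
  tab <- ecdf_table(u)
  ks <- max(abs(tab$cum_freq - tab$value))
  expect_lt(ks, 1.63 / sqrt(1000))  # 1% critical value
})
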