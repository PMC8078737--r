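test_that("simulated regions honour counts, placement rules and determinism", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_regions(cfg)
  cc <- table(sim$regions$region_class)
  expect_equal(unname(cc["origin_in_gene_body"]), 60, ignore_attr = TRUE)
  expect_equal(unname(cc["gene_body_center"]), 40, ignore_attr = TRUE)
  # deterministic per seed
  sim2 <- simulate_regions(cfg)
  expect_identical(sim$regions, sim2$regions)
  # origin anchors keep a 6-kb margin from both gene ends
  org <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ]
  expect_true(all(org$anchor - org$gene_start >= 6000))
  expect_true(all(org$gene_end - org$anchor > 6000))
  # center anchors sit at the midpoint
  ctr <- sim$regions[sim$regions$region_class == "gene_body_center", ]
  expect_true(all(ctr$anchor ==
                    ctr$gene_start + (ctr$gene_end - ctr$gene_start) %/% 2))
  # gene bodies never overlap within a chromosome
  for (ch in sim$genome$chrom_names) {
    r <- sim$regions[sim$regions$chrom == ch, ]
    r <- r[order(r$gene_start), ]
    if (nrow(r) > 1) expect_true(all(diff_ok <- r$gene_start[-1] >= r$gene_end[-nrow(r)]))
  }
  # an impossible request errors
  expect_error(simulate_regions(
    sim_config(n_chroms = 1, chrom_length = 1e5, n_origin_regions = 50,
               n_center_regions = 0)), "too small")
})

test_that("simulated region tables round-trip through the loader", {
  cfg <- small_sim_config(seed = 6)
  sim <- simulate_regions(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regions(sim$regions, path)
  back <- load_regions(path, sim$genome, quiet = TRUE)
  expect_equal(nrow(back), nrow(sim$regions))
  expect_equal(back$anchor, sim$regions$anchor)
  expect_equal(attr(back, "class_counts")[["origin_in_gene_body"]], 60L)
})

test_that("null simulations are exchangeable between case and control", {
  for (seed in c(11, 12, 13)) {
    cfg <- small_sim_config(fold_HO = 1, fold_CD = 1, seed = seed)
    sim <- simulate_regions(cfg)
    ctl <- normalize_track(bin_reads(simulate_reads(sim, "control", seed = seed + 100),
                                     sim$genome), norm_target = 1e5)
    cas <- normalize_track(bin_reads(simulate_reads(sim, "case", seed = seed + 200),
                                     sim$genome), norm_target = 1e5)
    org <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ]
    sub <- split_sub_windows(window_spec())$HO
    wc <- window_average(aggregate_profile(ctl, org), sub)$average
    wa <- window_average(aggregate_profile(cas, org), sub)$average
    expect_gt(t.test(wa, wc)$p.value, 0.01)
  }
})

test_that("injected head-on fold is recovered from window-average ratios", {
  ratios <- sapply(1:10, function(k) {
    cfg <- small_sim_config(fold_HO = 3, seed = 300 + k)
    sim <- simulate_regions(cfg)
    ctl <- normalize_track(bin_reads(simulate_reads(sim, "control", seed = 400 + k),
                                     sim$genome), norm_target = 1e5)
    cas <- normalize_track(bin_reads(simulate_reads(sim, "case", seed = 500 + k),
                                     sim$genome), norm_target = 1e5)
    org <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ]
    sub <- split_sub_windows(window_spec())$HO
    mean(window_average(aggregate_profile(cas, org), sub)$average) /
      mean(window_average(aggregate_profile(ctl, org), sub)$average)
  })
  # thinning renormalizes the case library, attenuating the realized fold by
  # 1 + q_HO (fold - 1) where q_HO is the head-on share of the library
  truth <- sim_truth(simulate_regions(small_sim_config(fold_HO = 3, seed = 301)))
  expected <- truth$case$expected_norm_HO / truth$control$expected_norm_HO
  expect_lt(abs(mean(ratios) - expected) / expected, 0.10)
  expect_gt(mean(ratios), 2.5)
})

test_that("strand flips mirror the enriched territory around each anchor", {
  cfg <- small_sim_config(fold_HO = 4, seed = 21)
  sim <- simulate_regions(cfg)
  flipped <- sim
  flipped$regions$strand <- ifelse(sim$regions$strand == "+", "-", "+")
  r1 <- driptrc:::sim_bin_rates(sim, "case")
  r2 <- driptrc:::sim_bin_rates(flipped, "case")
  org <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ]
  for (i in sample(nrow(org), 10)) {
    a0 <- (org$anchor[i] %/% 100) * 100
    bins <- ((a0 - 6000) / 100 + 1):((a0 + 6000) / 100)
    v1 <- r1[[org$chrom[i]]][bins]
    v2 <- r2[[org$chrom[i]]][bins]
    expect_equal(v1, rev(v2))
    expect_false(isTRUE(all.equal(v1, v2)))  # enrichment is one-sided
  }
})

test_that("fixture export is complete, loadable and atomic on failure", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(n_origin_regions = 30, n_center_regions = 10,
                          library_size_control = 2e4, library_size_case = 2e4,
                          seed = 31)
  fx <- export_fixture(cfg, file.path(dir, "fx"), norm_target = 2e4)
  for (f in c("chrom_sizes", "regions", "control", "case", "truth", "config")) {
    expect_true(file.exists(fx[[f]]), info = f)
  }
  g <- read_chrom_sizes(fx$chrom_sizes)
  regions <- load_regions(fx$regions, g, quiet = TRUE)
  expect_equal(sum(attr(regions, "class_counts")), 40L)
  # identical seeds give byte-identical fixtures
  fx2 <- export_fixture(cfg, file.path(dir, "fx2"), norm_target = 2e4)
  for (f in c("chrom_sizes", "regions", "control", "case", "truth")) {
    expect_identical(readLines(fx[[f]]), readLines(fx2[[f]]), info = f)
  }
  # unwritable destination: error, no partial output
  expect_error(export_fixture(cfg, file.path(dir, "nope", "deep", "fx")),
               "does not exist")
  expect_false(dir.exists(file.path(dir, "nope")))
})

test_that("pipeline recovers the truth table's expected window averages", {
  cfg <- small_sim_config(background_rate = 5, fold_HO = 2, seed = 41,
                          n_origin_regions = 200, n_center_regions = 0,
                          chrom_length = 2e7,
                          library_size_control = 5e5, library_size_case = 5e5)
  sim <- simulate_regions(cfg)
  truth <- sim_truth(sim, norm_target = 5e5)
  cas <- normalize_track(bin_reads(simulate_reads(sim, "case", seed = 42),
                                   sim$genome), norm_target = 5e5)
  org <- sim$regions[sim$regions$region_class == "origin_in_gene_body", ]
  sub <- split_sub_windows(window_spec())$HO
  got <- mean(window_average(aggregate_profile(cas, org), sub)$average)
  expect_lt(abs(got - truth$case$expected_norm_HO) /
              truth$case$expected_norm_HO, 0.05)
})
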