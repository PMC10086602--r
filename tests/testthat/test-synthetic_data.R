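small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chrom_spec = data.frame(chrom = c("chrA", "chrB"),
                                     length = c(1e6, 1e6)),
             per_type = data.frame(type_code = c(1L, 6L),
                                   n_elements = c(40L, 40L),
                                   length_scale = c(300, 800)),
             traits = data.frame(trait_id = c("q", "d"),
                                 category = c("quantitative", "disease"),
                                 sig_mode = c("pvalue", "log10bf"),
                                 n_loci = c(30L, 30L),
                                 members_mean = c(2, 2)),
             ...)
}

test_that("element simulation is a pure function of the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg(seed = 9)
  simulate_psi_elements(cfg, dir = d1)
  simulate_psi_elements(cfg, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a different seed gives different elements
  e1 <- simulate_psi_elements(small_cfg(seed = 9))$elements
  e3 <- simulate_psi_elements(small_cfg(seed = 10))$elements
  expect_false(identical(e1$start, e3$start))
})

test_that("chromosome weights steer element placement", {
  cfg <- small_cfg(seed = 2, chrom_weights = matrix(c(1, 0, 1, 0), 2,
                                                    byrow = TRUE))
  el <- simulate_psi_elements(cfg)$elements
  expect_true(all(el$chrom == "chrA"))
})

test_that("element lengths track the configured log-normal median", {
  cfg <- sim_config(seed = 3,
                    chrom_spec = data.frame(chrom = "chr1", length = 1e7),
                    per_type = data.frame(type_code = 1L, n_elements = 5000L,
                                          length_scale = 500))
  el <- simulate_psi_elements(cfg)$elements
  med <- median(el$end - el$start)
  expect_gt(med, 500 * 0.9)
  expect_lt(med, 500 * 1.1)
  # elements respect chromosome bounds and the 10 bp floor
  expect_true(all(el$start >= 0 & el$end <= 1e7))
  expect_true(all(el$end - el$start >= 10))
})

test_that("disease leads land in regions at the theta-odds rate", {
  theta <- 3
  cfg <- sim_config(seed = 4,
                    chrom_spec = data.frame(chrom = "chr1", length = 5e6),
                    per_type = data.frame(type_code = 1L, n_elements = 300L,
                                          length_scale = 800),
                    traits = data.frame(trait_id = "d", category = "disease",
                                        sig_mode = "pvalue", n_loci = 2000L,
                                        members_mean = 0),
                    theta = theta, decoy_rate = 0)
  sim <- simulate_psi_elements(cfg)
  regions <- merge_into_regions(sim$elements)
  gw <- simulate_gwas(cfg, regions, sim$genome)
  cvg <- gw$truth$realized_coverage
  expected <- theta * cvg / (theta * cvg + 1 - cvg)
  frac <- mean(unlist(gw$truth$lead_in_region))
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("theta = 1 collapses disease placement to coverage", {
  cfg <- small_cfg(seed = 5, theta = 1)
  sim <- simulate_psi_elements(cfg)
  regions <- merge_into_regions(sim$elements)
  gw <- simulate_gwas(cfg, regions, sim$genome)
  cvg <- gw$truth$realized_coverage
  # both categories share the same in-region probability c; check the
  # pooled fraction against it at simulation scale
  frac <- mean(unlist(gw$truth$lead_in_region))
  expect_lt(abs(frac - cvg), 4 * sqrt(cvg * (1 - cvg) / 60))
})

test_that("simulated GWAS round-trips: truth flags match map_variants", {
  cfg <- small_cfg(seed = 6)
  sim <- simulate_psi_elements(cfg)
  regions <- merge_into_regions(sim$elements)
  gw <- simulate_gwas(cfg, regions, sim$genome)
  leads <- gw$records[!is.na(gw$records$lead_id) &
                      gw$records$variant_id == gw$records$lead_id, ]
  leads$variant_key <- leads$variant_id
  mapped <- map_variants(leads, regions)
  truth <- unlist(gw$truth$lead_in_region)
  observed <- stats::setNames(leads$variant_id %in% mapped$variant_id,
                              leads$variant_id)
  expect_equal(observed[names(truth)], truth == TRUE,
               ignore_attr = FALSE)
  # scores respect the significance filters by construction
  sig <- gw$records
  sig$variant_key <- sig$variant_id
  expect_equal(nrow(filter_significant(sig)), nrow(sig))
})

test_that("decoys never change locus counts when singleton mode is off", {
  cfg_d <- small_cfg(seed = 8, decoy_rate = 0.3)
  cfg_0 <- small_cfg(seed = 8, decoy_rate = 0)
  for (cfg in list(cfg_d, cfg_0)) {
    sim <- simulate_psi_elements(cfg)
    regions <- merge_into_regions(sim$elements)
    gw <- simulate_gwas(cfg, regions, sim$genome)
    sig <- gw$records; sig$variant_key <- sig$variant_id
    mapped <- map_variants(sig, regions)
    a <- suppressWarnings(assign_blocks(sig, gw$ld))
    loci <- summarize_loci(a, mapped)
    if (identical(cfg, cfg_d)) n_with <- nrow(loci) else n_without <- nrow(loci)
  }
  expect_equal(n_with, n_without)
})

test_that("the fixture bundle is complete and the pipeline consumes it", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 12)
  fx <- end_to_end_fixture(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "chrom.sizes")))
  expect_true(file.exists(file.path(dir, "ld.tsv")))
  expect_true(file.exists(file.path(dir, "sim_truth.json")))
  report <- run_pipeline(dir)
  expect_s3_class(report, "psimap_report")
  expect_equal(report$elements$n_elements, 80)
  expect_gt(report$gwas$n_significant_records, 0)
})
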