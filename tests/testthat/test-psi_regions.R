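test_that("read_psi_bed parses valid rows and rejects malformed ones", {
  genome <- genome_table(c("chr1", "chr2"), c(1e6, 5e5))
  f <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr2\t0\t50\tname"))
  el <- read_psi_bed(f, 1, genome)
  expect_equal(nrow(el), 2)
  expect_equal(el$chrom, c("chr1", "chr2"))
  expect_equal(el$start, c(100, 0))
  expect_equal(el$end, c(200, 50))
  expect_equal(el$type_code, c(1L, 1L))

  bad <- withr::local_tempfile(lines = "chr1\t200\t100")
  expect_error(read_psi_bed(bad, 1, genome), "start.*>= end")
  short <- withr::local_tempfile(lines = c("chr1\t1\t2", "chr1\t5"))
  expect_error(read_psi_bed(short, 1, genome), "line 2")
  offgenome <- withr::local_tempfile(lines = "chrZ\t1\t2")
  expect_error(read_psi_bed(offgenome, 1, genome), "chrZ")
  toolong <- withr::local_tempfile(lines = "chr2\t0\t600000")
  expect_error(read_psi_bed(toolong, 1, genome), "exceeds")
  expect_error(read_psi_bed(f, 12, genome), "1..9")
})

test_that("a nine-file element set totals the sum of per-file counts", {
  # per-type counts mirroring the heterogeneity of real element catalogs
  counts <- c(2737, 63, 1000, 1488, 31, 11874, 131, 524, 1919)
  genome <- genome_table("chr1", 5e7)
  set.seed(42)
  dir <- withr::local_tempdir()
  paths <- character(9)
  for (k in 1:9) {
    start <- sort(sample.int(4e7, counts[k]))
    paths[k] <- file.path(dir, sprintf("t%d.bed", k))
    writeLines(sprintf("chr1\t%d\t%d", start, start + 100), paths[k])
  }
  el <- read_psi_elements(stats::setNames(paths, 1:9), genome)
  expect_equal(nrow(el), 19767)  # sum of the nine catalog sizes
  expect_equal(as.integer(table(el$type_code)), counts)
})

test_that("merging joins overlapping elements but not abutting ones", {
  r <- merge_into_regions(make_elements("chr1", c(100, 150), c(200, 250)))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100)
  expect_equal(r$end, 250)
  expect_true(r$multi_element)
  expect_equal(r$element_ids[[1]], c("e001", "e002"))

  r2 <- merge_into_regions(make_elements("chr1", c(100, 200), c(200, 300)))
  expect_equal(nrow(r2), 2)
  expect_false(any(r2$multi_element))

  expect_equal(nrow(merge_into_regions(make_elements(character(0),
                                                     numeric(0), numeric(0)))), 0)
})

test_that("merged regions match the base-array union oracle on random sets", {
  set.seed(101)
  for (rep in 1:25) {
    el <- random_elements(500, L = 1e6, max_len = 2000)
    r <- merge_into_regions(el)
    orc <- oracle_merge(el, list(chrT = 1e6))
    expect_equal(r$start, orc$start)
    expect_equal(r$end, orc$end)
    # total merged length equals union length from the oracle
    expect_equal(sum(r$end - r$start), sum(orc$end - orc$start))
  }
})

test_that("merging agrees with IRanges::reduce as an independent cross-check", {
  set.seed(77)
  el <- random_elements(800, L = 5e5, max_len = 1500)
  r <- merge_into_regions(el)
  ir <- IRanges::reduce(IRanges::IRanges(start = el$start + 1, end = el$end))
  expect_equal(r$start, IRanges::start(ir) - 1)
  expect_equal(r$end, IRanges::end(ir))
})

test_that("merging is idempotent and conserves element accounting", {
  set.seed(7)
  el <- random_elements(300, L = 50000, max_len = 500)
  r <- merge_into_regions(el)
  # feed regions back in as pseudo-elements: nothing merges further
  as_el <- make_elements(r$chrom, r$start, r$end,
                         ids = sprintf("re%04d", seq_len(nrow(r))))
  r2 <- merge_into_regions(as_el)
  expect_equal(r2$start, r$start)
  expect_equal(r2$end, r$end)
  # sum over regions of (n_elements - 1) = n_elements - n_regions
  expect_equal(sum(r$n_elements - 1L), nrow(el) - nrow(r))
  # union length never exceeds summed element lengths
  expect_lte(sum(r$end - r$start), sum(el$end - el$start))
})

test_that("regions carry type sets and the regulatory flag", {
  el <- rbind(make_elements("chr1", 100, 200, type_code = 1L, ids = "a"),
              make_elements("chr1", 150, 300, type_code = 6L, ids = "b"),
              make_elements("chr1", 1000, 1100, type_code = 6L, ids = "c"),
              make_elements("chr1", 2000, 2100, type_code = 7L, ids = "d"))
  r <- merge_into_regions(el)
  expect_equal(nrow(r), 3)
  expect_equal(r$type_set[[1]], c(1L, 6L))
  expect_true(r$regulatory[1])    # contains a regulatory type
  expect_false(r$regulatory[2])   # hsInsert only
  expect_false(r$regulatory[3])   # psTU only
})

test_that("region summary reports totals, means and coverage", {
  genome <- genome_table("chr1", 1000)
  r <- merge_into_regions(make_elements("chr1", 0, 100))
  s <- summarize_regions(r, genome)
  expect_equal(s$n_regions, 1)
  expect_equal(s$total_bp, 100)
  expect_equal(s$genome_coverage, 0.10)

  set.seed(5)
  el <- random_elements(400, L = 20000, max_len = 300)
  r <- merge_into_regions(el)
  g2 <- genome_table("chrT", 20000)
  s2 <- summarize_regions(r, g2)
  orc <- oracle_merge(el, list(chrT = 20000))
  expect_equal(s2$total_bp, sum(orc$end - orc$start))
  expect_equal(sum(s2$per_chrom$covered_bp), s2$total_bp)
  expect_equal(s2$mean_bp, round_half_up(s2$total_bp / s2$n_regions, 1))
  expect_equal(s2$mean_bp_trunc, trunc(s2$total_bp / s2$n_regions))
  expect_error(summarize_regions(r, genome_table("chrX", 100)), "missing")
})

test_that("mean region length uses both 1-decimal and truncated conventions", {
  # aggregate arithmetic as printed in catalog summaries:
  # 24,708,805 bp over 19,473 regions
  expect_equal(round_half_up(24708805 / 19473, 1), 1268.9)
  expect_equal(trunc(24708805 / 19473), 1268)
})

test_that("chromosome distribution test matches hand-computed values", {
  g <- genome_table(c("c1", "c2"), c(100, 100))
  r_even <- make_elements(rep(c("c1", "c2"), each = 10),
                          rep(seq(0, 90, 10), 2), rep(seq(5, 95, 10), 2))
  res <- chisq_chromosome_distribution(merge_into_regions(r_even), g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  r_skew <- make_elements(rep(c("c1", "c2"), c(5, 15)),
                          c(seq(0, 80, 20), seq(0, 84, 6)),
                          c(seq(0, 80, 20), seq(0, 84, 6)) + 2)
  res2 <- chisq_chromosome_distribution(merge_into_regions(r_skew), g)
  # hand evaluation: E = (10, 10); (5-10)^2/10 + (15-10)^2/10 = 5
  expect_equal(res2$statistic, 5.0)
  expect_equal(res2$df, 1)
  expect_equal(res2$p, stats::pchisq(5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res2$p, 4), 0.0253)
})

test_that("goodness-of-fit statistic is invariant to chromosome order", {
  set.seed(13)
  g <- genome_table(c("a", "b", "c"), c(5000, 3000, 2000))
  el <- make_elements(sample(c("a", "b", "c"), 60, replace = TRUE,
                             prob = c(0.6, 0.3, 0.1)),
                      start = sample.int(1500, 60), end = 0)
  el$end <- el$start + 3
  r <- merge_into_regions(el)
  res1 <- chisq_chromosome_distribution(r, g)
  res2 <- chisq_chromosome_distribution(r, g[c(3, 1, 2), ])
  expect_equal(res1$statistic, res2$statistic)
  expect_equal(res1$p, res2$p)
})

test_that("regions round-trip through the BED writer", {
  el <- rbind(make_elements("chr1", c(10, 50), c(40, 90), type_code = 2L),
              make_elements("chr2", 5, 25, type_code = 6L, ids = "x"))
  r <- merge_into_regions(el)
  f <- withr::local_tempfile()
  write_regions_bed(r, f)
  back <- read.delim(f)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_equal(as.character(back$type_set), c("2", "2", "6"))
  expect_equal(back$regulatory, c(TRUE, TRUE, FALSE))
})
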