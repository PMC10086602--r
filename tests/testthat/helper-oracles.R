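# Independent oracles used across the suite. These deliberately use naive
# algorithms (base arrays, all-pairs scans, closed forms) so they share no
# code path with the implementation they check.

# Base-array union oracle: mark every covered base on an array and extract
# maximal runs. The array holds two slots per base boundary so that
# half-open semantics survive: interval [s, e) marks slots 2s+1 .. 2e-1,
# hence abutting intervals ([a,b) and [b,c)) leave slot 2b unmarked and
# stay separate runs, while any shared base joins them. Chromosome lengths
# must be small enough to allocate.
oracle_merge <- function(elements, chrom_lengths) {
  out <- list()
  for (cc in sort(unique(elements$chrom))) {
    L <- chrom_lengths[[cc]]
    covered <- logical(2 * L)
    el <- elements[elements$chrom == cc, , drop = FALSE]
    for (i in seq_len(nrow(el)))
      covered[(2 * el$start[i] + 1):(2 * el$end[i] - 1)] <- TRUE
    r <- rle(covered)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1
    keep <- r$values
    if (any(keep))
      out[[cc]] <- data.frame(chrom = cc,
                              start = (run_start[keep] - 1) / 2,
                              end = (run_end[keep] + 1) / 2,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  rownames(res) <- NULL
  res
}

# All-pairs variant-to-region scan (1-based pos vs 0-based half-open region)
oracle_map <- function(records, regions) {
  hits <- integer(0)
  region_of <- character(0)
  for (i in seq_len(nrow(records))) {
    for (j in seq_len(nrow(regions))) {
      if (records$chrom[i] == regions$chrom[j] &&
          records$pos[i] - 1 >= regions$start[j] &&
          records$pos[i] - 1 < regions$end[j]) {
        hits <- c(hits, i)
        region_of <- c(region_of, regions$region_id[j])
      }
    }
  }
  list(idx = hits, region_id = region_of)
}

# Textbook closed forms for the 2x2 chi-square statistic
chisq2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

chisq2x2_yates <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * max(0, abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Small helpers to build fixtures in code
make_elements <- function(chrom, start, end, type_code = 1L,
                          ids = sprintf("e%03d", seq_along(start))) {
  data.frame(element_id = ids,
             type_code = rep(as.integer(type_code), length.out = length(start)),
             chrom = chrom, start = start, end = end,
             source_label = rep("test", length.out = length(start)),
             stringsAsFactors = FALSE)
}

make_records <- function(chrom, pos, trait_id = "t1",
                         category = "quantitative", sig_mode = "pvalue",
                         score = 1e-10, lead_id = NA_character_,
                         variant_id = sprintf("v%04d", seq_along(pos))) {
  data.frame(variant_id = variant_id, variant_key = variant_id,
             chrom = chrom, pos = pos, trait_id = trait_id,
             category = category, sig_mode = sig_mode, score = score,
             lead_id = lead_id, stringsAsFactors = FALSE)
}

random_elements <- function(n, chrom = "chrT", L = 10000, max_len = 400) {
  start <- floor(runif(n, 0, L - max_len))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  make_elements(chrom, start, pmin(start + len, L),
                type_code = sample(1:9, n, replace = TRUE))
}
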