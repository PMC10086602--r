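# Seeded synthetic generator: toy genome, nine PSI element sets with
# heterogeneous counts and length scales, and GWAS summary statistics with
# lead-variant LD blocks and a controllable enrichment of disease loci
# inside PSI regions. All outputs are a pure function of the config.

#' Build a simulation configuration
#'
#' Defaults describe a small five-chromosome toy genome (2 Mb each) with
#' ~600 elements whose per-type counts and median lengths are scaled from
#' the relative abundances and per-element length scales of the nine
#' published element classes, and four GWAS traits (two quantitative, two
#' disease; one disease trait scored by log10 Bayes factor to exercise both
#' significance modes). `theta` is the odds multiplier for a disease-trait
#' lead landing inside a PSI region relative to coverage-proportional
#' placement: with realized coverage c, disease leads land in-region with
#' probability theta*c / (theta*c + 1 - c); quantitative leads with
#' probability c.
#'
#' @param seed integer seed; every downstream draw derives from it
#' @param chrom_spec data.frame (`chrom`, `length`)
#' @param per_type data.frame (`type_code`, `n_elements`, `length_scale`);
#'   `length_scale` is the log-normal median element length in bp
#' @param chrom_weights optional matrix (9 x n_chrom) of per-type placement
#'   weights; default places elements proportional to chromosome length
#' @param traits data.frame (`trait_id`, `category`, `sig_mode`, `n_loci`,
#'   `members_mean`)
#' @param theta disease-lead enrichment odds multiplier (>= 0)
#' @param block_halfwidth half-width of an LD block in bp (members drawn
#'   within +/- this of the lead)
#' @param decoy_rate fraction of extra significant variants with r2 <= 0.8
#'   to every lead (excluded from loci)
#' @param length_sdlog log-normal sdlog for element lengths
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       chrom_spec = data.frame(
                         chrom = paste0("chr", 1:5),
                         length = rep(2e6, 5)),
                       per_type = data.frame(
                         type_code = 1:9,
                         n_elements = c(83L, 2L, 30L, 45L, 1L, 360L, 4L, 16L, 58L),
                         length_scale = c(250, 400, 200, 3300, 800, 850,
                                          3400, 330, 4200)),
                       chrom_weights = NULL,
                       traits = data.frame(
                         trait_id = c("q1", "q2", "d1", "d2"),
                         category = c("quantitative", "quantitative",
                                      "disease", "disease"),
                         sig_mode = c("pvalue", "pvalue", "pvalue", "log10bf"),
                         n_loci = rep(40L, 4),
                         members_mean = rep(3, 4)),
                       theta = 2,
                       block_halfwidth = 25000,
                       decoy_rate = 0.1,
                       length_sdlog = 0.6) {
  stopifnot(theta >= 0, all(per_type$n_elements >= 0),
            all(per_type$type_code %in% 1:9),
            all(traits$n_loci >= 0), decoy_rate >= 0,
            all(traits$category %in% c("quantitative", "disease")),
        all(traits$sig_mode %in% c("pvalue", "log10bf")))
  if (!is.null(chrom_weights)) {
    stopifnot(nrow(chrom_weights) == nrow(per_type),
              ncol(chrom_weights) == nrow(chrom_spec),
              all(chrom_weights >= 0),
              all(abs(rowSums(chrom_weights) - 1) < 1e-8))
  }
  structure(list(seed = as.integer(seed), chrom_spec = chrom_spec,
                 per_type = per_type, chrom_weights = chrom_weights,
                 traits = traits, theta = theta,
                 block_halfwidth = block_halfwidth, decoy_rate = decoy_rate,
                 length_sdlog = length_sdlog),
            class = "sim_config")
}

#' Simulate the nine PSI element sets
#'
#' Per type, element lengths are log-normal with the configured median
#' (floored at 10 bp), chromosomes drawn per the type's weights, starts
#' uniform along the chromosome. Deterministic given the config seed. When
#' `dir` is given, writes `chrom.sizes` and one `psi_type<k>.bed` per type.
#'
#' @param config a `sim_config`
#' @param dir optional output directory
#' @return list: `genome` (a `genome_table`), `elements` (element
#'   data.frame), `paths` (written files, if any)
#' @export
simulate_psi_elements <- function(config, dir = NULL) {
  set.seed(config$seed)
  genome <- genome_table(config$chrom_spec$chrom, config$chrom_spec$length)
  w <- config$chrom_weights
  if (is.null(w)) {
    w <- matrix(rep(genome$length / sum(genome$length),
                    each = nrow(config$per_type)),
                nrow = nrow(config$per_type))
  }
  out <- vector("list", nrow(config$per_type))
  for (k in seq_len(nrow(config$per_type))) {
    tc <- config$per_type$type_code[k]
    n <- config$per_type$n_elements[k]
    if (n == 0L) { out[[k]] <- empty_elements(); next }
    len <- pmax(10, round(stats::rlnorm(n, log(config$per_type$length_scale[k]),
                                        config$length_sdlog)))
    ci <- sample.int(nrow(genome), n, replace = TRUE, prob = w[k, ])
    L <- genome$length[ci]
    for (i in seq_len(n)) {
      attempts <- 0
      while (len[i] >= L[i]) {
        attempts <- attempts + 1
        if (attempts > 100)
          stop("element of type ", tc, " cannot fit on chromosome ",
               genome$chrom[ci[i]], " after 100 attempts")
        len[i] <- max(10, round(stats::rlnorm(1,
          log(config$per_type$length_scale[k]), config$length_sdlog)))
      }
    }
    start <- floor(stats::runif(n, 0, L - len))
    out[[k]] <- data.frame(
      element_id = sprintf("t%d_e%05d", tc, seq_len(n)),
      type_code = as.integer(tc),
      chrom = genome$chrom[ci], start = start, end = start + len,
      source_label = sprintf("sim_type%d", tc),
      stringsAsFactors = FALSE
    )
  }
  elements <- do.call(rbind, out)
  rownames(elements) <- NULL
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cs <- file.path(dir, "chrom.sizes")
    writeLines(sprintf("%s\t%d", genome$chrom, genome$length), cs)
    beds <- character(nrow(config$per_type))
    for (k in seq_len(nrow(config$per_type))) {
      tc <- config$per_type$type_code[k]
      beds[k] <- file.path(dir, sprintf("psi_type%d.bed", tc))
      el <- elements[elements$type_code == tc, , drop = FALSE]
      writeLines(sprintf("%s\t%d\t%d\t%s", el$chrom, el$start, el$end,
                         el$element_id), beds[k])
    }
    paths <- list(chrom_sizes = cs,
                  beds = stats::setNames(beds, config$per_type$type_code))
  }
  list(genome = genome, elements = elements, paths = paths)
}

# sample one 1-based position inside the merged regions (width-weighted)
sample_in_region <- function(regions, n) {
  widths <- regions$end - regions$start
  ri <- sample.int(nrow(regions), n, replace = TRUE, prob = widths)
  off <- floor(stats::runif(n, 0, widths[ri]))
  data.frame(chrom = regions$chrom[ri],
             pos = regions$start[ri] + off + 1,  # 1-based
             stringsAsFactors = FALSE)
}

# TRUE when the 1-based position lies inside some region
pos_in_regions <- function(chrom, pos, regions) {
  res <- logical(length(pos))
  for (cc in unique(chrom)) {
    ridx <- which(regions$chrom == cc)
    sel <- which(chrom == cc)
    if (length(ridx) == 0L) { res[sel] <- FALSE; next }
    o <- ridx[order(regions$start[ridx])]
    k <- findInterval(pos[sel] - 1, regions$start[o])
    res[sel] <- k >= 1 & (pos[sel] - 1) < regions$end[o][pmax(k, 1)]
  }
  res
}

# rejection-sample positions outside all regions
sample_out_region <- function(genome, regions, n) {
  chrom <- character(n); pos <- numeric(n)
  pgen <- genome$length / sum(genome$length)
  need <- seq_len(n)
  for (attempt in 1:1000) {
    m <- length(need)
    ci <- sample.int(nrow(genome), m, replace = TRUE, prob = pgen)
    pp <- floor(stats::runif(m, 0, genome$length[ci])) + 1
    chrom[need] <- genome$chrom[ci]; pos[need] <- pp
    inside <- pos_in_regions(chrom[need], pos[need], regions)
    need <- need[inside]
    if (length(need) == 0L) break
  }
  if (length(need)) stop("could not place positions outside regions")
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics over a merged region set
#'
#' For each trait, `n_loci` lead variants are placed in-region with
#' probability theta*c/(theta*c + 1 - c) for disease traits (c = realized
#' region coverage of the genome) and probability c for quantitative
#' traits. Each lead receives Poisson(`members_mean`) block members within
#' +/- `block_halfwidth` bp, with r2 to the lead drawn Uniform(0.81, 1);
#' members of an out-of-region lead are placed outside the regions, so a
#' locus maps iff its lead was placed in-region (the ground truth the
#' generator records). A further `decoy_rate` share of significant variants
#' carries r2 <= 0.8 to every lead (Uniform(0, 0.8) to the nearest lead)
#' and so joins no locus. Significance scores are log-uniform p-values in
#' (1e-30, 5e-8), or Uniform(6.001, 30) log10 Bayes factors for
#' Bayes-factor traits. Deterministic given the config seed.
#'
#' @param config a `sim_config`
#' @param regions merged regions built from the simulated elements
#' @param genome the `genome_table` the regions live on
#' @param dir optional output directory for per-trait TSVs and `ld.tsv`
#' @return list: `records` (all significant records, GWAS table columns),
#'   `ld` (LD pair data.frame), `truth` (list: `theta`,
#'   `realized_coverage`, `lead_in_region` named logical, `config` echo),
#'   `paths`
#' @export
simulate_gwas <- function(config, regions, genome, dir = NULL) {
  set.seed(config$seed + 1L)
  cov_bp <- sum(regions$end - regions$start)
  cvg <- cov_bp / sum(genome$length)
  if (cvg == 0 && config$theta > 0)
    stop("regions cover zero bases: cannot inject enrichment")
  rec_list <- list(); ld_list <- list(); truth_flags <- logical(0)
  for (ti in seq_len(nrow(config$traits))) {
    tr <- config$traits[ti, ]
    nl <- tr$n_loci
    if (nl == 0L) next
    q <- if (tr$category == "disease")
      config$theta * cvg / (config$theta * cvg + 1 - cvg) else cvg
    lead_in <- stats::runif(nl) < q
    lead_df <- data.frame(chrom = character(nl), pos = numeric(nl),
                          stringsAsFactors = FALSE)
    if (any(lead_in))
      lead_df[lead_in, ] <- sample_in_region(regions, sum(lead_in))
    if (any(!lead_in))
      lead_df[!lead_in, ] <- sample_out_region(genome, regions, sum(!lead_in))
    lead_ids <- sprintf("%s_L%03d", tr$trait_id, seq_len(nl))
    # block members around each lead
    n_mem <- stats::rpois(nl, tr$members_mean)
    mem_rows <- list()
    for (i in seq_len(nl)) {
      if (n_mem[i] == 0L) next
      L <- genome$length[match(lead_df$chrom[i], genome$chrom)]
      lo <- max(1, lead_df$pos[i] - config$block_halfwidth)
      hi <- min(L, lead_df$pos[i] + config$block_halfwidth)
      mp <- floor(stats::runif(n_mem[i], lo - 1, hi)) + 1
      if (!lead_in[i]) {
        # out-of-region loci stay out: resample members landing in a region
        for (attempt in 1:100) {
          inside <- pos_in_regions(rep(lead_df$chrom[i], length(mp)), mp, regions)
          if (!any(inside)) break
          mp[inside] <- floor(stats::runif(sum(inside), lo - 1, hi)) + 1
        }
        inside <- pos_in_regions(rep(lead_df$chrom[i], length(mp)), mp, regions)
        mp[inside] <- lead_df$pos[i]  # fall back to the (out-of-region) lead
      }
      mem_rows[[i]] <- data.frame(
        variant_id = sprintf("%s_m%02d", lead_ids[i], seq_len(n_mem[i])),
        chrom = lead_df$chrom[i], pos = mp, lead_id = lead_ids[i],
        r2 = stats::runif(n_mem[i], 0.81, 1), stringsAsFactors = FALSE)
    }
    members <- if (length(mem_rows)) do.call(rbind, mem_rows) else NULL
    n_core <- nl + sum(n_mem)
    n_decoy <- round(config$decoy_rate * n_core)
    decoys <- NULL
    if (n_decoy > 0) {
      dpos <- data.frame(
        chrom = genome$chrom[sample.int(nrow(genome), n_decoy, replace = TRUE,
                                        prob = genome$length)],
        stringsAsFactors = FALSE)
      dpos$pos <- floor(stats::runif(n_decoy, 0,
        genome$length[match(dpos$chrom, genome$chrom)])) + 1
      # r2 below the block threshold, to the nearest lead on the chromosome
      near <- vapply(seq_len(n_decoy), function(j) {
        cand <- which(lead_df$chrom == dpos$chrom[j])
        if (!length(cand)) cand <- seq_len(nl)
        cand[which.min(abs(lead_df$pos[cand] - dpos$pos[j]))]
      }, integer(1))
      decoys <- data.frame(
        variant_id = sprintf("%s_d%03d", tr$trait_id, seq_len(n_decoy)),
        chrom = dpos$chrom, pos = dpos$pos,
        lead_id = NA_character_,
        r2 = stats::runif(n_decoy, 0, 0.8),
        decoy_lead = lead_ids[near],
        stringsAsFactors = FALSE)
    }
    all_ids <- c(lead_ids,
                 if (!is.null(members)) members$variant_id,
                 if (!is.null(decoys)) decoys$variant_id)
    n_all <- length(all_ids)
    score <- if (tr$sig_mode == "pvalue")
      10^stats::runif(n_all, -30, log10(5e-8)) else
      stats::runif(n_all, 6.001, 30)
    rec <- data.frame(
      variant_id = all_ids,
      chrom = c(lead_df$chrom,
                if (!is.null(members)) members$chrom,
                if (!is.null(decoys)) decoys$chrom),
      pos = c(lead_df$pos,
              if (!is.null(members)) members$pos,
              if (!is.null(decoys)) decoys$pos),
      score = score,
      lead_id = c(lead_ids,
                  if (!is.null(members)) members$lead_id,
                  if (!is.null(decoys)) rep(NA_character_, nrow(decoys))),
      trait_id = tr$trait_id, category = tr$category,
      sig_mode = tr$sig_mode, stringsAsFactors = FALSE)
    rec_list[[ti]] <- rec
    ld_list[[ti]] <- rbind(
      data.frame(variant_id = lead_ids, lead_id = lead_ids, r2 = 1,
                 stringsAsFactors = FALSE),
      if (!is.null(members))
        members[, c("variant_id", "lead_id", "r2")],
      if (!is.null(decoys))
        data.frame(variant_id = decoys$variant_id,
                   lead_id = decoys$decoy_lead, r2 = decoys$r2,
                   stringsAsFactors = FALSE))
    truth_flags <- c(truth_flags, stats::setNames(lead_in, lead_ids))
  }
  records <- do.call(rbind, rec_list)
  ld <- do.call(rbind, ld_list)
  if (is.null(records))
    records <- data.frame(variant_id = character(), chrom = character(),
                          pos = numeric(), score = numeric(),
                          lead_id = character(), trait_id = character(),
                          category = character(), sig_mode = character(),
                          stringsAsFactors = FALSE)
  if (is.null(ld))
    ld <- data.frame(variant_id = character(), lead_id = character(),
                     r2 = numeric(), stringsAsFactors = FALSE)
  rownames(records) <- rownames(ld) <- NULL
  truth <- list(theta = config$theta, realized_coverage = cvg,
                seed = config$seed,
                lead_in_region = as.list(truth_flags))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gwas_paths <- character(nrow(config$traits))
    for (ti in seq_len(nrow(config$traits))) {
      tr <- config$traits[ti, ]
      gwas_paths[ti] <- file.path(dir, sprintf("gwas_%s.tsv", tr$trait_id))
      sub <- records[records$trait_id == tr$trait_id,
                     c("variant_id", "chrom", "pos", "score", "lead_id")]
      names(sub)[names(sub) == "score"] <- tr$sig_mode
      utils::write.table(sub, gwas_paths[ti], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
    ld_path <- file.path(dir, "ld.tsv")
    utils::write.table(ld, ld_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths <- list(gwas = stats::setNames(gwas_paths, config$traits$trait_id),
                  ld = ld_path)
  }
  list(records = records, ld = ld, truth = truth, paths = paths)
}

#' Write a complete synthetic input bundle
#'
#' Runs element simulation, region merging and GWAS simulation, and writes
#' every file the pipeline reads into one directory: `chrom.sizes`, nine
#' element BEDs, per-trait GWAS TSVs, `ld.tsv`, a `manifest.yaml` tying
#' them together, and `sim_truth.json` with the generator's ground truth.
#'
#' @param config a `sim_config`
#' @param dir output directory (created if needed)
#' @return invisibly, list: `dir`, `manifest` (path), `truth`
#' @export
end_to_end_fixture <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  sim <- simulate_psi_elements(config, dir = dir)
  regions <- merge_into_regions(sim$elements)
  gw <- simulate_gwas(config, regions, sim$genome, dir = dir)
  manifest <- list(
    chrom_sizes = "chrom.sizes",
    psi_beds = as.list(stats::setNames(
      basename(sim$paths$beds), paste0("type_", config$per_type$type_code))),
    ld = "ld.tsv",
    traits = lapply(seq_len(nrow(config$traits)), function(ti) {
      tr <- config$traits[ti, ]
      list(trait_id = tr$trait_id, category = tr$category,
           sig_mode = tr$sig_mode,
           path = basename(gw$paths$gwas[[tr$trait_id]]))
    })
  )
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  jsonlite::write_json(gw$truth, file.path(dir, "sim_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, manifest = mpath, truth = gw$truth))
}
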