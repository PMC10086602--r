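# End-to-end driver: read an input bundle, build regions, filter and map
# variants, derive loci, run the contingency contrasts, and write a
# consolidated report.

#' Run the full colocalization pipeline on an input bundle
#'
#' The bundle directory must contain a `manifest.yaml` (as written by
#' [end_to_end_fixture()], or hand-written to the same schema) pointing at
#' a chrom.sizes file, per-type element BEDs, per-trait GWAS TSVs and an
#' LD table. Stages: build-regions, filter, map, clump, tests. Any stage
#' error propagates with the stage name; when `out` is given, partially
#' written outputs are removed on failure.
#'
#' @param bundle bundle directory containing `manifest.yaml`
#' @param out optional output directory: writes `report.json`,
#'   `regions.bed`, `mapped_variants.tsv`, `loci.tsv`, `tables/*.tsv`,
#'   `run.log`
#' @param correction apply Yates continuity correction to 2x2 tests
#'   (default TRUE)
#' @param singleton promote unassigned significant variants to singleton
#'   loci (default FALSE)
#' @param multi_type "all" or "exclude": handling of multi-type regions in
#'   type-level counts
#' @return the report, a nested list (class `psimap_report`)
#' @export
run_pipeline <- function(bundle, out = NULL, correction = TRUE,
                         singleton = FALSE,
                         multi_type = c("all", "exclude")) {
  multi_type <- match.arg(multi_type)
  manifest_path <- file.path(bundle, "manifest.yaml")
  if (!file.exists(manifest_path))
    stop("[stage input] no manifest.yaml under ", bundle)
  man <- yaml::read_yaml(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(bundle, p))

  ## stage: build-regions
  st <- "build-regions"
  res <- tryCatch({
    genome <- read_chrom_sizes(resolve(man$chrom_sizes))
    bed_paths <- vapply(man$psi_beds, identity, character(1))
    type_codes <- as.integer(sub("^type_", "", names(man$psi_beds)))
    elements <- read_psi_elements(resolve(bed_paths), genome,
                                  type_codes = type_codes)
    regions <- merge_into_regions(elements)
    summary <- summarize_regions(regions, genome)
    chrom_test <- if (nrow(genome) >= 2 && nrow(regions) > 0)
      chisq_chromosome_distribution(regions, genome) else NULL
    list(genome = genome, elements = elements, regions = regions,
         summary = summary, chrom_test = chrom_test)
  }, error = function(e) stop_stage(st, e))

  ## stage: filter
  st <- "filter"
  gw <- tryCatch({
    traits <- do.call(rbind, lapply(man$traits, function(tr)
      data.frame(trait_id = tr$trait_id, category = tr$category,
                 sig_mode = tr$sig_mode, path = tr$path,
                 stringsAsFactors = FALSE)))
    recs <- do.call(rbind, lapply(seq_len(nrow(traits)), function(i)
      read_gwas_table(resolve(traits$path[i]), traits[i, ])))
    sig <- filter_significant(recs)
    list(traits = traits, n_input_records = nrow(recs), sig = sig)
  }, error = function(e) stop_stage(st, e))

  ## stage: map
  st <- "map"
  mp <- tryCatch({
    mapped <- map_variants(gw$sig, res$regions)
    plei <- count_pleiotropic(mapped)
    tcounts <- type_level_counts(mapped, gw$traits, multi_type = multi_type)
    list(mapped = mapped, plei = plei, tcounts = tcounts)
  }, error = function(e) stop_stage(st, e))

  ## stage: clump
  st <- "clump"
  lc <- tryCatch({
    if (nrow(gw$sig) == 0L) {
      list(assignments = NULL, loci = NULL, locus_rate = NULL)
    } else {
      ld <- read_ld_table(resolve(man$ld))
      assignments <- assign_blocks(gw$sig, ld)
      loci <- summarize_loci(assignments, mp$mapped, singleton = singleton)
      list(assignments = assignments, loci = loci,
           locus_rate = if (nrow(loci) > 0) locus_mapping_rate(loci) else NULL)
    }
  }, error = function(e) stop_stage(st, e))

  ## stage: tests
  st <- "tests"
  tests <- tryCatch({
    out_tests <- list()
    out_tests$chromosome_distribution <- res$chrom_test
    safely <- function(expr, label) {
      tryCatch(suppressWarnings(expr), error = function(e)
        list(skipped = TRUE, reason = conditionMessage(e), label = label))
    }
    if (nrow(mp$mapped) > 0) {
      out_tests$type_contrast_hsInsert <- safely(
        chisq_independence(build_type_contrast_table(mp$tcounts, 6L),
                           correction = correction), "type contrast")
    } else {
      out_tests$type_contrast_hsInsert <-
        list(skipped = TRUE, reason = "no mapped variants")
    }
    if (!is.null(lc$loci) && nrow(lc$loci) > 0) {
      out_tests$locus_category <- safely(
        chisq_independence(build_locus_category_table(lc$loci, gw$traits),
                           correction = correction), "locus category")
    } else {
      out_tests$locus_category <- list(skipped = TRUE, reason = "no loci")
    }
    out_tests$regulatory <- safely(
      chisq_independence(build_regulatory_table(res$regions, mp$mapped),
                         correction = correction), "regulatory")
    out_tests
  }, error = function(e) stop_stage(st, e))

  report <- build_report(res, gw, mp, lc, tests,
                         flags = list(correction = correction,
                                      singleton = singleton,
                                      multi_type = multi_type))
  if (!is.null(out)) {
    ok <- FALSE
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    on.exit(if (!ok) unlink(out, recursive = TRUE), add = TRUE)
    write_report_bundle(report, res, mp, lc, out)
    ok <- TRUE
  }
  report
}

chisq_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (!inherits(x, "chisq_result")) return(x)  # skipped marker
  tab <- x$table
  list(table = if (is.matrix(tab))
         stats::setNames(lapply(seq_len(nrow(tab)), function(i)
           as.list(stats::setNames(as.numeric(tab[i, ]), colnames(tab)))),
           rownames(tab))
       else as.list(tab),
       statistic = x$statistic, df = x$df, p = x$p,
       p_display = x$p_display, correction = x$correction, kind = x$kind)
}

build_report <- function(res, gw, mp, lc, tests, flags) {
  s <- res$summary
  n_sig <- nrow(gw$sig)
  n_mapped_records <- nrow(mp$mapped)
  mapped_region_ids <- unique(mp$mapped$region_id)
  n_mapped_regions <- length(mapped_region_ids)
  # non-regulatory share among mapped regions
  reg_flag <- res$regions$regulatory[match(mapped_region_ids,
                                           res$regions$region_id)]
  n_nonreg_mapped <- sum(!reg_flag)
  report <- list(
    flags = flags,
    elements = list(n_elements = nrow(res$elements),
                    per_type = as.list(table(res$elements$type_code))),
    regions = list(
      n_regions = s$n_regions,
      n_multi_element = s$n_multi_element,
      multi_element_pct = s$multi_element_pct,
      total_bp = s$total_bp,
      mean_bp = s$mean_bp,
      mean_bp_trunc = s$mean_bp_trunc,
      genome_coverage = s$genome_coverage,
      genome_coverage_pct = s$genome_coverage_pct,
      per_chrom = s$per_chrom
    ),
    gwas = list(
      n_traits = nrow(gw$traits),
      n_input_records = gw$n_input_records,
      n_significant_records = n_sig
    ),
    mapping = list(
      n_mapped_records = n_mapped_records,
      n_distinct_mapped_variants = mp$plei$n_distinct_mapped,
      n_pleiotropic = mp$plei$n_pleiotropic,
      pleiotropic_pct = mp$plei$pleiotropic_pct,
      variant_rate = if (n_sig > 0)
        variant_mapping_rate(n_mapped_records, n_sig) else NULL,
      n_mapped_regions = n_mapped_regions,
      mapped_region_pct = if (s$n_regions > 0)
        pct_share(n_mapped_regions, s$n_regions) else NA_real_,
      n_nonregulatory_mapped_regions = n_nonreg_mapped,
      nonregulatory_mapped_share_pct = if (n_mapped_regions > 0)
        pct_share(n_nonreg_mapped, n_mapped_regions) else NA_real_,
      type_counts = as.data.frame(mp$tcounts)
    ),
    loci = if (!is.null(lc$locus_rate)) list(
      n_input_loci = lc$locus_rate$n_input_loci,
      n_mapped_loci = lc$locus_rate$n_mapped_loci,
      locus_rate_pct = lc$locus_rate$rate_pct,
      n_unassigned_variants = if (!is.null(lc$assignments))
        sum(lc$assignments$unassigned) else 0L
    ) else list(skipped = TRUE, reason = "no significant variants or loci"),
    tests = lapply(tests, chisq_to_list)
  )
  validate_report(report)
  class(report) <- c("psimap_report", "list")
  report
}

# internal-consistency assertion: displayed percentages recompute from
# their numerator/denominator fields
validate_report <- function(r) {
  chk <- function(pct, num, den) {
    if (is.null(pct) || is.na(pct) || den == 0) return(invisible())
    stopifnot(isTRUE(all.equal(pct, pct_share(num, den))))
  }
  chk(r$regions$multi_element_pct, r$regions$n_multi_element,
      r$regions$n_regions)
  chk(r$mapping$pleiotropic_pct, r$mapping$n_pleiotropic,
      r$mapping$n_distinct_mapped_variants)
  chk(r$mapping$mapped_region_pct, r$mapping$n_mapped_regions,
      r$regions$n_regions)
  chk(r$mapping$nonregulatory_mapped_share_pct,
      r$mapping$n_nonregulatory_mapped_regions, r$mapping$n_mapped_regions)
  if (!is.null(r$loci$locus_rate_pct))
    chk(r$loci$locus_rate_pct, r$loci$n_mapped_loci, r$loci$n_input_loci)
  invisible(r)
}

write_report_bundle <- function(report, res, mp, lc, out) {
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write_regions_bed(res$regions, file.path(out, "regions.bed"))
  write_mapped_variants(mp$mapped, file.path(out, "mapped_variants.tsv"))
  if (!is.null(lc$loci))
    utils::write.table(lc$loci, file.path(out, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tdir <- file.path(out, "tables")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(report$tests)) {
    tt <- report$tests[[nm]]
    if (is.null(tt) || isTRUE(tt$skipped)) next
    tab <- tt$table
    df <- if (is.list(tab) && !is.null(names(tab)) &&
              is.list(tab[[1]])) {
      cbind(data.frame(row = names(tab), stringsAsFactors = FALSE),
            do.call(rbind, lapply(tab, function(x)
              as.data.frame(x, stringsAsFactors = FALSE))))
    } else {
      data.frame(category = names(unlist(tab)), count = unlist(tab),
                 stringsAsFactors = FALSE)
    }
    utils::write.table(df, file.path(tdir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(
    sprintf("psimap run: %d elements -> %d regions", report$elements$n_elements,
            report$regions$n_regions),
    sprintf("thresholds: p < %g (strict), log10BF > %g (strict), r2 > 0.8 (strict)",
            GWAS_P_THRESHOLD, GWAS_LOG10BF_THRESHOLD),
    sprintf("flags: correction=%s singleton=%s multi_type=%s",
            report$flags$correction, report$flags$singleton,
            report$flags$multi_type))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.psimap_report <- function(x, ...) {
  cat("psimap pipeline report\n")
  cat(sprintf("  elements: %d; regions: %d (%.1f%% multi-element), coverage %.2f%%\n",
              x$elements$n_elements, x$regions$n_regions,
              x$regions$multi_element_pct, x$regions$genome_coverage_pct))
  cat(sprintf("  significant records: %d; mapped: %d",
              x$gwas$n_significant_records, x$mapping$n_mapped_records))
  if (!is.null(x$mapping$variant_rate))
    cat(sprintf(" (%.1f%%)", x$mapping$variant_rate$rate_pct))
  cat("\n")
  if (is.null(x$loci$skipped))
    cat(sprintf("  loci: %d mapped of %d (%.1f%%)\n", x$loci$n_mapped_loci,
                x$loci$n_input_loci, x$loci$locus_rate_pct))
  invisible(x)
}
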