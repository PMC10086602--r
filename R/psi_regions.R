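# PSI element input, region merging and region-level summaries.
#
# Elements are stored 0-based half-open (BED convention). Overlap means at
# least one shared base; abutting intervals (end == next start) share no base
# and are kept as separate regions.

#' Read a chromosome-sizes table
#'
#' Two-column, headerless TSV in UCSC chrom.sizes format: chromosome name and
#' length in bp.
#'
#' @param path file path
#' @return data.frame with columns `chrom` (character) and `length` (numeric bp)
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_table(df$chrom, df$length)
}

#' Construct a genome table
#'
#' @param chrom character vector of chromosome names (unique)
#' @param length numeric vector of chromosome lengths in bp (> 0)
#' @return validated data.frame of class `genome_table`
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in genome table")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("all chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_table", "data.frame"))
}

#' Read one PSI element file
#'
#' BED3+ (tab-separated, no header): chrom, start (0-based), end (half-open).
#' Extra columns are ignored. Every row is validated against the genome
#' table: unknown chromosomes are rejected, as are inverted or out-of-bounds
#' intervals.
#'
#' @param path file path
#' @param type_code integer PSI type code in 1..9
#' @param genome a `genome_table`
#' @param source_label label recorded on each element (defaults to the file
#'   basename)
#' @return data.frame of elements: `element_id`, `type_code`, `chrom`,
#'   `start`, `end`, `source_label`
#' @export
read_psi_bed <- function(path, type_code, genome,
                         source_label = basename(path)) {
  type_code <- as.integer(type_code)
  if (is.na(type_code) || type_code < 1L || type_code > 9L)
    stop("type_code must be an integer in 1..9")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_elements())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_row <- lengths(parts)
  bad <- which(ncol_row < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d has %d column(s); need >= 3 (chrom, start, end)",
                 path, bad[1], ncol_row[bad[1]]))
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("%s: line %d: start/end not integers", path, bad[1]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s: line %d: start (%d) >= end (%d)",
                 path, bad[1], start[bad[1]], end[bad[1]]))
  bad <- which(start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: negative start", path, bad[1]))
  unknown <- !(chrom %in% genome$chrom)
  if (any(unknown))
    stop(sprintf("%s: line %d: chromosome '%s' absent from genome table",
                 path, which(unknown)[1], chrom[which(unknown)[1]]))
  chrom_len <- genome$length[match(chrom, genome$chrom)]
  bad <- which(end > chrom_len)
  if (length(bad))
    stop(sprintf("%s: line %d: end %d exceeds length of %s (%d)",
                 path, bad[1], end[bad[1]], chrom[bad[1]], chrom_len[bad[1]]))
  data.frame(
    element_id = sprintf("t%d_e%05d", type_code, seq_along(chrom)),
    type_code = type_code,
    chrom = chrom, start = start, end = end,
    source_label = source_label,
    stringsAsFactors = FALSE
  )
}

empty_elements <- function() {
  data.frame(element_id = character(), type_code = integer(),
             chrom = character(), start = numeric(), end = numeric(),
             source_label = character(), stringsAsFactors = FALSE)
}

#' Read a full set of PSI element files
#'
#' @param paths named list or vector of file paths; names (or the
#'   `type_codes` argument) give each file's type code
#' @param genome a `genome_table`
#' @param type_codes integer codes parallel to `paths` (defaults to
#'   `as.integer(names(paths))`)
#' @return one combined element data.frame
#' @export
read_psi_elements <- function(paths, genome, type_codes = NULL) {
  paths <- unlist(paths)
  if (is.null(type_codes)) type_codes <- as.integer(names(paths))
  stopifnot(length(type_codes) == length(paths), !anyNA(type_codes))
  out <- mapply(read_psi_bed, paths, type_codes,
                MoreArgs = list(genome = genome), SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Merge PSI elements into non-overlapping PSI regions
#'
#' Regions are the connected components of overlapping elements per
#' chromosome under half-open semantics: two elements belong to the same
#' region iff a chain of pairwise overlaps (>= 1 shared base) links them.
#' Abutting elements are not merged. Each region records the ids and type
#' codes of all its constituent elements; a region is regulatory unless its
#' type set is contained in the non-regulatory classes (hsInsert, psTU).
#'
#' @param elements element data.frame as returned by [read_psi_bed()]
#' @return data.frame of regions sorted by (chrom, start): `region_id`,
#'   `chrom`, `start`, `end`, `element_ids` (list column), `type_set` (list
#'   column of sorted unique codes), `n_elements`, `multi_element`,
#'   `regulatory`
#' @export
merge_into_regions <- function(elements) {
  if (nrow(elements) == 0L) return(empty_regions())
  # stable ordering so region ids and constituent lists are reproducible
  o <- order(elements$chrom, elements$start, elements$end, elements$element_id)
  el <- elements[o, , drop = FALSE]
  new_chrom <- c(TRUE, el$chrom[-1] != el$chrom[-nrow(el)])
  # running max end per chromosome; a new component starts when the next
  # element's start is at or beyond everything seen so far (abutting splits)
  run_max <- el$end
  comp_break <- logical(nrow(el))
  comp_break[1] <- TRUE
  if (nrow(el) > 1) {
    for (i in 2:nrow(el)) {
      if (new_chrom[i] || el$start[i] >= run_max[i - 1]) {
        comp_break[i] <- TRUE
      } else {
        run_max[i] <- max(run_max[i - 1], el$end[i])
      }
    }
  }
  grp <- cumsum(comp_break)
  idx <- split(seq_len(nrow(el)), grp)
  n <- length(idx)
  chrom <- vapply(idx, function(i) el$chrom[i[1]], character(1))
  start <- vapply(idx, function(i) el$start[i[1]], numeric(1))
  end <- vapply(idx, function(i) max(el$end[i]), numeric(1))
  element_ids <- lapply(idx, function(i) el$element_id[i])
  type_set <- lapply(idx, function(i) sort(unique(el$type_code[i])))
  n_elements <- lengths(idx)
  regions <- data.frame(
    region_id = sprintf("R%06d", seq_len(n)),
    chrom = chrom, start = start, end = end,
    n_elements = as.integer(n_elements),
    multi_element = n_elements > 1L,
    regulatory = !vapply(type_set, function(ts)
      all(ts %in% nonregulatory_types), logical(1)),
    stringsAsFactors = FALSE
  )
  regions$element_ids <- unname(element_ids)
  regions$type_set <- unname(type_set)
  rownames(regions) <- NULL
  regions
}

empty_regions <- function() {
  df <- data.frame(region_id = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   n_elements = integer(), multi_element = logical(),
                   regulatory = logical(), stringsAsFactors = FALSE)
  df$element_ids <- list()
  df$type_set <- list()
  df
}

#' Summarize a merged region set
#'
#' Counts, length totals and genome coverage. The mean region length is
#' reported both to one decimal and truncated toward zero to an integer (the
#' rounding convention used in summary tables of this kind).
#'
#' @param regions merged regions from [merge_into_regions()]
#' @param genome a `genome_table` covering every chromosome in `regions`
#' @return list of class `region_summary`: `n_regions`, `n_multi_element`,
#'   `multi_element_pct`, `total_bp`, `mean_bp` (1 decimal), `mean_bp_trunc`
#'   (integer), `genome_coverage` (fraction), `genome_coverage_pct`, and a
#'   `per_chrom` data.frame (`chrom`, `n_regions`, `covered_bp`,
#'   `coverage_fraction`)
#' @export
summarize_regions <- function(regions, genome) {
  missing <- setdiff(unique(regions$chrom), genome$chrom)
  if (length(missing))
    stop("genome table is missing chromosome(s): ",
         paste(missing, collapse = ", "))
  widths <- regions$end - regions$start
  total_bp <- sum(widths)
  n <- nrow(regions)
  covered <- tapply(widths, factor(regions$chrom, levels = genome$chrom), sum)
  covered[is.na(covered)] <- 0
  counts <- tapply(rep(1L, n), factor(regions$chrom, levels = genome$chrom), sum)
  counts[is.na(counts)] <- 0L
  per_chrom <- data.frame(
    chrom = genome$chrom,
    n_regions = as.integer(counts),
    covered_bp = as.numeric(covered),
    coverage_fraction = as.numeric(covered) / genome$length,
    stringsAsFactors = FALSE
  )
  coverage <- total_bp / sum(genome$length)
  structure(list(
    n_regions = n,
    n_multi_element = sum(regions$multi_element),
    multi_element_pct = if (n > 0) pct_share(sum(regions$multi_element), n) else NA_real_,
    total_bp = total_bp,
    mean_bp = if (n > 0) round_half_up(total_bp / n, 1) else NA_real_,
    mean_bp_trunc = if (n > 0) trunc(total_bp / n) else NA_real_,
    genome_coverage = coverage,
    genome_coverage_pct = round_half_up(100 * coverage, 2),
    per_chrom = per_chrom
  ), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("PSI region summary: %d regions (%d multi-element, %.1f%%)\n",
              x$n_regions, x$n_multi_element, x$multi_element_pct))
  cat(sprintf("  total %d bp, mean %.1f bp (truncated %d), genome coverage %.2f%%\n",
              x$total_bp, x$mean_bp, x$mean_bp_trunc, x$genome_coverage_pct))
  invisible(x)
}

#' Chi-square test of region distribution across chromosomes
#'
#' Goodness-of-fit of observed region counts per chromosome against expected
#' counts proportional to chromosome length: E_c = N * L_c / sum(L). Tests
#' whether regions are distributed evenly once chromosomal lengths are
#' accounted for.
#'
#' @param regions merged regions
#' @param genome a `genome_table` with >= 2 chromosomes
#' @return a `chisq_result` (see [chisq_independence()]); `table` holds the
#'   observed counts, `expected` the length-proportional expectations
#' @export
chisq_chromosome_distribution <- function(regions, genome) {
  if (nrow(genome) < 2) stop("need >= 2 chromosomes for a distribution test")
  missing <- setdiff(unique(regions$chrom), genome$chrom)
  if (length(missing))
    stop("genome table is missing chromosome(s): ",
         paste(missing, collapse = ", "))
  obs <- table(factor(regions$chrom, levels = genome$chrom))
  n_total <- sum(obs)
  if (n_total == 0) stop("no regions to test")
  p <- genome$length / sum(genome$length)
  expected <- n_total * p
  if (any(expected == 0))
    stop("expected count of 0 for some chromosome; exclude zero-length chromosomes")
  ct <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p))
  new_chisq_result(
    table = stats::setNames(as.numeric(obs), genome$chrom),
    expected = stats::setNames(expected, genome$chrom),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p = unname(ct$p.value),
    correction = FALSE,
    kind = "goodness_of_fit"
  )
}

#' Write merged regions as a BED-style TSV
#'
#' Columns: chrom, start, end, region_id, type_set (comma-joined codes),
#' n_elements, regulatory flag.
#'
#' @param regions merged regions
#' @param path output path
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    region_id = regions$region_id,
    type_set = vapply(regions$type_set, paste, character(1), collapse = ","),
    n_elements = regions$n_elements,
    regulatory = regions$regulatory,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
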