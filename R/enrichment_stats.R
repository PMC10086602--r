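# Contingency tables and chi-square tests used by the colocalization
# contrasts: trait-category vs mapping, focal-type vs pooled types,
# regulatory vs non-regulatory regions.

new_chisq_result <- function(table, statistic, df, p, correction,
                             expected = NULL, kind = "independence") {
  structure(list(
    table = table,
    expected = expected,
    statistic = statistic,
    df = df,
    p = p,
    p_display = format_p_display(p),
    correction = correction,
    kind = kind
  ), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-squared %s test%s: X2 = %.4g, df = %d, p = %s\n",
              x$kind, if (isTRUE(x$correction)) " (Yates)" else "",
              x$statistic, x$df, x$p_display))
  print(x$table)
  invisible(x)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Expected counts from row/column margins; for 2x2 tables with
#' `correction = TRUE` the Yates continuity correction is applied
#' (|O - E| reduced by 0.5, floored at 0). A zero expected cell is an
#' error; an expected cell below 5 triggers a warning only.
#'
#' @param table count matrix, at least 2x2, preferably with dimnames
#' @param correction apply Yates continuity correction (2x2 only;
#'   default TRUE)
#' @return object of class `chisq_result`: `table`, `expected`,
#'   `statistic`, `df`, `p` (raw), `p_display` (floored at 2.2e-16 for
#'   display), `correction`
#' @export
chisq_independence <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2x2")
  if (any(table < 0)) stop("negative counts in contingency table")
  n <- sum(table)
  if (n == 0) stop("empty contingency table")
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0))
    stop("expected cell count of 0; drop empty rows/columns before testing")
  if (any(expected < 5))
    warning("expected cell count < 5; chi-squared approximation may be inaccurate")
  apply_yates <- isTRUE(correction) && nrow(table) == 2 && ncol(table) == 2
  ct <- suppressWarnings(stats::chisq.test(table, correct = apply_yates))
  new_chisq_result(
    table = table,
    expected = expected,
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p = unname(ct$p.value),
    correction = apply_yates
  )
}

#' Focal-type vs pooled-types contrast table
#'
#' 2x2 table contrasting one PSI type's mapped-variant counts against all
#' other types pooled, split by trait category. Rows: focal type, all other
#' types; columns: disease, quantitative.
#'
#' @param type_counts matrix from [type_level_counts()] (types x categories)
#' @param focal_type integer PSI type code in 1..9
#' @return 2x2 count matrix with dimnames
#' @export
build_type_contrast_table <- function(type_counts, focal_type) {
  stopifnot(focal_type %in% 1:9)
  if (sum(type_counts) == 0) stop("no mapped variant counts to contrast")
  key <- as.character(focal_type)
  if (!key %in% rownames(type_counts))
    stop("focal type ", focal_type, " absent from type counts")
  focal <- unname(type_counts[key, c("disease", "quantitative")])
  others <- colSums(type_counts[setdiff(rownames(type_counts), key), ,
                                drop = FALSE])[c("disease", "quantitative")]
  tab <- rbind(focal, others)
  dimnames(tab) <- list(
    c(unname(psi_type_labels[key]), "other_types"),
    c("disease", "quantitative")
  )
  tab
}

#' Trait-category vs locus-mapping contrast table
#'
#' 2x2 table of loci by trait category (disease vs quantitative) and mapped
#' status (>= 1 member variant inside a PSI region vs none).
#'
#' @param loci per-locus data.frame from [summarize_loci()]
#' @param traits trait table with `trait_id` and `category`
#' @return 2x2 count matrix, rows (disease, quantitative) x columns
#'   (mapped, unmapped)
#' @export
build_locus_category_table <- function(loci, traits) {
  cat_of <- traits$category[match(loci$trait_id, traits$trait_id)]
  if (anyNA(cat_of))
    stop("locus trait(s) missing from trait table: ",
         paste(unique(loci$trait_id[is.na(cat_of)]), collapse = ", "))
  tab <- matrix(0, 2, 2, dimnames = list(c("disease", "quantitative"),
                                         c("mapped", "unmapped")))
  for (cc in c("disease", "quantitative")) {
    sel <- cat_of == cc
    tab[cc, "mapped"] <- sum(loci$mapped[sel])
    tab[cc, "unmapped"] <- sum(!loci$mapped[sel])
  }
  tab
}

#' Regulatory vs non-regulatory region hit table
#'
#' Single-type regions only (multi-type regions are excluded for
#' simplicity), classified regulatory (type not hsInsert/psTU) vs
#' non-regulatory, crossed with whether >= 1 significant variant mapped
#' into the region.
#'
#' @param regions merged regions
#' @param mapped mapped variants from [map_variants()]
#' @return 2x2 count matrix, rows (regulatory, non_regulatory) x columns
#'   (hit, no_hit)
#' @export
build_regulatory_table <- function(regions, mapped) {
  single <- lengths(regions$type_set) == 1L
  reg <- regions[single, , drop = FALSE]
  hit_ids <- unique(mapped$region_id)
  is_hit <- reg$region_id %in% hit_ids
  is_regulatory <- reg$regulatory
  tab <- matrix(c(sum(is_regulatory & is_hit), sum(is_regulatory & !is_hit),
                  sum(!is_regulatory & is_hit), sum(!is_regulatory & !is_hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("regulatory", "non_regulatory"),
                                c("hit", "no_hit")))
  tab
}
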