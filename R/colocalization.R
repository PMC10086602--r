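# Positional mapping of significant variants into merged PSI regions, plus
# pleiotropy and per-type tallies. This is positional overlap only, not
# posterior-probability signal colocalization.

#' Map variants into PSI regions
#'
#' A variant with 1-based position p maps into region [s, e) (0-based
#' half-open) iff s <= p - 1 < e. Regions are disjoint, so at most one can
#' match. Unmapped variants are absent from the output.
#'
#' @param records significant GWAS records ([filter_significant()])
#' @param regions merged regions ([merge_into_regions()])
#' @return data.frame: the record columns plus `region_id` and `type_set`
#'   (list column, the region's full set of PSI type codes)
#' @export
map_variants <- function(records, regions) {
  empty <- cbind(records[0, , drop = FALSE],
                 data.frame(region_id = character(), stringsAsFactors = FALSE))
  empty$type_set <- list()
  if (nrow(records) == 0L || nrow(regions) == 0L) return(empty)
  hit_idx <- rep(NA_integer_, nrow(records))
  for (cc in unique(records$chrom)) {
    ridx <- which(regions$chrom == cc)
    if (length(ridx) == 0L) next
    o <- ridx[order(regions$start[ridx])]
    starts <- regions$start[o]
    ends <- regions$end[o]
    vsel <- which(records$chrom == cc)
    pos0 <- records$pos[vsel] - 1  # convert 1-based position to 0-based offset
    k <- findInterval(pos0, starts)
    ok <- k >= 1 & pos0 < ends[pmax(k, 1)]
    hit_idx[vsel[ok]] <- o[k[ok]]
  }
  mapped <- which(!is.na(hit_idx))
  out <- records[mapped, , drop = FALSE]
  out$region_id <- regions$region_id[hit_idx[mapped]]
  out$type_set <- regions$type_set[hit_idx[mapped]]
  rownames(out) <- NULL
  out
}

#' Count distinct and pleiotropic mapped variants
#'
#' A mapped variant is pleiotropic when it is significant and mapped in two
#' or more distinct traits. Identity follows the variant key (variant_id
#' when present, else chrom:pos).
#'
#' @param mapped mapped variants from [map_variants()]
#' @return list: `n_distinct_mapped`, `n_pleiotropic`, `pleiotropic_pct`
#'   (share of distinct mapped variants; NA when none)
#' @export
count_pleiotropic <- function(mapped) {
  if (nrow(mapped) == 0L)
    return(list(n_distinct_mapped = 0L, n_pleiotropic = 0L,
                pleiotropic_pct = NA_real_))
  traits_per_variant <- tapply(mapped$trait_id, mapped$variant_key,
                               function(x) length(unique(x)))
  n_distinct <- length(traits_per_variant)
  n_plei <- sum(traits_per_variant >= 2)
  list(n_distinct_mapped = n_distinct,
       n_pleiotropic = as.integer(n_plei),
       pleiotropic_pct = pct_share(n_plei, n_distinct))
}

#' Mapped-variant counts by PSI type and trait category
#'
#' Tallies variant-trait mapping events per PSI type. A variant mapped into
#' a multi-type region increments every type in the region's type set by
#' default; `multi_type = "exclude"` drops such events instead.
#'
#' @param mapped mapped variants from [map_variants()]
#' @param traits trait table with `trait_id` and `category`
#' @param multi_type "all" (count each constituent type) or "exclude"
#'   (drop events in multi-type regions)
#' @return 9 x 2 integer matrix, rows = type codes "1".."9", columns =
#'   c("disease", "quantitative")
#' @export
type_level_counts <- function(mapped, traits,
                              multi_type = c("all", "exclude")) {
  multi_type <- match.arg(multi_type)
  tab <- matrix(0L, nrow = 9, ncol = 2,
                dimnames = list(as.character(1:9),
                                c("disease", "quantitative")))
  if (nrow(mapped) == 0L) return(tab)
  cat_of <- traits$category[match(mapped$trait_id, traits$trait_id)]
  if (anyNA(cat_of))
    stop("mapped variant trait(s) missing from trait table: ",
         paste(unique(mapped$trait_id[is.na(cat_of)]), collapse = ", "))
  for (i in seq_len(nrow(mapped))) {
    ts <- mapped$type_set[[i]]
    if (multi_type == "exclude" && length(ts) > 1L) next
    for (tc in ts)
      tab[as.character(tc), cat_of[i]] <- tab[as.character(tc), cat_of[i]] + 1L
  }
  tab
}

#' Write mapped variants as TSV
#'
#' @param mapped mapped variants
#' @param path output path
#' @export
write_mapped_variants <- function(mapped, path) {
  df <- mapped[, c("variant_key", "chrom", "pos", "trait_id", "category",
                   "region_id")]
  df$type_set <- vapply(mapped$type_set, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
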