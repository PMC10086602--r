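# LD-block locus derivation: collapse significant variants onto reported
# lead variants via r^2 > 0.8 blocks, then count loci and locus-level
# mapping rates. Loci are trait-specific: the same genomic lead reported
# for two traits counts as two loci.

#' Read an LD table
#'
#' TSV with header and columns `variant_id`, `lead_id`, `r2`.
#'
#' @param path file path
#' @return data.frame of LD pairs
#' @export
read_ld_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "lead_id", "r2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("LD table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$r2 < 0 | df$r2 > 1)) stop("r2 values must lie in [0, 1]")
  df
}

#' Assign significant variants to lead-variant LD blocks
#'
#' A variant joins lead L's block iff r2(variant, L) > 0.8 (strict). When
#' several leads qualify, the variant joins the lead with the highest r2;
#' ties break to the lead at the smaller genomic position. Every lead is a
#' member of its own block (r2 = 1 by convention). Variants whose best r2
#' is <= 0.8 against every lead are flagged unassigned and excluded from
#' locus counts (unless singleton mode is enabled downstream).
#'
#' Leads default to the distinct non-missing `lead_id` values per trait;
#' pass a data.frame (`trait_id`, `lead_id`) to override. A lead that never
#' occurs among the trait's records triggers a warning; its block is still
#' created when the lead id appears in the LD table.
#'
#' @param records significant GWAS records
#' @param ld LD pairs from [read_ld_table()]
#' @param leads optional data.frame (`trait_id`, `lead_id`)
#' @return data.frame, one row per (trait, variant): `trait_id`,
#'   `variant_key`, `lead_id` (NA when unassigned), `r2`, `unassigned`
#' @export
assign_blocks <- function(records, ld, leads = NULL) {
  if (is.null(leads)) {
    ok <- !is.na(records$lead_id) & records$lead_id != ""
    leads <- unique(records[ok, c("trait_id", "lead_id")])
  }
  leads <- unique(leads[, c("trait_id", "lead_id")])
  if (nrow(leads) == 0L) stop("no leads available for any trait")
  out <- vector("list", length(unique(records$trait_id)))
  names(out) <- unique(records$trait_id)
  # lead genomic positions, for the tie-break (smaller position wins)
  lead_pos <- records$pos[match(leads$lead_id, records$variant_key)]
  for (tt in names(out)) {
    rsel <- records[records$trait_id == tt, , drop = FALSE]
    tleads <- leads$lead_id[leads$trait_id == tt]
    if (length(tleads) == 0L) {
      warning("trait ", tt, " has no leads; all its variants left unassigned")
      out[[tt]] <- data.frame(trait_id = tt, variant_key = rsel$variant_key,
                              lead_id = NA_character_, r2 = NA_real_,
                              unassigned = TRUE, stringsAsFactors = FALSE)
      next
    }
    absent <- setdiff(tleads, rsel$variant_key)
    if (length(absent))
      warning("lead(s) not among significant records of trait ", tt, ": ",
              paste(absent, collapse = ", "))
    pairs <- ld[ld$lead_id %in% tleads & ld$variant_id %in% rsel$variant_key,
                c("variant_id", "lead_id", "r2"), drop = FALSE]
    # a lead belongs to its own block with r2 = 1 by convention
    self <- data.frame(variant_id = intersect(tleads, rsel$variant_key),
                       stringsAsFactors = FALSE)
    if (nrow(self)) {
      self$lead_id <- self$variant_id
      self$r2 <- 1
      pairs <- rbind(pairs, self)
    }
    pairs <- pairs[pairs$r2 > 0.8, , drop = FALSE]  # strict threshold
    best <- rep(NA_character_, nrow(rsel))
    best_r2 <- rep(NA_real_, nrow(rsel))
    if (nrow(pairs)) {
      tb_pos <- lead_pos[match(pairs$lead_id, leads$lead_id)]
      tb_pos[is.na(tb_pos)] <- Inf
      o <- order(pairs$variant_id, -pairs$r2, tb_pos, pairs$lead_id)
      pairs <- pairs[o, , drop = FALSE]
      top <- pairs[!duplicated(pairs$variant_id), , drop = FALSE]
      m <- match(rsel$variant_key, top$variant_id)
      best <- top$lead_id[m]
      best_r2 <- top$r2[m]
    }
    out[[tt]] <- data.frame(trait_id = tt, variant_key = rsel$variant_key,
                            lead_id = best, r2 = best_r2,
                            unassigned = is.na(best),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize LD blocks into loci
#'
#' One locus per (trait, lead) block. A locus is mapped when at least one
#' member variant maps into a PSI region. With `singleton = TRUE`,
#' unassigned variants form their own single-variant loci instead of being
#' excluded.
#'
#' @param assignments output of [assign_blocks()]
#' @param mapped mapped variants from [map_variants()]
#' @param singleton promote unassigned variants to singleton loci
#'   (default FALSE)
#' @return data.frame, one row per locus: `trait_id`, `lead_id`,
#'   `n_members`, `n_mapped_members`, `mapped`
#' @export
summarize_loci <- function(assignments, mapped, singleton = FALSE) {
  a <- assignments
  if (singleton) {
    a$lead_id[a$unassigned] <- a$variant_key[a$unassigned]
    a$unassigned <- FALSE
  }
  a <- a[!a$unassigned, , drop = FALSE]
  mapped_key <- paste(mapped$trait_id, mapped$variant_key, sep = "\r")
  is_mapped <- paste(a$trait_id, a$variant_key, sep = "\r") %in% mapped_key
  grp <- paste(a$trait_id, a$lead_id, sep = "\r")
  ug <- unique(grp)
  idx <- split(seq_len(nrow(a)), factor(grp, levels = ug))
  data.frame(
    trait_id = vapply(idx, function(i) a$trait_id[i[1]], character(1)),
    lead_id = vapply(idx, function(i) a$lead_id[i[1]], character(1)),
    n_members = lengths(idx),
    n_mapped_members = vapply(idx, function(i) sum(is_mapped[i]), integer(1)),
    mapped = vapply(idx, function(i) any(is_mapped[i]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Locus-level mapping rate
#'
#' Percentage of loci with at least one member variant inside a PSI region.
#'
#' @param loci per-locus table from [summarize_loci()]
#' @return list: `n_input_loci`, `n_mapped_loci`, `rate_pct` (1 decimal)
#' @export
locus_mapping_rate <- function(loci) {
  n_in <- nrow(loci)
  if (n_in == 0L) stop("no loci: cannot compute a mapping rate")
  n_map <- sum(loci$mapped)
  list(n_input_loci = n_in, n_mapped_loci = as.integer(n_map),
       rate_pct = pct_share(n_map, n_in))
}

#' Variant-level mapping rate
#'
#' Percentage of significant variant-trait records that map into a PSI
#' region.
#'
#' @param n_mapped number of mapped variant-trait records
#' @param n_input number of significant variant-trait records
#' @return list: `n_input`, `n_mapped`, `rate_pct` (1 decimal)
#' @export
variant_mapping_rate <- function(n_mapped, n_input) {
  if (n_input == 0L) stop("no significant records: cannot compute a mapping rate")
  list(n_input = n_input, n_mapped = n_mapped,
       rate_pct = pct_share(n_mapped, n_input))
}
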