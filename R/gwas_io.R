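# GWAS summary-statistics input and genome-wide significance filtering.
#
# Each trait is either quantitative or a dichotomous disease, and reports
# significance either as a p-value or as a log10 Bayes factor. Thresholds
# are strict: p < 5e-8, log10 BF > 6.

#' Genome-wide significance thresholds
#' @export
GWAS_P_THRESHOLD <- 5e-8
#' @rdname GWAS_P_THRESHOLD
#' @export
GWAS_LOG10BF_THRESHOLD <- 6

#' Construct a trait specification
#'
#' @param trait_id trait identifier
#' @param category "quantitative" or "disease"
#' @param sig_mode "pvalue" or "log10bf" — which significance score the
#'   trait's summary statistics carry
#' @return one-row data.frame
#' @export
trait_spec <- function(trait_id, category, sig_mode = "pvalue") {
  category <- match.arg(category, c("quantitative", "disease"))
  sig_mode <- match.arg(sig_mode, c("pvalue", "log10bf"))
  data.frame(trait_id = as.character(trait_id), category = category,
             sig_mode = sig_mode, stringsAsFactors = FALSE)
}

#' Read a trait manifest
#'
#' YAML (list of records under `traits:`) or TSV with header. Required
#' fields: trait_id, category, sig_mode, path. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest file
#' @return data.frame: trait_id, category, sig_mode, path
#' @export
read_trait_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    recs <- y$traits %||% y
    df <- do.call(rbind, lapply(recs, function(r)
      data.frame(trait_id = r$trait_id, category = r$category,
                 sig_mode = r$sig_mode, path = r$path,
                 stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
  }
  need <- c("trait_id", "category", "sig_mode", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(df$category %in% c("quantitative", "disease")),
            all(df$sig_mode %in% c("pvalue", "log10bf")))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' Read one GWAS summary-statistics table
#'
#' Tab-separated with header. Required columns: `chrom`, `pos` (1-based),
#' and the score column for the trait's significance mode (`pvalue` or
#' `log10bf`). Optional: `variant_id`, `lead_id`. Variant identity is
#' `variant_id` when present and non-empty, else `"chrom:pos"`.
#'
#' @param path file path
#' @param trait one-row trait spec ([trait_spec()])
#' @return data.frame of records: `variant_id`, `variant_key`, `chrom`,
#'   `pos`, `trait_id`, `category`, `sig_mode`, `score`, `lead_id`
#' @export
read_gwas_table <- function(path, trait) {
  stopifnot(nrow(trait) == 1)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = NA,
                          na.strings = c("NA", ""))
  score_col <- trait$sig_mode
  need <- c("chrom", "pos", score_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) {
    return(data.frame(variant_id = character(), variant_key = character(),
                      chrom = character(), pos = numeric(),
                      trait_id = character(), category = character(),
                      sig_mode = character(), score = numeric(),
                      lead_id = character(), stringsAsFactors = FALSE))
  }
  score <- df[[score_col]]
  if (!is.numeric(score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(score))) & !is.na(score))
    if (length(bad))
      stop(sprintf("%s: line %d: non-numeric %s value '%s'",
                   path, bad[1] + 1L, score_col, score[bad[1]]))
    score <- as.numeric(score)
  }
  pos <- df$pos
  if (!is.numeric(pos)) stop(sprintf("%s: non-numeric pos column", path))
  if (any(pos < 1)) stop(sprintf("%s: positions must be >= 1 (1-based)", path))
  if (trait$sig_mode == "pvalue" &&
      any(!is.na(score) & (score <= 0 | score > 1)))
    stop(sprintf("%s: p-values must lie in (0, 1]", path))
  variant_id <- if ("variant_id" %in% names(df)) as.character(df$variant_id)
                else rep(NA_character_, nrow(df))
  key <- ifelse(is.na(variant_id) | variant_id == "",
                paste0(df$chrom, ":", format(pos, scientific = FALSE, trim = TRUE)),
                variant_id)
  data.frame(
    variant_id = variant_id,
    variant_key = key,
    chrom = as.character(df$chrom),
    pos = pos,
    trait_id = trait$trait_id,
    category = trait$category,
    sig_mode = trait$sig_mode,
    score = score,
    lead_id = if ("lead_id" %in% names(df)) as.character(df$lead_id)
              else rep(NA_character_, nrow(df)),
    stringsAsFactors = FALSE
  )
}

#' Filter records to genome-wide significance
#'
#' Strict thresholds: keeps p < 5e-8 for p-value traits and log10 BF > 6
#' for Bayes-factor traits. Records exactly at a threshold are excluded.
#' Duplicate (variant, trait) rows are collapsed to the most significant
#' one with a warning.
#'
#' @param records records from [read_gwas_table()] (one or more traits)
#' @return the significant subset, same columns
#' @export
filter_significant <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- ifelse(records$sig_mode == "pvalue",
                 !is.na(records$score) & records$score < GWAS_P_THRESHOLD,
                 !is.na(records$score) & records$score > GWAS_LOG10BF_THRESHOLD)
  out <- records[keep, , drop = FALSE]
  # dedupe per (trait, variant) keeping smallest p / largest log10 BF
  dupkey <- paste(out$trait_id, out$variant_key, sep = "\r")
  if (anyDuplicated(dupkey)) {
    warning("duplicate (variant, trait) rows collapsed to the most significant")
    rank_score <- ifelse(out$sig_mode == "pvalue", out$score, -out$score)
    o <- order(match(dupkey, unique(dupkey)), rank_score)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(dupkey[o]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
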