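#' PSI type codes
#'
#' The nine classes of primate-specific genomic information (PSI) elements
#' handled by the pipeline, keyed by the integer codes used in element files.
#' Types 6 (human-specific insertions, hsInsert) and 7 (primate-specific
#' transcriptional units, psTU) are the two classes without obvious
#' regulatory evidence; regions composed solely of them are flagged
#' non-regulatory.
#'
#' @format named character vector: code (as name) to brief type label
#' @export
psi_type_labels <- c(
  "1" = "HAR",      # human accelerated region
  "2" = "HGE",      # human gained enhancer (corticogenesis)
  "3" = "hbCRE",    # human-biased cis-regulatory element
  "4" = "psCRE",    # primate-specific cis-regulatory element (brain)
  "5" = "DNM",      # recurrent de novo mutation in neurodevelopmental CRE
  "6" = "hsInsert", # human-specific insertion
  "7" = "psTU",     # primate-specific transcriptional unit
  "8" = "haDHS",    # human accelerated DNase I hypersensitive site
  "9" = "hsGRE"     # hominin-specific gene regulatory element
)

#' Non-regulatory PSI type codes
#'
#' hsInsert (6) and psTU (7): the element classes lacking direct regulatory
#' evidence, used to split regions into regulatory vs non-regulatory.
#' @export
nonregulatory_types <- c(6L, 7L)
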