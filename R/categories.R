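#' Default ICD-chapter to category mapping
#'
#' The conventional grouping of ICD-10 chapters into phenome-scan categories
#' (circulatory, endocrine, respiratory, neoplasms, digestive, neurological,
#' musculoskeletal, gynecologic and obstetric, hematopoietic, dermatologic,
#' genitourinary, mental health, infectious diseases, sense organs, injuries
#' and poisonings, symptoms). Shipped as a plain TSV so users can substitute
#' their own table.
#'
#' @param path Optional path to an alternative mapping TSV with columns
#'   `code_start`, `code_end`, `category`.
#' @return Data.frame with columns `code_start`, `code_end`, `category`.
#' @export
icd_chapter_categories <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icd_chapter_categories.tsv",
                        package = "mrphewas")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assign phenome-scan categories from ICD codes
#'
#' Maps each ICD code to its chapter category through an inclusive code
#' range table (see [icd_chapter_categories()]). Codes matching no range —
#' including external-cause codes, which the default table deliberately
#' omits — return `"others"`.
#'
#' @param icd_code Character vector of ICD codes (letter + digits).
#' @param map Range table; defaults to the shipped chapter mapping.
#' @return Character vector of category names.
#' @export
#' @examples
#' assign_category(c("I25", "E11", "Z51"))
assign_category <- function(icd_code, map = icd_chapter_categories()) {
  key <- icd_sort_key(icd_code)
  lo <- icd_sort_key(map$code_start)
  hi <- icd_sort_key(map$code_end)
  out <- rep("others", length(icd_code))
  for (i in seq_along(icd_code)) {
    if (is.na(key[i])) next
    hit <- which(key[i] >= lo & key[i] <= hi)
    if (length(hit)) out[i] <- map$category[hit[1]]
  }
  out
}
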