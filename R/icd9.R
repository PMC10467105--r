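# ICD-9-CM top-level chapters and the rollup of per-disease code lists to
# a single chapter label.

#' The ICD-9-CM top-level chapter table
#'
#' Numeric code ranges with their chapter labels, plus the V/E
#' supplementary classifications.
#'
#' @return data.frame with columns `start`, `end`, `chapter`.
#' @export
icd9_chapters <- function() {
  data.frame(
    start = c(1, 140, 240, 280, 290, 320, 390, 460, 520, 580, 630, 680,
              710, 740, 760, 780, 800),
    end = c(139.999, 239.999, 279.999, 289.999, 319.999, 389.999, 459.999,
            519.999, 579.999, 629.999, 679.999, 709.999, 739.999, 759.999,
            779.999, 799.999, 999.999),
    chapter = c(
      "INFECTIOUS AND PARASITIC DISEASES",
      "NEOPLASMS",
      "ENDOCRINE, NUTRITIONAL AND METABOLIC DISEASES, AND IMMUNITY DISORDERS",
      "DISEASES OF THE BLOOD AND BLOOD-FORMING ORGANS",
      "MENTAL DISORDERS",
      "DISEASES OF THE NERVOUS SYSTEM AND SENSE ORGANS",
      "DISEASES OF THE CIRCULATORY SYSTEM",
      "DISEASES OF THE RESPIRATORY SYSTEM",
      "DISEASES OF THE DIGESTIVE SYSTEM",
      "DISEASES OF THE GENITOURINARY SYSTEM",
      "COMPLICATIONS OF PREGNANCY, CHILDBIRTH, AND THE PUERPERIUM",
      "DISEASES OF THE SKIN AND SUBCUTANEOUS TISSUE",
      "DISEASES OF THE MUSCULOSKELETAL SYSTEM AND CONNECTIVE TISSUE",
      "CONGENITAL ANOMALIES",
      "CERTAIN CONDITIONS ORIGINATING IN THE PERINATAL PERIOD",
      "SYMPTOMS, SIGNS, AND ILL-DEFINED CONDITIONS",
      "INJURY AND POISONING"),
    stringsAsFactors = FALSE)
}

icd9_chapter_of <- function(code) {
  code <- trimws(code)
  if (!nzchar(code)) return("UNCLASSIFIED")
  first <- toupper(substr(code, 1, 1))
  if (first == "V")
    return("SUPPLEMENTARY CLASSIFICATION OF FACTORS INFLUENCING HEALTH STATUS")
  if (first == "E")
    return("SUPPLEMENTARY CLASSIFICATION OF EXTERNAL CAUSES OF INJURY AND POISONING")
  num <- suppressWarnings(as.numeric(code))
  if (is.na(num)) return("UNCLASSIFIED")
  ch <- icd9_chapters()
  hit <- which(num >= ch$start & num <= ch$end)
  if (!length(hit)) return("UNCLASSIFIED")
  ch$chapter[hit[1]]
}

#' Roll a disease's ICD-9 codes up to one top-level chapter
#'
#' Each code maps to its chapter; when codes span several chapters the
#' more specific one wins: residual buckets (injury/poisoning "not
#' elsewhere classified" territory, ill-defined symptom codes,
#' supplementary classifications, unmappable codes) are avoided whenever a
#' specific disease chapter is available. Ties among specific chapters are
#' broken by the chapter of the lowest code. Unmappable codes land in
#' "UNCLASSIFIED", logged via `message()`.
#'
#' @param codes character vector of ICD-9 codes (e.g. `"401"`,
#'   `"997.91"`).
#' @return A single chapter label.
#' @export
icd9_rollup <- function(codes) {
  codes <- trimws(codes[nzchar(trimws(codes))])
  if (!length(codes)) return("UNCLASSIFIED")
  chapters <- vapply(codes, icd9_chapter_of, character(1))
  if (any(chapters == "UNCLASSIFIED"))
    message(sprintf("unmappable ICD-9 code(s): %s",
                    paste(codes[chapters == "UNCLASSIFIED"],
                          collapse = ", ")))
  residual <- c("INJURY AND POISONING",
                "SYMPTOMS, SIGNS, AND ILL-DEFINED CONDITIONS",
                "SUPPLEMENTARY CLASSIFICATION OF FACTORS INFLUENCING HEALTH STATUS",
                "SUPPLEMENTARY CLASSIFICATION OF EXTERNAL CAUSES OF INJURY AND POISONING",
                "UNCLASSIFIED")
  specific <- chapters[!chapters %in% residual]
  if (length(specific)) return(unname(specific[1]))
  unname(chapters[1])
}
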