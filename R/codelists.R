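#' Diagnostic categories recognised by the phenotyping algorithm
#'
#' Every clinical code in a diagnosis codelist maps to exactly one of these
#' categories. `DEPRESSION` codes count towards MDD case status;
#' `BIPOLAR`, `PSYCHOTIC` and `SUBSTANCE_USE` are exclusion categories;
#' `OTHER_PSYCHIATRIC` disqualifies a patient from the screened control set
#' without excluding them as a case; `NON_PSYCHIATRIC` is neutral.
#'
#' @export
DIAGNOSIS_CATEGORIES <- c(
  "DEPRESSION", "BIPOLAR", "PSYCHOTIC", "SUBSTANCE_USE",
  "OTHER_PSYCHIATRIC", "NON_PSYCHIATRIC"
)

#' Pharmacological classes recognised by the phenotyping algorithm
#' @export
DRUG_CLASSES <- c("ANTIDEPRESSANT", "ANTIPSYCHOTIC", "MOOD_STABILIZER", "OTHER")

EXCLUSION_CATEGORIES <- c("BIPOLAR", "PSYCHOTIC", "SUBSTANCE_USE")
PSYCHIATRIC_CATEGORIES <- c(
  "DEPRESSION", "BIPOLAR", "PSYCHOTIC", "SUBSTANCE_USE", "OTHER_PSYCHIATRIC"
)

#' Construct a codelist
#'
#' A codelist bundles the two lookup tables that turn raw coded records into
#' analysable events: a diagnosis map from clinical codes (Read v2 / CTV3) to
#' diagnostic categories, and a drug map from name patterns to canonical drug
#' identifiers and pharmacological classes. Lookups are total: codes absent
#' from the diagnosis map resolve to `NON_PSYCHIATRIC`, drug names with no
#' matching pattern resolve to class `OTHER`, and both fallbacks are counted
#' by the readers rather than dropped, so exclusion logic stays conservative.
#'
#' @param diagnosis data.frame with columns `code`, `category` (one of
#'   [DIAGNOSIS_CATEGORIES]).
#' @param drugs data.frame with columns `pattern`, `drug_id`, `class` (one of
#'   [DRUG_CLASSES]). Patterns are matched case-insensitively as prefixes of
#'   the prescribed product name; the longest matching pattern wins, which
#'   lets substance-level entries absorb product-level names such as
#'   "Citalopram 20mg tablets".
#' @return An object of class `codelist`.
#' @export
codelist <- function(diagnosis, drugs) {
  stopifnot(is.data.frame(diagnosis), is.data.frame(drugs))
  need_dx <- c("code", "category")
  need_rx <- c("pattern", "drug_id", "class")
  if (!all(need_dx %in% names(diagnosis)))
    stop("diagnosis codelist needs columns: ", paste(need_dx, collapse = ", "))
  if (!all(need_rx %in% names(drugs)))
    stop("drug codelist needs columns: ", paste(need_rx, collapse = ", "))
  bad <- setdiff(unique(diagnosis$category), DIAGNOSIS_CATEGORIES)
  if (length(bad)) stop("unknown diagnosis categories: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(drugs$class), DRUG_CLASSES)
  if (length(bad)) stop("unknown drug classes: ", paste(bad, collapse = ", "))
  if (anyDuplicated(diagnosis$code))
    stop("each clinical code must map to exactly one category")
  drugs$pattern <- tolower(trimws(drugs$pattern))
  if (anyDuplicated(drugs$pattern))
    stop("duplicated drug patterns in codelist")
  structure(
    list(
      diagnosis = data.frame(
        code = as.character(diagnosis$code),
        category = as.character(diagnosis$category),
        stringsAsFactors = FALSE
      ),
      drugs = data.frame(
        pattern = drugs$pattern,
        drug_id = as.character(drugs$drug_id),
        class = as.character(drugs$class),
        stringsAsFactors = FALSE
      )
    ),
    class = "codelist"
  )
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist>", nrow(x$diagnosis), "clinical codes,",
      nrow(x$drugs), "drug patterns\n")
  invisible(x)
}

#' Read codelists from delimited files
#'
#' The diagnosis file has columns `code, category`; the drug file has
#' `pattern, drug_id, class`. Comma- and tab-delimited files are both
#' accepted (the delimiter is sniffed from the header line).
#'
#' @param diagnosis_path,drugs_path paths to the two codelist files.
#' @return A [codelist].
#' @export
read_codelists <- function(diagnosis_path, drugs_path) {
  codelist(
    diagnosis = read_delim_auto(diagnosis_path),
    drugs = read_delim_auto(drugs_path)
  )
}

#' Write a codelist to a pair of delimited files
#' @param x a [codelist].
#' @param diagnosis_path,drugs_path output paths (tab-delimited).
#' @export
write_codelists <- function(x, diagnosis_path, drugs_path) {
  stopifnot(inherits(x, "codelist"))
  utils::write.table(x$diagnosis, diagnosis_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$drugs, drugs_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Illustrative synthetic codelists
#'
#' A small, entirely synthetic codelist covering the diagnostic categories
#' and drug classes the algorithm needs. The clinical codes imitate the shape
#' of Read v2 codes but are not a clinical resource: real analyses should
#' supply curated codelists as input. The drug map lists common
#' antidepressants, two antipsychotics and two mood stabilizers at substance
#' level, which the longest-prefix matcher extends to product-level names.
#'
#' @return A [codelist].
#' @export
example_codelists <- function() {
  diagnosis <- data.frame(
    code = c("E112.", "E113.", "Eu32.", "Eu33.", "E2B..",
             "E11y.", "Eu31.",
             "Eu20.", "E10..",
             "Eu10.", "E23..",
             "E200.", "Eu41.",
             "H33..", "G30.."),
    category = c(rep("DEPRESSION", 5),
                 rep("BIPOLAR", 2),
                 rep("PSYCHOTIC", 2),
                 rep("SUBSTANCE_USE", 2),
                 rep("OTHER_PSYCHIATRIC", 2),
                 rep("NON_PSYCHIATRIC", 2)),
    stringsAsFactors = FALSE
  )
  ad <- c("citalopram", "sertraline", "fluoxetine", "paroxetine",
          "venlafaxine", "mirtazapine", "amitriptyline", "duloxetine")
  ap <- c("quetiapine", "olanzapine")
  ms <- c("lithium", "valproate")
  drugs <- data.frame(
    pattern = c(ad, ap, ms),
    drug_id = c(ad, ap, ms),
    class = c(rep("ANTIDEPRESSANT", length(ad)),
              rep("ANTIPSYCHOTIC", length(ap)),
              rep("MOOD_STABILIZER", length(ms))),
    stringsAsFactors = FALSE
  )
  codelist(diagnosis, drugs)
}

#' Map clinical codes to diagnostic categories
#'
#' Total lookup: codes not present in the codelist map to `NON_PSYCHIATRIC`.
#'
#' @param code character vector of clinical codes.
#' @param codelist a [codelist].
#' @return list with `category` (character vector) and `n_unknown`
#'   (count of codes that fell through to the neutral category).
#' @export
map_diagnosis_codes <- function(code, codelist) {
  stopifnot(inherits(codelist, "codelist"))
  idx <- match(as.character(code), codelist$diagnosis$code)
  category <- codelist$diagnosis$category[idx]
  n_unknown <- sum(is.na(idx) & !is.na(code) & nzchar(code))
  category[is.na(category)] <- "NON_PSYCHIATRIC"
  list(category = category, n_unknown = n_unknown)
}

#' Canonicalise prescribed drug names
#'
#' Product names mix substance-level and product-level spellings
#' ("Citalopram", "citalopram 20mg tablets"). Names are lower-cased and
#' matched against codelist patterns by longest prefix; the winning pattern's
#' `drug_id` and `class` are assigned. Unmatched names keep their lower-cased
#' spelling as `drug_id` with class `OTHER` and are counted, never dropped.
#'
#' @param drug_name character vector of prescribed product names.
#' @param codelist a [codelist].
#' @return list with `drug_id`, `class` (character vectors) and `n_unmapped`.
#' @export
canonicalise_drug <- function(drug_name, codelist) {
  stopifnot(inherits(codelist, "codelist"))
  name <- tolower(trimws(as.character(drug_name)))
  pats <- codelist$drugs$pattern
  # longest pattern first so the first prefix hit is the longest match
  ord <- order(-nchar(pats))
  pats <- pats[ord]
  ids <- codelist$drugs$drug_id[ord]
  cls <- codelist$drugs$class[ord]
  drug_id <- name
  class <- rep("OTHER", length(name))
  unmatched <- rep(TRUE, length(name))
  for (i in seq_along(pats)) {
    hit <- unmatched & startsWith(name, pats[i])
    if (any(hit)) {
      drug_id[hit] <- ids[i]
      class[hit] <- cls[i]
      unmatched[hit] <- FALSE
    }
  }
  list(drug_id = drug_id, class = class, n_unmapped = sum(unmatched & nzchar(name)))
}
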