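# Concept identity: UMLS CUI sets, canonical keys, validation.
#
# A medical concept is identified by a non-empty set of UMLS Concept Unique
# Identifiers (CUIs, "C" + 7 digits). One CUI = precoordinated concept;
# two or more = postcoordinated combination (e.g. "Hemorrhage" + "Location").
# Identity is the unordered, deduplicated CUI set; the canonical rendering
# is the sorted, space-joined string, which serves as the counting key
# throughout the package.

.cui_pattern <- "^C[0-9]{7}$"

#' Test whether strings are syntactically valid UMLS CUIs
#'
#' A valid CUI is the letter `C` followed by exactly seven decimal digits.
#' No Metathesaurus lookup is performed; codes are opaque validated strings.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
#' @examples
#' is_cui(c("C0001779", "c0001779", "C123"))
is_cui <- function(x) {
  !is.na(x) & grepl(.cui_pattern, x)
}

#' Construct a concept code from CUIs
#'
#' Deduplicates and sorts the CUIs; a single CUI gives a precoordinated
#' concept, two or more a postcoordinated one.
#'
#' @param cuis character vector of CUIs.
#' @return a `concept_code` object (sorted unique character vector).
#' @export
concept_code <- function(cuis) {
  cuis <- unique(as.character(cuis))
  if (length(cuis) == 0) {
    stop("concept_code requires at least one CUI", call. = FALSE)
  }
  bad <- cuis[!is_cui(cuis)]
  if (length(bad) > 0) {
    stop("invalid CUI token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(sort(cuis), class = "concept_code")
}

#' Parse an annotation string into a concept code
#'
#' Splits on whitespace and validates every token as a CUI. Order and
#' duplication in the input are irrelevant: `"C0450429 C0019080 C0019080"`
#' yields the same concept as `"C0019080 C0450429"`.
#'
#' @param text annotation string, e.g. `"C0001779"` or `"C0019080 C0450429"`.
#' @return a `concept_code`.
#' @export
#' @examples
#' parse_concept("C0019080 C0450429")
parse_concept <- function(text) {
  if (length(text) != 1 || is.na(text)) {
    stop("annotation must be a single non-NA string", call. = FALSE)
  }
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    stop("empty annotation string", call. = FALSE)
  }
  concept_code(tokens)
}

#' Canonical key of a concept code
#'
#' The lexicographically sorted CUIs joined by single spaces. Two concept
#' codes are the same concept iff their canonical keys are equal.
#'
#' @param code a `concept_code` or character vector of CUIs.
#' @return single string.
#' @export
canonical_key <- function(code) {
  if (!inherits(code, "concept_code")) code <- concept_code(code)
  paste(code, collapse = " ")
}

#' Is a concept code postcoordinated?
#'
#' @param code a `concept_code` or canonical key string.
#' @return `TRUE` when the concept combines two or more CUIs.
#' @export
is_postcoordinated <- function(code) {
  if (inherits(code, "concept_code")) return(length(code) >= 2)
  grepl(" ", code, fixed = TRUE)
}

#' @export
print.concept_code <- function(x, ...) {
  kind <- if (length(x) >= 2) "postcoordinated" else "precoordinated"
  cat("<concept_code> ", paste(x, collapse = " "), " (", kind, ")\n", sep = "")
  invisible(x)
}

#' @export
format.concept_code <- function(x, ...) paste(x, collapse = " ")
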