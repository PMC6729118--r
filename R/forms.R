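# Containers: annotated items, form documents, corpora.
#
# A corpus is a list of form documents, each labeled with a documentation
# context (routine, registry, study_crf, eligibility, quality_assurance,
# recommendation, risk_score, or any user-defined label). Items are ordered
# within a form; an item may carry a concept code, be uncoded (no suitable
# annotation found), or be excluded from all statistics with a reason.

.datatypes <- c("text", "integer", "float", "boolean", "date", "datetime",
                "codelist")
.exclusion_reasons <- c("none", "nondistinct", "administrative")

#' Seed set of documentation-context labels
#'
#' The context taxonomy is an open set; these are the labels used for
#' multi-context ACS-style form collections. Any non-empty string is a
#' valid context.
#'
#' @return character vector.
#' @export
context_labels <- function() {
  c("routine", "registry", "study_crf", "eligibility",
    "quality_assurance", "recommendation", "risk_score")
}

#' Construct one annotated form item
#'
#' @param item_id opaque identifier, unique within the form.
#' @param name short item name.
#' @param question prompt text; may be empty.
#' @param datatype one of `text`, `integer`, `float`, `boolean`, `date`,
#'   `datetime`, `codelist`.
#' @param code optional `concept_code` (or character vector of CUIs, or a
#'   canonical key string); `NULL` means no suitable annotation was found.
#' @param excluded exclusion flag: `"none"`, `"nondistinct"` or
#'   `"administrative"`. Excluded items never contribute to any statistic.
#' @return an `annotated_item`.
#' @export
annotated_item <- function(item_id, name = item_id, question = "",
                           datatype = "text", code = NULL,
                           excluded = "none") {
  stopifnot(is.character(item_id), length(item_id) == 1, nzchar(item_id))
  datatype <- match.arg(datatype, .datatypes)
  excluded <- match.arg(excluded, .exclusion_reasons)
  if (!is.null(code) && !inherits(code, "concept_code")) {
    code <- if (length(code) == 1 && grepl(" ", code)) {
      parse_concept(code)
    } else {
      concept_code(code)
    }
  }
  structure(
    list(item_id = item_id, name = name, question = question,
         datatype = datatype, code = code, excluded = excluded),
    class = "annotated_item"
  )
}

#' Construct a form document
#'
#' @param form_id opaque identifier, unique within a corpus.
#' @param title human-readable form name.
#' @param context documentation-context label (non-empty string).
#' @param items list of [annotated_item()]s, order significant.
#' @return a `form_document`.
#' @export
form_document <- function(form_id, title = form_id, context, items = list()) {
  stopifnot(is.character(form_id), length(form_id) == 1, nzchar(form_id))
  stopifnot(is.character(context), length(context) == 1, nzchar(context))
  if (!all(vapply(items, inherits, logical(1), "annotated_item"))) {
    stop("items must all be annotated_item objects", call. = FALSE)
  }
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    stop("duplicate item_id within form '", form_id, "'", call. = FALSE)
  }
  structure(
    list(form_id = form_id, title = title, context = context, items = items),
    class = "form_document"
  )
}

#' Bundle form documents into a corpus
#'
#' @param forms list of [form_document()]s with unique `form_id`s.
#' @return a `form_corpus` (a classed list of forms).
#' @export
form_corpus <- function(forms) {
  if (!all(vapply(forms, inherits, logical(1), "form_document"))) {
    stop("forms must all be form_document objects", call. = FALSE)
  }
  ids <- vapply(forms, `[[`, character(1), "form_id")
  if (anyDuplicated(ids)) {
    stop("duplicate form_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(forms, class = "form_corpus")
}

#' Flatten a corpus into one row per item
#'
#' The long table that drives every downstream statistic. `key` is the
#' canonical concept key (`NA` for uncoded items), `coded` whether a concept
#' is attached, `excluded` whether the item is flagged out of all counts.
#'
#' @param corpus a `form_corpus` or list of `form_document`s.
#' @return data.frame with columns `form_id`, `context`, `item_id`, `name`,
#'   `question`, `datatype`, `key`, `coded`, `excluded`, `exclusion_reason`.
#' @export
corpus_items <- function(corpus) {
  rows <- lapply(corpus, function(f) {
    if (length(f$items) == 0) return(NULL)
    data.frame(
      form_id = f$form_id,
      context = f$context,
      item_id = vapply(f$items, `[[`, character(1), "item_id"),
      name = vapply(f$items, `[[`, character(1), "name"),
      question = vapply(f$items, `[[`, character(1), "question"),
      datatype = vapply(f$items, `[[`, character(1), "datatype"),
      key = vapply(f$items, function(it)
        if (is.null(it$code)) NA_character_ else canonical_key(it$code),
        character(1)),
      exclusion_reason = vapply(f$items, `[[`, character(1), "excluded"),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(out)) {
    out <- data.frame(
      form_id = character(), context = character(), item_id = character(),
      name = character(), question = character(), datatype = character(),
      key = character(), exclusion_reason = character(),
      stringsAsFactors = FALSE
    )
  }
  out$coded <- !is.na(out$key)
  out$excluded <- out$exclusion_reason != "none"
  out
}

#' @export
print.form_document <- function(x, ...) {
  n_coded <- sum(vapply(x$items, function(it) !is.null(it$code), logical(1)))
  cat("<form_document> ", x$form_id, " (", x$context, "): ",
      length(x$items), " items, ", n_coded, " coded\n", sep = "")
  invisible(x)
}

#' @export
print.form_corpus <- function(x, ...) {
  items <- corpus_items(x)
  cat("<form_corpus> ", length(x), " forms, ", nrow(items), " items across ",
      length(unique(items$context)), " context(s)\n", sep = "")
  invisible(x)
}
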