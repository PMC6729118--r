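# Common-data-element list: filtering, categorization, export.
#
# A concept enters the CDE list when it occurs at least `min_frequency`
# times across the corpus AND appears in at least `min_contexts`
# documentation contexts (defaults 2 and 2). Category assignment and
# display names come from user-supplied maps — the expert-review step is
# represented declaratively, never automated.

.default_categories <- c("patient data", "timepoints", "patient history",
                         "laboratory", "medication", "procedures",
                         "examinations", "diagnosis", "ECG", "outcome")

#' Default CDE category list
#'
#' @return character vector of the seeded category names (user-extensible
#'   via the `categories` argument of [assign_categories()]).
#' @export
cde_categories <- function() .default_categories

#' Generate a common-data-element list
#'
#' Filters the corpus-wide concept frequency table by the two inclusion
#' rules (minimum total occurrences; minimum number of distinct
#' documentation contexts) and orders entries by frequency descending,
#' ties broken by concept key.
#'
#' @param corpus a `form_corpus`, parsed and (optionally) cleaned.
#' @param min_frequency minimum absolute occurrence count (default 2;
#'   concepts appearing only once are dropped).
#' @param min_contexts minimum number of distinct contexts (default 2).
#' @param denominator_mode passed to [count_frequencies()].
#' @return a `cde_list`: data.frame with columns `concept_key`,
#'   `display_name`, `absolute_frequency`, `relative_frequency_pct`,
#'   `contexts` (semicolon-joined), `n_contexts`, `category`
#'   (all `"uncategorized"` until [assign_categories()]). Attribute
#'   `provenance` records the corpus fingerprint and parameters.
#' @export
generate_cde_list <- function(corpus, min_frequency = 2, min_contexts = 2,
                              denominator_mode = "all_items") {
  items <- corpus_items(corpus)
  n_ctx_corpus <- length(unique(items$context))
  if (n_ctx_corpus < min_contexts) {
    stop("corpus has only ", n_ctx_corpus, " distinct context(s); ",
         "min_contexts = ", min_contexts, " is unreachable ",
         "(lower it explicitly if intended)", call. = FALSE)
  }
  tab <- count_frequencies(corpus, denominator_mode = denominator_mode)
  n_contexts <- lengths(strsplit(tab$contexts, ";", fixed = TRUE))
  keep <- tab$absolute_frequency >= min_frequency & n_contexts >= min_contexts
  entries <- data.frame(
    concept_key = tab$key[keep],
    display_name = tab$key[keep],
    absolute_frequency = tab$absolute_frequency[keep],
    relative_frequency_pct = tab$relative_frequency_pct[keep],
    contexts = tab$contexts[keep],
    n_contexts = n_contexts[keep],
    category = rep("uncategorized", sum(keep)),
    stringsAsFactors = FALSE
  )
  entries <- entries[order(-entries$absolute_frequency, entries$concept_key), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(
    entries,
    provenance = list(
      corpus_fingerprint = fingerprint(items[order(items$form_id,
                                                   items$item_id), ]),
      parameters = list(min_frequency = min_frequency,
                        min_contexts = min_contexts,
                        denominator_mode = denominator_mode),
      n_forms = length(corpus)
    ),
    class = c("cde_list", "data.frame")
  )
}

#' Assign categories and display names to a CDE list
#'
#' @param list a `cde_list`.
#' @param category_map named character vector or two-column data.frame
#'   (`concept_key`, `category`); unmapped entries stay `uncategorized`.
#' @param name_map optional named character vector `concept_key ->
#'   display_name`.
#' @param categories allowed category names; a map naming a category
#'   outside this list is a configuration error.
#' @return the `cde_list` with categories (and names) filled in; entry
#'   count unchanged.
#' @export
assign_categories <- function(list, category_map = NULL, name_map = NULL,
                              categories = cde_categories()) {
  stopifnot(inherits(list, "cde_list"))
  if (is.data.frame(category_map)) {
    stopifnot(all(c("concept_key", "category") %in% names(category_map)))
    category_map <- stats::setNames(category_map$category,
                                    category_map$concept_key)
  }
  if (!is.null(category_map) && length(category_map) > 0) {
    unknown <- setdiff(unique(unname(category_map)), categories)
    if (length(unknown) > 0) {
      stop("category map uses unknown categories: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    hit <- list$concept_key %in% names(category_map)
    list$category[hit] <- unname(category_map[list$concept_key[hit]])
  }
  if (!is.null(name_map) && length(name_map) > 0) {
    hit <- list$concept_key %in% names(name_map)
    list$display_name[hit] <- unname(name_map[list$concept_key[hit]])
  }
  list
}

#' Read a two-column category map CSV
#'
#' Header `concept_key,category`.
#'
#' @param path CSV file.
#' @return data.frame usable in [assign_categories()].
#' @export
read_category_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("concept_key", "category") %in% names(df))) {
    stop("category map CSV must have columns concept_key,category",
         call. = FALSE)
  }
  df
}

#' Export a CDE list
#'
#' `csv` writes one row per entry with all fields (contexts
#' semicolon-joined, relative frequency rounded half-up). `odm` renders
#' the list as a single ODM form with one item per entry carrying its
#' UMLS alias; re-reading that file reproduces the concept-key set.
#'
#' @param list a `cde_list`.
#' @param path output file.
#' @param format `"csv"` or `"odm"`.
#' @param digits rounding for the CSV relative frequency column.
#' @return `path`, invisibly.
#' @export
export_cde <- function(list, path, format = c("csv", "odm"), digits = 1) {
  stopifnot(inherits(list, "cde_list"))
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown CDE export format; supported: csv, odm", call. = FALSE))
  if (format == "csv") {
    out <- as.data.frame(list)
    out$relative_frequency_pct <- round_half_up(out$relative_frequency_pct,
                                                digits)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    items <- lapply(seq_len(nrow(list)), function(i) {
      annotated_item(
        item_id = sprintf("CDE.%04d", i),
        name = list$display_name[i],
        question = sprintf("Common data element: %s", list$display_name[i]),
        datatype = "text",
        code = parse_concept(list$concept_key[i])
      )
    })
    form <- form_document(form_id = "CDE.LIST",
                          title = "Common data elements",
                          context = "recommendation", items = items)
    write_odm(form, path)
  }
  invisible(path)
}

#' @export
print.cde_list <- function(x, ...) {
  cat("<cde_list> ", nrow(x), " entries",
      " (min_frequency = ",
      attr(x, "provenance")$parameters$min_frequency,
      ", min_contexts = ",
      attr(x, "provenance")$parameters$min_contexts, ")\n", sep = "")
  NextMethod()
}
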