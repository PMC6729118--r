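# Context merging and pairwise concept-set overlap.
#
# Overlap statistics operate on UNIQUE concept sets (frequencies ignored)
# and report directional relative overlap |A intersect B| / |A| for each
# side of a pair — not Jaccard, which is offered as an extra. Matching is
# exact on canonical keys; no semantic similarity between distinct CUIs.

#' Construct a labeled concept set
#'
#' @param label context or hospital name.
#' @param keys character vector of canonical concept keys (deduplicated).
#' @return a `concept_set`.
#' @export
concept_set <- function(label, keys = character()) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  structure(list(label = label, keys = sort(unique(as.character(keys)))),
            class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat("<concept_set> ", x$label, ": ", length(x$keys), " unique concepts\n",
      sep = "")
  invisible(x)
}

#' Merge forms into one unique-concept set
#'
#' Union of canonical keys over the non-excluded coded items of the given
#' forms — the per-context merge used before pairwise comparison.
#' Idempotent and order-invariant.
#'
#' @param forms a `form_corpus` or list of `form_document`s.
#' @param label set label; defaults to the forms' shared context (an error
#'   if they disagree and no label is given).
#' @return a `concept_set`.
#' @export
merge_context <- function(forms, label = NULL) {
  if (length(forms) == 0) {
    warning("merging zero forms: empty concept set", call. = FALSE)
    return(concept_set(label %||% "empty"))
  }
  contexts <- unique(vapply(forms, `[[`, character(1), "context"))
  if (is.null(label)) {
    if (length(contexts) != 1) {
      stop("forms span several contexts (", paste(contexts, collapse = ", "),
           "); supply an explicit label", call. = FALSE)
    }
    label <- contexts
  }
  items <- corpus_items(forms)
  keys <- items$key[items$coded & !items$excluded]
  concept_set(label, unique(keys))
}

#' Split a corpus into per-context concept sets
#'
#' @param corpus a `form_corpus`.
#' @return named list of `concept_set`s, one per context, in first-seen
#'   order of contexts.
#' @export
context_sets <- function(corpus) {
  contexts <- unique(vapply(corpus, `[[`, character(1), "context"))
  sets <- lapply(contexts, function(ctx) {
    merge_context(Filter(function(f) f$context == ctx, corpus), label = ctx)
  })
  stats::setNames(sets, contexts)
}

#' Pairwise overlap of two concept sets
#'
#' Reports both directional relative overlaps: `rel_a` = mutual / |A| and
#' `rel_b` = mutual / |B|, in percent at full precision, plus display
#' values rounded half-up at the chosen precision. An empty side yields
#' `NA` for that side's relative overlap.
#'
#' @param a,b `concept_set`s.
#' @param precision decimal places of the display rounding (0 renders
#'   integers, as some published tables do).
#' @return an `overlap_result`: list with `label_a`, `label_b`, `size_a`,
#'   `size_b`, `mutual`, `rel_a`, `rel_b` (full precision),
#'   `rel_a_display`, `rel_b_display`, `jaccard`.
#' @export
pairwise_overlap <- function(a, b, precision = 1) {
  stopifnot(inherits(a, "concept_set"), inherits(b, "concept_set"))
  mutual <- length(intersect(a$keys, b$keys))
  union_n <- length(union(a$keys, b$keys))
  rel <- function(size) if (size == 0) NA_real_ else mutual / size * 100
  rel_a <- rel(length(a$keys))
  rel_b <- rel(length(b$keys))
  structure(
    list(
      label_a = a$label, label_b = b$label,
      size_a = length(a$keys), size_b = length(b$keys),
      mutual = mutual,
      rel_a = rel_a, rel_b = rel_b,
      rel_a_display = round_half_up(rel_a, precision),
      rel_b_display = round_half_up(rel_b, precision),
      jaccard = if (union_n == 0) NA_real_ else mutual / union_n
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s (%d) vs %s (%d): %d mutual (%.1f%% / %.1f%%)\n",
              x$label_a, x$size_a, x$label_b, x$size_b, x$mutual,
              x$rel_a, x$rel_b))
  invisible(x)
}

#' All pairwise overlaps between concept sets
#'
#' Every unordered pair exactly once, in input order of the sets.
#'
#' @param sets list of `concept_set`s with distinct labels (at least 2).
#' @param precision display rounding, see [pairwise_overlap()].
#' @return an `overlap_matrix` data.frame in long format with columns
#'   `label_a`, `label_b`, `size_a`, `size_b`, `mutual`, `rel_a_pct`,
#'   `rel_b_pct` (full precision), `rel_a_display`, `rel_b_display`,
#'   `jaccard`.
#' @export
overlap_matrix <- function(sets, precision = 1) {
  if (length(sets) < 2) stop("need at least two concept sets", call. = FALSE)
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate set labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(length(sets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ov <- pairwise_overlap(sets[[pairs[1, j]]], sets[[pairs[2, j]]],
                           precision = precision)
    data.frame(label_a = ov$label_a, label_b = ov$label_b,
               size_a = ov$size_a, size_b = ov$size_b, mutual = ov$mutual,
               rel_a_pct = ov$rel_a, rel_b_pct = ov$rel_b,
               rel_a_display = ov$rel_a_display,
               rel_b_display = ov$rel_b_display,
               jaccard = ov$jaccard, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("overlap_matrix", "data.frame"))
}

#' Concepts common to every set
#'
#' @param sets list of `concept_set`s (at least 2).
#' @param label label of the result set.
#' @return a `concept_set` holding the intersection of all inputs.
#' @export
common_core <- function(sets, label = "common_core") {
  if (length(sets) < 2) stop("need at least two concept sets", call. = FALSE)
  keys <- Reduce(intersect, lapply(sets, `[[`, "keys"))
  concept_set(label, keys)
}

#' Export an overlap matrix
#'
#' Writes the long-format table and, optionally, a square matrix of
#' directional relative overlaps (row label's set as denominator).
#'
#' @param m an `overlap_matrix`.
#' @param path long-format CSV path.
#' @param square_path optional square-matrix CSV path.
#' @param digits half-up rounding applied to percentage columns on export.
#' @return `path`, invisibly.
#' @export
export_overlap_csv <- function(m, path, square_path = NULL, digits = 1) {
  out <- data.frame(
    label_a = m$label_a, label_b = m$label_b,
    size_a = m$size_a, size_b = m$size_b, mutual = m$mutual,
    rel_a_pct = round_half_up(m$rel_a_pct, digits),
    rel_b_pct = round_half_up(m$rel_b_pct, digits),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(square_path)) {
    labels <- unique(c(m$label_a, m$label_b))
    sq <- matrix(100, length(labels), length(labels),
                 dimnames = list(labels, labels))
    for (i in seq_len(nrow(m))) {
      sq[m$label_a[i], m$label_b[i]] <- round_half_up(m$rel_a_pct[i], digits)
      sq[m$label_b[i], m$label_a[i]] <- round_half_up(m$rel_b_pct[i], digits)
    }
    utils::write.csv(as.data.frame(sq), square_path, row.names = TRUE)
  }
  invisible(path)
}
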