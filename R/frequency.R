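# Concept frequency, annotation coverage, and the cumulative coverage curve.
#
# Counts run over non-excluded items only. Occurrences of the same concept
# within one form count separately (follow-up subforms re-ask questions).
# The relative-frequency denominator defaults to all (non-excluded) items,
# including uncoded ones, because published tables in this domain express
# concept shares against the full item total; a coded-items-only
# denominator is available as an option.

#' Concept frequency table
#'
#' One row per unique canonical concept key over the non-excluded, coded
#' items of the corpus, with absolute occurrence counts and relative
#' frequencies in percent.
#'
#' @param corpus a `form_corpus`.
#' @param denominator_mode `"all_items"` (default: all non-excluded items,
#'   coded or not) or `"coded_items"`.
#' @return a `concept_freq` data.frame with columns `key`,
#'   `absolute_frequency`, `relative_frequency_pct` (full precision),
#'   `contexts` (semicolon-joined labels where the concept occurs), sorted
#'   by frequency descending with ties broken by key. Attribute `totals`
#'   is a list: `total_items`, `coded_items`, `unique_concepts`,
#'   `postcoordinated_unique`, `singleton_unique`;
#'   attribute `denominator_mode` echoes the mode.
#' @export
count_frequencies <- function(corpus,
                              denominator_mode = c("all_items",
                                                   "coded_items")) {
  denominator_mode <- match.arg(denominator_mode)
  items <- corpus_items(corpus)
  live <- items[!items$excluded, , drop = FALSE]
  coded <- live[live$coded, , drop = FALSE]

  if (nrow(coded) == 0) {
    tab <- data.frame(key = character(), absolute_frequency = integer(),
                      relative_frequency_pct = numeric(),
                      contexts = character(), stringsAsFactors = FALSE)
  } else {
    counts <- table(coded$key)
    ctx <- vapply(split(coded$context, coded$key), function(x)
      paste(sort(unique(x)), collapse = ";"), character(1))
    tab <- data.frame(key = names(counts),
                      absolute_frequency = as.integer(counts),
                      contexts = unname(ctx[names(counts)]),
                      stringsAsFactors = FALSE)
    denom <- if (denominator_mode == "all_items") nrow(live) else nrow(coded)
    tab$relative_frequency_pct <- tab$absolute_frequency / denom * 100
    tab <- tab[order(-tab$absolute_frequency, tab$key), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab <- tab[, c("key", "absolute_frequency", "relative_frequency_pct",
                   "contexts")]
  }

  totals <- list(
    total_items = nrow(live),
    coded_items = nrow(coded),
    unique_concepts = nrow(tab),
    postcoordinated_unique = sum(is_postcoordinated(tab$key)),
    singleton_unique = sum(tab$absolute_frequency == 1)
  )
  structure(tab, totals = totals, denominator_mode = denominator_mode,
            class = c("concept_freq", "data.frame"))
}

#' Annotation coverage of a corpus
#'
#' Share of non-excluded items that carry at least one UMLS code,
#' in percent, conventionally reported with two decimals (3637 coded of
#' 3710 -> 98.03).
#'
#' @param corpus a `form_corpus`.
#' @param digits decimal places for half-up rounding; `NULL` for full
#'   precision.
#' @return percentage, or `NA_real_` for an itemless corpus (coverage is
#'   undefined there, never 0 or 100).
#' @export
annotation_coverage <- function(corpus, digits = 2) {
  items <- corpus_items(corpus)
  live <- items[!items$excluded, , drop = FALSE]
  if (nrow(live) == 0) return(NA_real_)
  pct <- sum(live$coded) / nrow(live) * 100
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Cumulative coverage curve
#'
#' Sorts concepts by absolute frequency descending (ties broken by key
#' ascending) and accumulates occurrence percentages: the value at rank r
#' is the share of all coded occurrences captured by the r most frequent
#' concepts. The final point is 100.
#'
#' @param table a `concept_freq` from [count_frequencies()].
#' @return a `coverage_curve` data.frame with columns `rank`, `key`,
#'   `absolute_frequency`, `cumulative_pct`.
#' @export
cumulative_coverage <- function(table) {
  stopifnot(inherits(table, "concept_freq"))
  if (nrow(table) == 0) {
    return(structure(
      data.frame(rank = integer(), key = character(),
                 absolute_frequency = integer(), cumulative_pct = numeric(),
                 stringsAsFactors = FALSE),
      class = c("coverage_curve", "data.frame")))
  }
  ord <- order(-table$absolute_frequency, table$key)
  freq <- table$absolute_frequency[ord]
  coded <- sum(freq)
  out <- data.frame(
    rank = seq_along(freq),
    key = table$key[ord],
    absolute_frequency = freq,
    cumulative_pct = cumsum(freq) / coded * 100,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("coverage_curve", "data.frame"))
}

#' Smallest head covering a given share of occurrences
#'
#' The minimal rank r whose cumulative coverage reaches the threshold
#' (comparison is `>=`: hitting exactly 50.000 counts as covering 50).
#'
#' @param curve a `coverage_curve`.
#' @param threshold_pct percentage in (0, 100].
#' @return integer rank.
#' @export
head_size_for_coverage <- function(curve, threshold_pct) {
  stopifnot(inherits(curve, "coverage_curve"))
  if (nrow(curve) == 0) stop("empty coverage curve", call. = FALSE)
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  }
  # tolerate display-level floating error at the 100% endpoint
  idx <- which(curve$cumulative_pct >= threshold_pct - 1e-9)
  if (length(idx) == 0) nrow(curve) else idx[[1]]
}

#' Vocabulary summary statistics
#'
#' @param table a `concept_freq`.
#' @param digits decimal places for the postcoordinated share (half-up).
#' @return list: `unique_concepts`, `postcoordinated_unique`,
#'   `postcoordinated_share_pct`, `singleton_unique`,
#'   `singleton_share_pct`, and `singleton_tail_start` — the first rank of
#'   the sorted table from which every concept occurs exactly once
#'   (`NA` when there are no singletons).
#' @export
vocabulary_stats <- function(table, digits = 1) {
  stopifnot(inherits(table, "concept_freq"))
  totals <- attr(table, "totals")
  n <- totals$unique_concepts
  share <- function(x) {
    if (n == 0) return(NA_real_)
    round_half_up(x / n * 100, digits)
  }
  curve_order <- order(-table$absolute_frequency, table$key)
  freq_sorted <- table$absolute_frequency[curve_order]
  tail_start <- if (totals$singleton_unique == 0) NA_integer_ else
    which(freq_sorted == 1)[[1]]
  list(
    unique_concepts = n,
    postcoordinated_unique = totals$postcoordinated_unique,
    postcoordinated_share_pct = share(totals$postcoordinated_unique),
    singleton_unique = totals$singleton_unique,
    singleton_share_pct = share(totals$singleton_unique),
    singleton_tail_start = tail_start
  )
}

#' Export a frequency table to CSV
#'
#' Columns: `concept_key`, `absolute_frequency`, `relative_frequency_pct`
#' (rounded per `digits`), `contexts_present`. Output is deterministic for
#' a given table.
#'
#' @param table a `concept_freq`.
#' @param path output CSV path.
#' @param digits half-up rounding for the relative frequency column.
#' @return `path`, invisibly.
#' @export
export_frequency_csv <- function(table, path, digits = 1) {
  out <- data.frame(
    concept_key = table$key,
    absolute_frequency = table$absolute_frequency,
    relative_frequency_pct = round_half_up(table$relative_frequency_pct,
                                           digits),
    contexts_present = table$contexts,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a coverage curve to CSV
#'
#' @param curve a `coverage_curve`.
#' @param path output CSV path.
#' @param digits half-up rounding for the cumulative percentage.
#' @return `path`, invisibly.
#' @export
export_curve_csv <- function(curve, path, digits = 2) {
  out <- data.frame(
    rank = curve$rank,
    cumulative_pct = round_half_up(curve$cumulative_pct, digits),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot a cumulative coverage curve
#'
#' Rank versus cumulative percentage of concept occurrences, with optional
#' horizontal threshold markers (e.g. 25/50/75).
#'
#' @param curve a `coverage_curve`.
#' @param thresholds percentages to mark.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the marked ranks (named by threshold).
#' @export
plot_coverage_curve <- function(curve, thresholds = c(25, 50, 75), ...) {
  graphics::plot(curve$rank, curve$cumulative_pct, type = "l",
                 xlab = "Concept rank (most frequent first)",
                 ylab = "Cumulative share of occurrences [%]", ...)
  marks <- vapply(thresholds, function(t)
    head_size_for_coverage(curve, t), integer(1))
  graphics::abline(h = thresholds, lty = 3, col = "grey50")
  graphics::points(marks, curve$cumulative_pct[marks], pch = 19)
  invisible(stats::setNames(marks, thresholds))
}
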