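# Code cleaning: declarative CUI-set remapping.
#
# Manual code review ("different codes must not be used for identical
# medical concepts") is represented as a user-supplied remapping from
# canonical concept key to canonical concept key. The map is closed over
# chains (A->B, B->C becomes A->C) before use, so one application is a
# fixpoint; cycles are a configuration error.

#' Construct a cleaning map
#'
#' @param old character vector of canonical concept keys to replace.
#' @param new character vector (same length) of replacement keys.
#' @return a `cleaning_map`: a named character vector `old -> new`, closed
#'   over chains.
#' @export
#' @examples
#' cleaning_map(c("C0000001", "C0000002"), c("C0000002", "C0000003"))
cleaning_map <- function(old = character(), new = character()) {
  stopifnot(length(old) == length(new))
  old <- vapply(old, function(k) canonical_key(parse_concept(k)), character(1),
                USE.NAMES = FALSE)
  new <- vapply(new, function(k) canonical_key(parse_concept(k)), character(1),
                USE.NAMES = FALSE)
  identity_entries <- old == new
  old <- old[!identity_entries]
  new <- new[!identity_entries]
  if (anyDuplicated(old)) {
    stop("cleaning map defines multiple targets for: ",
         paste(unique(old[duplicated(old)]), collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(new, old)
  map <- close_cleaning_map(map)
  structure(map, class = "cleaning_map")
}

# Resolve chains to fixpoint; detect cycles.
close_cleaning_map <- function(map) {
  resolve <- function(key) {
    seen <- character()
    while (key %in% names(map)) {
      if (key %in% seen) {
        stop("cleaning map contains a cycle through '", key, "'",
             call. = FALSE)
      }
      seen <- c(seen, key)
      key <- unname(map[[key]])
    }
    key
  }
  stats::setNames(vapply(names(map), resolve, character(1)), names(map))
}

#' Read a cleaning map from a two-column CSV
#'
#' Expected header: `old_key,new_key`. Keys are annotation strings
#' (whitespace-separated CUIs) and are canonicalized on read.
#'
#' @param path CSV file path.
#' @return a `cleaning_map`.
#' @export
read_cleaning_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("old_key", "new_key")
  if (!all(need %in% names(df))) {
    stop("cleaning map CSV must have columns old_key,new_key", call. = FALSE)
  }
  cleaning_map(df$old_key, df$new_key)
}

#' Apply a cleaning map to a corpus
#'
#' Every item whose canonical key appears in the map is rewritten to the
#' mapped concept; all other items are untouched. The total item count and
#' the multiset of item ids are preserved.
#'
#' @param corpus a `form_corpus`.
#' @param map a `cleaning_map`.
#' @return the remapped `form_corpus`, with attribute `change_log`: a
#'   data.frame of `(form_id, item_id, old, new)`, one row per rewritten
#'   item.
#' @export
apply_cleaning <- function(corpus, map) {
  if (!inherits(map, "cleaning_map")) {
    stop("map must be a cleaning_map (see cleaning_map(), read_cleaning_map())",
         call. = FALSE)
  }
  log_rows <- list()
  forms <- lapply(corpus, function(f) {
    f$items <- lapply(f$items, function(it) {
      if (is.null(it$code)) return(it)
      key <- canonical_key(it$code)
      if (key %in% names(map)) {
        new_key <- unname(map[[key]])
        log_rows[[length(log_rows) + 1]] <<- data.frame(
          form_id = f$form_id, item_id = it$item_id,
          old = key, new = new_key, stringsAsFactors = FALSE
        )
        it$code <- parse_concept(new_key)
      }
      it
    })
    f
  })
  out <- form_corpus(forms)
  attr(out, "change_log") <- if (length(log_rows) > 0) {
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(form_id = character(), item_id = character(),
               old = character(), new = character(), stringsAsFactors = FALSE)
  }
  out
}
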