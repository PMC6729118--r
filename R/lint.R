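# Coding-principle checks on an annotated corpus.
#
# The coding principles enforced here: prefer one precoordinated CUI, allow
# at most two CUIs when postcoordination is needed, leave the item uncoded
# when even that fails, and discard nondistinct ("Other medication") and
# administrative ("Technician id") items that carry no reusable medical
# concept. Human judgment is out of scope; the checks flag candidates and
# can optionally apply the exclusions.

#' Default lint rule configuration
#'
#' @param nondistinct_patterns case-insensitive regular expressions applied
#'   to item name and question; matches propose a `nondistinct` exclusion.
#' @param administrative_patterns as above, proposing `administrative`.
#' @param max_cuis maximum CUIs per concept before a `max-two-codes`
#'   finding (default 2).
#' @param max_cuis_severity severity of that finding, `"warn"` or
#'   `"error"` (strict mode).
#' @return a list usable as `rules` in [lint_coding()].
#' @export
lint_rules <- function(nondistinct_patterns = c("^other medication",
                                                "^other comments?",
                                                "^other\\b.*specify"),
                       administrative_patterns = c("technician id",
                                                   "\\bform version\\b",
                                                   "\\brecord id\\b"),
                       max_cuis = 2,
                       max_cuis_severity = c("warn", "error")) {
  list(
    nondistinct_patterns = nondistinct_patterns,
    administrative_patterns = administrative_patterns,
    max_cuis = max_cuis,
    max_cuis_severity = match.arg(max_cuis_severity)
  )
}

#' Read lint rules from a YAML file
#'
#' Recognized top-level keys mirror the arguments of [lint_rules()].
#'
#' @param path YAML file.
#' @return a lint rules list.
#' @export
read_lint_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- lint_rules()
  do.call(lint_rules, utils::modifyList(
    defaults[c("nondistinct_patterns", "administrative_patterns",
               "max_cuis", "max_cuis_severity")],
    raw[intersect(names(raw), c("nondistinct_patterns",
                                "administrative_patterns", "max_cuis",
                                "max_cuis_severity"))]
  ))
}

#' Check a corpus against the coding principles
#'
#' Produces a validation report with one finding per (item, rule):
#' `max-two-codes` for concepts combining more than `max_cuis` CUIs,
#' `unannotated` (informational) for items without a code, and
#' `nondistinct` / `administrative` exclusion proposals from the
#' configurable name/question patterns. With `apply = TRUE`, proposed
#' exclusions are written onto the returned corpus.
#'
#' @param corpus a `form_corpus`.
#' @param rules a list from [lint_rules()] / [read_lint_rules()].
#' @param apply set the `excluded` flag for matched items.
#' @return a `validation_report`: list with `findings` (data.frame:
#'   `form_id`, `item_id`, `rule`, `severity`, `message`), `summary`
#'   (counts per rule), and `corpus` (the possibly modified corpus).
#' @export
lint_coding <- function(corpus, rules = lint_rules(), apply = FALSE) {
  findings <- list()
  add <- function(form_id, item_id, rule, severity, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      form_id = form_id, item_id = item_id, rule = rule,
      severity = severity, message = message, stringsAsFactors = FALSE
    )
  }
  matches_any <- function(patterns, it) {
    any(vapply(patterns, function(p) {
      grepl(p, it$name, ignore.case = TRUE) ||
        (nzchar(it$question) && grepl(p, it$question, ignore.case = TRUE))
    }, logical(1)))
  }

  forms <- lapply(corpus, function(f) {
    f$items <- lapply(f$items, function(it) {
      if (!is.null(it$code) && length(it$code) > rules$max_cuis) {
        add(f$form_id, it$item_id, "max-two-codes", rules$max_cuis_severity,
            sprintf("concept uses %d CUIs (limit %d): %s",
                    length(it$code), rules$max_cuis, canonical_key(it$code)))
      }
      if (is.null(it$code) && it$excluded == "none") {
        add(f$form_id, it$item_id, "unannotated", "info",
            "no UMLS annotation assigned")
      }
      if (it$excluded == "none") {
        if (matches_any(rules$nondistinct_patterns, it)) {
          add(f$form_id, it$item_id, "nondistinct", "warn",
              sprintf("nondistinct item '%s': exclusion proposed", it$name))
          if (apply) it$excluded <- "nondistinct"
        } else if (matches_any(rules$administrative_patterns, it)) {
          add(f$form_id, it$item_id, "administrative", "warn",
              sprintf("administrative item '%s': exclusion proposed", it$name))
          if (apply) it$excluded <- "administrative"
        }
      }
      it
    })
    f
  })

  findings <- if (length(findings) > 0) {
    do.call(rbind, c(findings, list(make.row.names = FALSE)))
  } else {
    data.frame(form_id = character(), item_id = character(),
               rule = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(
      findings = findings,
      summary = as.list(table(findings$rule)),
      corpus = form_corpus(forms)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$findings), " finding(s)\n", sep = "")
  if (nrow(x$findings) > 0) {
    tab <- table(x$findings$rule)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}
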