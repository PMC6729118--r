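# CDISC ODM 1.3 metadata I/O.
#
# Target structure: ODM > Study > MetaDataVersion > FormDef / ItemGroupDef /
# ItemDef. UMLS annotations live in item-level <Alias> elements; the set of
# accepted Alias Context strings defaults to {"UMLS", "UMLS CUI"} and is
# configurable, since source files differ in this convention. A
# postcoordinated concept may be written as one alias whose Name is a
# whitespace-separated CUI list ("C0019080 C0450429") or as multiple UMLS
# aliases on one item; both normalize to one CUI set. On write, the single
# space-joined alias form is emitted.
#
# ODM has no standard slot for a documentation context; it is carried as a
# Study-level Alias (Context "DocumentationContext") on write and may be
# overridden from a sidecar context map on read — the override wins.

.odm_ns <- "http://www.cdisc.org/ns/odm/v1.3"

#' ODM dialect configuration
#'
#' @param alias_contexts Alias `Context` attribute values accepted as UMLS
#'   annotations.
#' @param context override for the documentation-context label; when `NULL`
#'   the study-level `DocumentationContext` alias is used, and its absence
#'   is an error.
#' @param context_alias Alias `Context` value carrying the documentation
#'   context at study level.
#' @return a list of dialect settings for [read_odm()] / [write_odm()].
#' @export
odm_dialect <- function(alias_contexts = c("UMLS", "UMLS CUI"),
                        context = NULL,
                        context_alias = "DocumentationContext") {
  list(alias_contexts = alias_contexts, context = context,
       context_alias = context_alias)
}

# ODM DataType -> internal closed set; unknown types fall back to text.
.odm_datatype_map <- c(
  text = "text", string = "text", integer = "integer", float = "float",
  double = "float", boolean = "boolean", date = "date",
  datetime = "datetime", time = "datetime"
)

#' Read one ODM form definition
#'
#' Parses an ODM 1.3 metadata file into a [form_document()]. Every UMLS
#' alias found on an item is kept (postcoordination preserved); items
#' without any annotation get an absent code; an annotation that fails CUI
#' syntax leaves the item uncoded and is recorded as a diagnostic, never
#' silently dropped. An `ItemDef` with a `CodeListRef` maps to datatype
#' `codelist`.
#'
#' @param path path to an ODM XML file.
#' @param dialect an [odm_dialect()] configuration.
#' @return a `form_document`; attribute `diagnostics` holds a data.frame of
#'   structured warnings (level, file, item_id, message).
#' @export
read_odm <- function(path, dialect = odm_dialect()) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("malformed XML in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  root <- xml2::xml_name(doc)
  if (root != "ODM") {
    stop("not an ODM document (root element '", root, "') in '", path, "'",
         call. = FALSE)
  }
  xml2::xml_ns_strip(doc)
  diags <- empty_diagnostics()

  study <- xml2::xml_find_first(doc, ".//Study")
  if (inherits(study, "xml_missing")) {
    stop("ODM file '", path, "' has no Study element", call. = FALSE)
  }

  # context: dialect override > study-level alias > error
  context <- dialect$context
  if (is.null(context)) {
    ctx_node <- xml2::xml_find_first(
      study, sprintf(".//Alias[@Context='%s']", dialect$context_alias))
    if (!inherits(ctx_node, "xml_missing")) {
      context <- xml2::xml_attr(ctx_node, "Name")
    }
  }
  if (is.null(context) || is.na(context) || !nzchar(context)) {
    stop("no documentation context for '", path,
         "': supply one via the dialect/context map or a study-level '",
         dialect$context_alias, "' alias", call. = FALSE)
  }

  form_def <- xml2::xml_find_first(study, ".//FormDef")
  study_oid <- xml2::xml_attr(study, "OID")
  form_id <- if (!inherits(form_def, "xml_missing")) {
    xml2::xml_attr(form_def, "OID")
  } else {
    study_oid
  }
  title <- if (!inherits(form_def, "xml_missing")) {
    xml2::xml_attr(form_def, "Name")
  } else {
    name_node <- xml2::xml_find_first(study, ".//GlobalVariables/StudyName")
    if (!inherits(name_node, "xml_missing")) xml2::xml_text(name_node)
    else form_id
  }

  # Preserve definition order via ItemGroupRef/ItemRef where present.
  item_defs <- xml2::xml_find_all(study, ".//ItemDef")
  defs_by_oid <- stats::setNames(as.list(item_defs),
                                 xml2::xml_attr(item_defs, "OID"))
  ref_oids <- xml2::xml_attr(
    xml2::xml_find_all(study, ".//ItemGroupDef/ItemRef"), "ItemOID")
  ordered_oids <- c(intersect(ref_oids, names(defs_by_oid)),
                    setdiff(names(defs_by_oid), ref_oids))

  if (length(ordered_oids) == 0) {
    warning("ODM file '", path, "' defines no items", call. = FALSE)
  }

  items <- lapply(ordered_oids, function(oid) {
    def <- defs_by_oid[[oid]]
    name <- xml2::xml_attr(def, "Name")
    q_node <- xml2::xml_find_first(def, ".//Question/TranslatedText")
    question <- if (inherits(q_node, "xml_missing")) "" else
      xml2::xml_text(q_node)
    raw_attr <- xml2::xml_attr(def, "DataType")
    raw_type <- tolower(raw_attr)
    has_codelist <- !inherits(xml2::xml_find_first(def, ".//CodeListRef"),
                              "xml_missing")
    datatype <- if (has_codelist) {
      "codelist"
    } else if (raw_type %in% names(.odm_datatype_map)) {
      .odm_datatype_map[[raw_type]]
    } else {
      diags <<- bind_diagnostics(diags, diagnostic(
        "warn", sprintf("unknown ODM DataType '%s' mapped to text", raw_attr),
        file = path, item_id = oid))
      "text"
    }

    alias_xpath <- paste(
      sprintf(".//Alias[@Context='%s']", dialect$alias_contexts),
      collapse = " | ")
    alias_names <- xml2::xml_attr(
      xml2::xml_find_all(def, alias_xpath), "Name")
    code <- NULL
    if (length(alias_names) > 0) {
      tokens <- unlist(strsplit(trimws(alias_names), "\\s+"))
      tokens <- tokens[nzchar(tokens)]
      bad <- tokens[!is_cui(tokens)]
      if (length(bad) > 0) {
        diags <<- bind_diagnostics(diags, diagnostic(
          "warn",
          sprintf("annotation failed CUI syntax (%s); item left unannotated",
                  paste(bad, collapse = ", ")),
          file = path, item_id = oid))
      } else {
        code <- concept_code(tokens)
      }
    }

    excl_node <- xml2::xml_find_first(def, ".//Alias[@Context='ExclusionReason']")
    excluded <- if (inherits(excl_node, "xml_missing")) "none" else {
      reason <- xml2::xml_attr(excl_node, "Name")
      if (reason %in% .exclusion_reasons) reason else "none"
    }

    annotated_item(item_id = oid, name = name, question = question,
                   datatype = datatype, code = code, excluded = excluded)
  })

  out <- form_document(form_id = form_id, title = title, context = context,
                       items = items)
  attr(out, "diagnostics") <- diags
  out
}

#' Write a form document as ODM XML
#'
#' Emits an ODM 1.3 metadata file that [read_odm()] reads back to an
#' identical `form_document` (round-trip on all fields). Concept codes are
#' written as one `Alias Context="UMLS"` with the canonical space-joined
#' CUI list; the documentation context as a study-level
#' `DocumentationContext` alias; `codelist` items carry a `CodeListRef` to
#' a shared placeholder code list.
#'
#' @param form a `form_document`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_odm <- function(form, path) {
  if (!inherits(form, "form_document")) {
    stop("form must be a form_document", call. = FALSE)
  }
  doc <- xml2::xml_new_root(
    "ODM", xmlns = .odm_ns,
    FileOID = paste0("odmcde.", form$form_id),
    FileType = "Snapshot", ODMVersion = "1.3.2",
    CreationDateTime = "1970-01-01T00:00:00"
  )
  study <- xml2::xml_add_child(doc, "Study", OID = form$form_id)
  gv <- xml2::xml_add_child(study, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", form$title)
  xml2::xml_add_child(gv, "StudyDescription",
                      "UMLS-annotated form definition")
  xml2::xml_add_child(gv, "ProtocolName", form$form_id)
  xml2::xml_add_child(study, "Alias", Context = "DocumentationContext",
                      Name = form$context)

  mdv <- xml2::xml_add_child(study, "MetaDataVersion",
                             OID = "MDV.1", Name = form$title)
  form_def <- xml2::xml_add_child(mdv, "FormDef", OID = form$form_id,
                                  Name = form$title, Repeating = "No")
  xml2::xml_add_child(form_def, "ItemGroupRef", ItemGroupOID = "IG.1",
                      Mandatory = "No")
  ig <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = "IG.1",
                            Name = "Items", Repeating = "No")
  for (it in form$items) {
    xml2::xml_add_child(ig, "ItemRef", ItemOID = it$item_id,
                        Mandatory = "No")
  }
  needs_codelist <- FALSE
  for (it in form$items) {
    odm_type <- switch(it$datatype, codelist = "text", float = "float",
                       it$datatype)
    def <- xml2::xml_add_child(mdv, "ItemDef", OID = it$item_id,
                               Name = it$name, DataType = odm_type)
    if (nzchar(it$question)) {
      q <- xml2::xml_add_child(def, "Question")
      tt <- xml2::xml_add_child(q, "TranslatedText", it$question)
      xml2::xml_set_attr(tt, "xml:lang", "en")
    }
    if (it$datatype == "codelist") {
      xml2::xml_add_child(def, "CodeListRef", CodeListOID = "CL.generic")
      needs_codelist <- TRUE
    }
    if (!is.null(it$code)) {
      xml2::xml_add_child(def, "Alias", Context = "UMLS",
                          Name = canonical_key(it$code))
    }
    if (it$excluded != "none") {
      xml2::xml_add_child(def, "Alias", Context = "ExclusionReason",
                          Name = it$excluded)
    }
  }
  if (needs_codelist) {
    cl <- xml2::xml_add_child(mdv, "CodeList", OID = "CL.generic",
                              Name = "Generic", DataType = "text")
    cli <- xml2::xml_add_child(cl, "CodeListItem", CodedValue = "NA")
    dec <- xml2::xml_add_child(cli, "Decode")
    tt <- xml2::xml_add_child(dec, "TranslatedText", "Not specified")
    xml2::xml_set_attr(tt, "xml:lang", "en")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a set of ODM files into one corpus
#'
#' Batch wrapper over [read_odm()] with per-file context assignment,
#' aggregated diagnostics, and deterministic handling of duplicate form
#' ids (suffixing `#2`, `#3`, ... in input order, with a warning).
#'
#' @param paths character vector of ODM file paths.
#' @param context_map named character vector `path -> context label`, or a
#'   data.frame with columns `path`, `context` and optionally `form_id`
#'   (an override). Files not covered fall back to `default_context`,
#'   then to the in-file study alias.
#' @param default_context context label applied when `context_map` has no
#'   entry for a file; `NULL` means rely on the file itself.
#' @param keep_going parse errors in single files are recorded rather than
#'   aborting the batch.
#' @param dialect base [odm_dialect()].
#' @return a `form_corpus`; attributes `diagnostics` (aggregated
#'   structured log) and `errors` (data.frame of failed files, only when
#'   `keep_going`).
#' @export
read_corpus <- function(paths, context_map = NULL, default_context = NULL,
                        keep_going = FALSE, dialect = odm_dialect()) {
  if (length(paths) == 0) {
    warning("empty path list: returning empty corpus", call. = FALSE)
    out <- form_corpus(list())
    attr(out, "diagnostics") <- empty_diagnostics()
    return(out)
  }
  ctx_for <- function(p) NULL
  id_for <- function(p) NULL
  if (is.data.frame(context_map)) {
    stopifnot(all(c("path", "context") %in% names(context_map)))
    ctx_for <- function(p) {
      i <- match(p, context_map$path)
      if (is.na(i)) NULL else context_map$context[[i]]
    }
    if ("form_id" %in% names(context_map)) {
      id_for <- function(p) {
        i <- match(p, context_map$path)
        v <- if (is.na(i)) NA_character_ else context_map$form_id[[i]]
        if (is.na(v) || !nzchar(v)) NULL else v
      }
    }
  } else if (!is.null(context_map)) {
    ctx_for <- function(p) {
      if (p %in% names(context_map)) unname(context_map[[p]]) else NULL
    }
  }

  forms <- list()
  diags <- empty_diagnostics()
  errors <- data.frame(file = character(), message = character(),
                       stringsAsFactors = FALSE)
  for (p in paths) {
    d <- dialect
    d$context <- ctx_for(p) %||% default_context %||% dialect$context
    f <- tryCatch(read_odm(p, dialect = d), error = function(e) e)
    if (inherits(f, "error")) {
      if (!keep_going) {
        stop("failed on '", p, "': ", conditionMessage(f),
             " (set keep_going = TRUE to collect errors instead)",
             call. = FALSE)
      }
      errors <- rbind(errors, data.frame(file = p,
                                         message = conditionMessage(f),
                                         stringsAsFactors = FALSE))
      next
    }
    override <- id_for(p)
    if (!is.null(override)) f$form_id <- override
    diags <- bind_diagnostics(diags, attr(f, "diagnostics"))
    attr(f, "diagnostics") <- NULL
    forms[[length(forms) + 1]] <- f
  }

  # deterministic duplicate-id resolution in input order
  ids <- vapply(forms, `[[`, character(1), "form_id")
  if (anyDuplicated(ids)) {
    seen <- new.env(parent = emptyenv())
    for (i in seq_along(forms)) {
      id <- forms[[i]]$form_id
      n <- (get0(id, envir = seen, ifnotfound = 0L)) + 1L
      assign(id, n, envir = seen)
      if (n > 1L) {
        new_id <- paste0(id, "#", n)
        diags <- bind_diagnostics(diags, diagnostic(
          "warn", sprintf("duplicate form_id '%s' renamed to '%s'",
                          id, new_id), file = paths[[i]]))
        forms[[i]]$form_id <- new_id
      }
    }
    warning("duplicate form_id(s) resolved by deterministic suffixing",
            call. = FALSE)
  }

  out <- form_corpus(forms)
  attr(out, "diagnostics") <- diags
  if (keep_going) attr(out, "errors") <- errors
  out
}

#' Read a sidecar corpus configuration
#'
#' A YAML or JSON list of `{path, context, form_id}` records, with paths
#' resolved relative to the config file's directory.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return data.frame with columns `path`, `context`, `form_id`.
#' @export
read_context_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported context map format '", ext, "' (yaml or json)",
         call. = FALSE)
  }
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  rows <- lapply(raw, function(r) {
    data.frame(path = as.character(r$path),
               context = as.character(r$context %||% NA_character_),
               form_id = as.character(r$form_id %||% NA_character_),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}
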