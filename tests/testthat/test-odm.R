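test_that("read_odm recovers items, annotations and context", {
  f <- form_document("F.ACS.1", title = "Admission form", context = "routine",
                     items = list(
    annotated_item("I1", name = "Date of birth", question = "Birth date?",
                   datatype = "date", code = "C0001779"),
    annotated_item("I2", name = "Bleeding location",
                   code = "C0019080 C0450429"),
    annotated_item("I3", name = "Comments")
  ))
  path <- withr::local_tempfile(fileext = ".xml")
  write_odm(f, path)

  back <- read_odm(path)
  expect_identical(back$form_id, "F.ACS.1")
  expect_identical(back$context, "routine")
  expect_length(back$items, 3)
  expect_identical(canonical_key(back$items[[1]]$code), "C0001779")
  expect_false(is_postcoordinated(back$items[[1]]$code))
  expect_identical(canonical_key(back$items[[2]]$code), "C0019080 C0450429")
  expect_true(is_postcoordinated(back$items[[2]]$code))
  expect_null(back$items[[3]]$code)

  # dialect override beats the in-file study alias
  over <- read_odm(path, odm_dialect(context = "registry"))
  expect_identical(over$context, "registry")
})

test_that("round-trip identity holds on random forms (property)", {
  set.seed(404)
  for (i in 1:20) {
    corpus <- rand_corpus(n_forms = 1, items_range = c(0, 12))
    f <- corpus[[1]]
    path <- withr::local_tempfile(fileext = ".xml")
    if (length(f$items) == 0) {
      expect_warning(
        {
          write_odm(f, path)
          back <- read_odm(path)
        },
        "no items"
      )
    } else {
      write_odm(f, path)
      back <- read_odm(path)
    }
    attr(back, "diagnostics") <- NULL
    expect_identical(back, f)
  }
})

test_that("multiple UMLS aliases and alias variants normalize to one set", {
  xml <- '<?xml version="1.0"?>
<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="x" FileType="Snapshot">
 <Study OID="S1">
  <GlobalVariables><StudyName>t</StudyName></GlobalVariables>
  <Alias Context="DocumentationContext" Name="registry"/>
  <MetaDataVersion OID="M" Name="m">
   <ItemGroupDef OID="G" Name="g" Repeating="No">
     <ItemRef ItemOID="I1"/><ItemRef ItemOID="I2"/><ItemRef ItemOID="I3"/>
   </ItemGroupDef>
   <ItemDef OID="I1" Name="split aliases" DataType="text">
     <Alias Context="UMLS" Name="C0019080"/>
     <Alias Context="UMLS CUI" Name="C0450429"/>
   </ItemDef>
   <ItemDef OID="I2" Name="bad annotation" DataType="text">
     <Alias Context="UMLS" Name="NOT-A-CUI"/>
   </ItemDef>
   <ItemDef OID="I3" Name="odd datatype" DataType="partialDate"/>
  </MetaDataVersion>
 </Study>
</ODM>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  f <- read_odm(path)
  # two aliases on one item merge into one postcoordinated set
  expect_identical(canonical_key(f$items[[1]]$code), "C0019080 C0450429")
  # invalid annotation: item unannotated, diagnostic recorded
  expect_null(f$items[[2]]$code)
  diags <- attr(f, "diagnostics")
  expect_true(any(grepl("NOT-A-CUI", diags$message)))
  # unknown datatype falls back to text with a diagnostic
  expect_identical(f$items[[3]]$datatype, "text")
  expect_true(any(grepl("partialDate", diags$message)))
  # parsing never invents annotations
  n_alias_items <- 2L
  expect_lte(sum(corpus_items(list(f))$coded), n_alias_items)
})

test_that("read_odm rejects malformed or non-ODM input", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<ODM><unclosed>", bad)
  expect_error(read_odm(bad), "malformed XML")

  other <- withr::local_tempfile(fileext = ".xml")
  writeLines("<NotODM xmlns='urn:x'><a/></NotODM>", other)
  expect_error(read_odm(other), "not an ODM document")
})

test_that("read_corpus batches, keeps going, and suffixes duplicate ids", {
  dir <- withr::local_tempdir()
  forms <- list(
    form_from_keys("FA", "registry", c("C0000001", "C0000002")),
    form_from_keys("FB", "routine", "C0000001"),
    form_from_keys("FA", "risk_score", "C0000003")   # duplicate id
  )
  paths <- file.path(dir, sprintf("f%d.xml", 1:3))
  for (i in 1:3) write_odm(forms[[i]], paths[i])
  bad <- file.path(dir, "broken.xml")
  writeLines("not xml at all <", bad)

  expect_error(read_corpus(c(paths, bad)), "broken.xml")

  expect_warning(
    corpus <- read_corpus(c(paths, bad), keep_going = TRUE),
    "duplicate form_id"
  )
  expect_length(corpus, 3)
  expect_identical(nrow(attr(corpus, "errors")), 1L)
  ids <- vapply(corpus, `[[`, character(1), "form_id")
  expect_setequal(ids, c("FA", "FB", "FA#2"))

  # context map overrides in-file labels
  cmap <- stats::setNames(c("eligibility", "eligibility", "eligibility"),
                          paths)
  suppressWarnings(corpus2 <- read_corpus(paths, context_map = cmap))
  expect_true(all(vapply(corpus2, `[[`, character(1), "context") ==
                    "eligibility"))

  expect_warning(empty <- read_corpus(character()), "empty path list")
  expect_length(empty, 0)
})

test_that("sidecar context maps resolve paths and form_id overrides", {
  dir <- withr::local_tempdir()
  write_odm(form_from_keys("F1", "registry", "C0000001"),
            file.path(dir, "a.xml"))
  cfg <- file.path(dir, "corpus.yaml")
  yaml::write_yaml(list(list(path = "a.xml", context = "quality_assurance",
                             form_id = "QA-01")), cfg)
  cmap <- read_context_map(cfg)
  expect_identical(cmap$path, file.path(dir, "a.xml"))
  corpus <- read_corpus(cmap$path, context_map = cmap)
  expect_identical(corpus[[1]]$context, "quality_assurance")
  expect_identical(corpus[[1]]$form_id, "QA-01")
})
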