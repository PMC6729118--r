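small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    contexts = list(
      list(label = "registry", n_forms = 6, items_per_form = c(10, 25)),
      list(label = "routine", n_forms = 5, items_per_form = c(10, 25)),
      list(label = "risk_score", n_forms = 4, items_per_form = c(5, 14))
    ),
    core_vocab_size = 30, private_vocab_size_per_context = 40,
    zipf_exponent = 0.8
  ), list(...))
  do.call(synth_config, args)
}

test_that("generation is deterministic under (config, seed)", {
  a <- generate_corpus(small_cfg(seed = 42))
  b <- generate_corpus(small_cfg(seed = 42))
  expect_identical(a, b)
  c <- generate_corpus(small_cfg(seed = 43))
  expect_false(identical(a$corpus, c$corpus))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(generate_corpus(small_cfg())); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("config invariants are enforced", {
  expect_error(small_cfg(p_annotatable = 1.2), "probabilities")
  expect_error(small_cfg(zipf_exponent = 0), "zipf_exponent")
  expect_error(small_cfg(core_vocab_size = -1), "sizes")
  expect_error(generate_corpus(small_cfg(core_vocab_size = 0,
                                         private_vocab_size_per_context = 0)),
               "empty vocabulary")
})

test_that("ledger agrees with a full rescan of the emitted corpus", {
  g <- generate_corpus(small_cfg(seed = 7))
  items <- corpus_items(g$corpus)

  # corpus shape
  expect_length(g$corpus, 6 + 5 + 4)
  expect_setequal(unique(items$context),
                  c("registry", "routine", "risk_score"))

  # per-concept-per-context occurrence counts match exactly
  coded <- items[items$coded, ]
  scan <- aggregate(list(count = coded$item_id),
                    by = list(key = coded$key, context = coded$context),
                    FUN = length)
  scan <- scan[order(scan$key, scan$context), c("key", "context", "count")]
  led <- g$ledger$occurrences[order(g$ledger$occurrences$key,
                                    g$ledger$occurrences$context), ]
  rownames(scan) <- rownames(led) <- NULL
  expect_identical(scan$key, led$key)
  expect_identical(scan$context, led$context)
  expect_identical(as.integer(scan$count), led$count)

  # unannotated bookkeeping
  expect_identical(sum(!items$coded), g$ledger$unannotated)
  for (ctx in names(g$ledger$unannotated_by_context)) {
    expect_identical(sum(!items$coded & items$context == ctx),
                     g$ledger$unannotated_by_context[[ctx]])
  }

  # postcoordinated vocabulary bookkeeping; private concepts stay private
  expect_setequal(g$ledger$postcoordinated_keys,
                  g$ledger$vocabulary$key[g$ledger$vocabulary$postcoordinated])
  voc <- g$ledger$vocabulary
  occ_ctx <- split(g$ledger$occurrences$context, g$ledger$occurrences$key)
  for (k in names(occ_ctx)) {
    row <- voc[voc$key == k, ]
    if (row$kind == "private") {
      expect_identical(unique(occ_ctx[[k]]), row$context)
    }
  }
})

test_that("pipeline frequency table recovers ledger counts exactly", {
  g <- generate_corpus(small_cfg(seed = 11))
  tab <- count_frequencies(g$corpus)
  led_total <- tapply(g$ledger$occurrences$count, g$ledger$occurrences$key,
                      sum)
  expect_identical(
    stats::setNames(tab$absolute_frequency, tab$key)[sort(tab$key)],
    stats::setNames(as.integer(led_total), names(led_total))[sort(tab$key)]
  )
  # pairwise mutual concepts equal ledger-realized shared usage
  sets <- context_sets(g$corpus)
  occ <- g$ledger$occurrences
  for (pair in list(c("registry", "routine"), c("registry", "risk_score"),
                    c("routine", "risk_score"))) {
    realized <- intersect(occ$key[occ$context == pair[1]],
                          occ$key[occ$context == pair[2]])
    ov <- pairwise_overlap(sets[[pair[1]]], sets[[pair[2]]])
    expect_identical(ov$mutual, length(realized))
  }
})

test_that("p_annotatable = 1 gives full coverage; uncoded items emitted", {
  full <- generate_corpus(small_cfg(seed = 3, p_annotatable = 1))
  expect_identical(annotation_coverage(full$corpus), 100)
  expect_identical(full$ledger$unannotated, 0L)

  hole <- generate_corpus(small_cfg(seed = 3, p_annotatable = 0.5))
  expect_gt(hole$ledger$unannotated, 0L)
  # lint's unannotated count equals the generator ledger
  rep <- lint_coding(hole$corpus)
  expect_identical(sum(rep$findings$rule == "unannotated"),
                   hole$ledger$unannotated)
})

test_that("synthetic CUIs stay inside the reserved C9 block", {
  g <- generate_corpus(small_cfg(seed = 5))
  cuis <- unlist(strsplit(g$ledger$vocabulary$key, " "))
  expect_true(all(is_cui(cuis)))
  expect_true(all(startsWith(cuis, "C9")))
})

test_that("the calibrated preset matches its documented expectations", {
  g <- generate_corpus(acs_corpus_preset(seed = 1))
  expect_length(g$corpus, 86)
  tab <- count_frequencies(g$corpus)
  tot <- attr(tab, "totals")
  vs <- vocabulary_stats(tab)
  curve <- cumulative_coverage(tab)

  # ~3700 items, ~850 unique concepts (within 15% of 842)
  expect_gt(tot$total_items, 3200)
  expect_lt(tot$total_items, 4200)
  expect_lt(abs(tot$unique_concepts - 842) / 842, 0.15)

  # annotatability and postcoordination recover their probabilities
  expect_lt(abs(annotation_coverage(g$corpus) - 98), 2)
  expect_lt(abs(vs$postcoordinated_share_pct - 6), 2)

  # head-heavy curve: top ~7% of concepts cover half of occurrences
  head_share <- head_size_for_coverage(curve, 50) / tot$unique_concepts * 100
  expect_gte(head_share, 5)
  expect_lte(head_share, 10)

  # majority-singleton tail
  expect_gt(vs$singleton_share_pct, 40)
})

test_that("write_synth_corpus round-trips through read_corpus", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "corpus")
  g <- generate_corpus(small_cfg(seed = 21))
  write_synth_corpus(g, out)
  expect_error(write_synth_corpus(g, out), "not empty")

  cmap <- read_context_map(file.path(out, "context_map.yaml"))
  corpus <- read_corpus(cmap$path, context_map = cmap)
  expect_length(corpus, length(g$corpus))
  expect_identical(corpus_items(corpus), corpus_items(g$corpus))
  expect_true(file.exists(file.path(out, "ledger.json")))
})
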