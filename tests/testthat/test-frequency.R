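test_that("count_frequencies matches the flat-scan oracle (property)", {
  set.seed(405)
  for (i in 1:30) {
    corpus <- rand_corpus(n_forms = sample(2:6, 1), pool_size = 15,
                          p_uncoded = 0.15, p_excluded = 0.1)
    tab <- count_frequencies(corpus)
    oracle <- oracle_counts(corpus)
    expect_identical(
      stats::setNames(tab$absolute_frequency, tab$key)[sort(tab$key)],
      oracle$counts
    )
    tot <- attr(tab, "totals")
    expect_identical(tot$total_items, oracle$n_live)
    expect_identical(tot$coded_items, oracle$n_coded)
    expect_identical(sum(tab$absolute_frequency), oracle$n_coded)
    expect_identical(tot$unique_concepts, nrow(tab))
    expect_identical(tot$singleton_unique, sum(tab$absolute_frequency == 1))
    # relative frequencies per denominator mode
    expect_equal(tab$relative_frequency_pct,
                 tab$absolute_frequency / oracle$n_live * 100)
    tab2 <- count_frequencies(corpus, denominator_mode = "coded_items")
    expect_equal(tab2$relative_frequency_pct,
                 tab2$absolute_frequency / oracle$n_coded * 100)
  }
})

test_that("form order never changes the table or curve (determinism)", {
  set.seed(406)
  corpus <- rand_corpus(n_forms = 6, pool_size = 10)
  shuffled <- form_corpus(unclass(corpus)[sample(length(corpus))])
  expect_identical(count_frequencies(corpus), count_frequencies(shuffled))
  expect_identical(cumulative_coverage(count_frequencies(corpus)),
                   cumulative_coverage(count_frequencies(shuffled)))
})

test_that("annotation coverage is exact, rounded half-up, NA when empty", {
  # 1 coded + 1 uncoded -> 50.00
  corpus <- form_corpus(list(form_from_keys("F1", "registry",
                                            c("C0000001", NA))))
  expect_identical(annotation_coverage(corpus), 50)
  # all coded -> 100
  all_coded <- form_corpus(list(form_from_keys("F1", "registry",
                                               c("C0000001", "C0000002"))))
  expect_identical(annotation_coverage(all_coded), 100)
  # itemless corpus: undefined, not 0 or 100
  expect_identical(annotation_coverage(form_corpus(list())), NA_real_)

  # binomial sampling check on a generated corpus
  cfg <- synth_config(seed = 77, contexts = list(
    list(label = "registry", n_forms = 10, items_per_form = c(90, 110)),
    list(label = "routine", n_forms = 10, items_per_form = c(90, 110))),
    core_vocab_size = 40, private_vocab_size_per_context = 40,
    p_annotatable = 0.9)
  g <- generate_corpus(cfg)
  expect_lt(abs(annotation_coverage(g$corpus) - 90), 2)
})

test_that("cumulative curve: fixed arithmetic and oracle equivalence", {
  # frequencies [3,2,1] over 6 coded items -> 50 / 83.3 / 100
  corpus <- form_corpus(list(
    form_from_keys("F1", "registry",
                   c(rep("C0000001", 3), rep("C0000002", 2), "C0000003"))
  ))
  curve <- cumulative_coverage(count_frequencies(corpus))
  expect_equal(curve$cumulative_pct, c(50, 250 / 3, 100))
  expect_identical(curve$key,
                   c("C0000001", "C0000002", "C0000003"))
  expect_identical(head_size_for_coverage(curve, 50), 1L)
  expect_identical(head_size_for_coverage(curve, 100), 3L)

  # uniform frequencies -> linear in rank
  uni <- form_corpus(list(form_from_keys("F1", "routine",
                                         rep(sprintf("C000000%d", 1:4), 2))))
  ucurve <- cumulative_coverage(count_frequencies(uni))
  expect_equal(ucurve$cumulative_pct, seq(25, 100, by = 25))

  set.seed(407)
  for (i in 1:30) {
    corpus <- rand_corpus(n_forms = sample(2:5, 1), pool_size = 20)
    tab <- count_frequencies(corpus)
    if (nrow(tab) == 0) next
    curve <- cumulative_coverage(tab)
    oracle <- oracle_curve(oracle_counts(corpus)$counts)
    expect_equal(curve$cumulative_pct, unname(oracle))
    expect_identical(curve$key, names(oracle))
    # monotone, ends at 100
    expect_true(all(diff(curve$cumulative_pct) >= -1e-12))
    expect_equal(curve$cumulative_pct[nrow(curve)], 100)
    # head size agrees with linear-scan oracle at random thresholds
    for (t in stats::runif(5, 1, 100)) {
      expect_identical(head_size_for_coverage(curve, t),
                       oracle_head(curve$cumulative_pct, t))
    }
    # monotone in threshold
    hs <- vapply(c(10, 30, 50, 70, 90, 100), function(t)
      head_size_for_coverage(curve, t), integer(1))
    expect_true(all(diff(hs) >= 0))
  }
})

test_that("degenerate frequency inputs are handled", {
  empty_tab <- count_frequencies(form_corpus(list()))
  expect_identical(nrow(empty_tab), 0L)
  expect_identical(attr(empty_tab, "totals")$coded_items, 0L)
  expect_identical(nrow(cumulative_coverage(empty_tab)), 0L)
  expect_error(head_size_for_coverage(cumulative_coverage(empty_tab), 50),
               "empty")
  expect_error(head_size_for_coverage(
    cumulative_coverage(count_frequencies(form_corpus(list(
      form_from_keys("F1", "registry", "C0000001"))))), 0),
    "threshold")
})

test_that("vocabulary_stats reports shares and the singleton tail", {
  corpus <- form_corpus(list(
    form_from_keys("F1", "registry",
                   c(rep("C0000001", 3), rep("C0000002 C0000003", 2),
                     "C0000004", "C0000005"))
  ))
  vs <- vocabulary_stats(count_frequencies(corpus))
  expect_identical(vs$unique_concepts, 4L)
  expect_identical(vs$postcoordinated_unique, 1L)
  expect_identical(vs$postcoordinated_share_pct, 25)
  expect_identical(vs$singleton_unique, 2L)
  expect_identical(vs$singleton_tail_start, 3L)

  # no postcoordination -> share 0
  mono <- form_corpus(list(form_from_keys("F1", "routine",
                                          c("C0000001", "C0000001"))))
  vs2 <- vocabulary_stats(count_frequencies(mono))
  expect_identical(vs2$postcoordinated_share_pct, 0)
  expect_true(is.na(vs2$singleton_tail_start))
})

test_that("postcoordination share of a generated vocabulary recovers p", {
  cfg <- synth_config(seed = 88, contexts = list(
    list(label = "registry", n_forms = 20, items_per_form = c(80, 120)),
    list(label = "routine", n_forms = 20, items_per_form = c(80, 120))),
    core_vocab_size = 400, private_vocab_size_per_context = 200,
    zipf_exponent = 0.3, p_postcoordinated = 0.06)
  g <- generate_corpus(cfg)
  vs <- vocabulary_stats(count_frequencies(g$corpus))
  expect_lt(abs(vs$postcoordinated_share_pct - 6), 2)
})
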