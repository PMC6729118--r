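# Test helpers: a random-corpus builder independent of the package's
# synthetic generator, and brute-force oracles for the statistics.

# random CUI in the C00xxxxx block (disjoint from the generator's C9 block)
rand_cui <- function(n = 1) sprintf("C00%05d", sample.int(99999, n))

rand_key <- function(p_post = 0.2) {
  n <- if (stats::runif(1) < p_post) 2 else 1
  paste(sort(rand_cui(n)), collapse = " ")
}

# small random corpus built directly from constructors; keys drawn from a
# shared pool so repeats/overlap occur
rand_corpus <- function(n_forms = 4, n_contexts = 2, items_range = c(3, 10),
                        pool_size = 12, p_uncoded = 0.1, p_excluded = 0.05,
                        p_post = 0.2) {
  pool <- unique(replicate(pool_size, rand_key(p_post)))
  contexts <- paste0("ctx", seq_len(n_contexts))
  forms <- lapply(seq_len(n_forms), function(fi) {
    n_items <- sample(seq(items_range[1], items_range[2]), 1)
    items <- lapply(seq_len(n_items), function(ii) {
      code <- if (stats::runif(1) < p_uncoded) NULL else
        sample(pool, 1)
      excluded <- if (stats::runif(1) < p_excluded)
        sample(c("nondistinct", "administrative"), 1) else "none"
      annotated_item(sprintf("I%03d", ii), name = sprintf("item %d", ii),
                     question = sprintf("question %d?", ii),
                     datatype = sample(c("text", "integer", "float",
                                         "boolean", "date", "datetime",
                                         "codelist"), 1),
                     code = code, excluded = excluded)
    })
    form_document(sprintf("F%03d", fi), title = sprintf("Form %d", fi),
                  context = contexts[(fi - 1) %% n_contexts + 1],
                  items = items)
  })
  form_corpus(forms)
}

# ---- independent oracles ------------------------------------------------

# flat-scan recount with an environment as hash map
oracle_counts <- function(corpus) {
  counts <- new.env(parent = emptyenv())
  n_live <- 0L
  n_coded <- 0L
  for (f in corpus) {
    for (it in f$items) {
      if (it$excluded != "none") next
      n_live <- n_live + 1L
      if (is.null(it$code)) next
      n_coded <- n_coded + 1L
      k <- paste(sort(unclass(it$code)), collapse = " ")
      assign(k, get0(k, envir = counts, ifnotfound = 0L) + 1L, envir = counts)
    }
  }
  keys <- sort(ls(counts))
  list(
    counts = stats::setNames(
      vapply(keys, function(k) get(k, envir = counts), integer(1)), keys),
    n_live = n_live, n_coded = n_coded
  )
}

# sort + prefix-sum curve from a named count vector
oracle_curve <- function(counts) {
  ord <- order(-counts, names(counts))
  f <- counts[ord]
  cumsum(f) / sum(f) * 100
}

oracle_head <- function(cum_pct, threshold) {
  for (r in seq_along(cum_pct)) {
    if (cum_pct[r] >= threshold - 1e-9) return(r)
  }
  length(cum_pct)
}

# per-context unique keys by direct scan
oracle_context_keys <- function(corpus) {
  out <- list()
  for (f in corpus) {
    for (it in f$items) {
      if (it$excluded != "none" || is.null(it$code)) next
      k <- paste(sort(unclass(it$code)), collapse = " ")
      out[[f$context]] <- union(out[[f$context]], k)
    }
  }
  out
}

# brute-force CDE filter: loops, no vectorization shared with the package
oracle_cde_keys <- function(corpus, min_frequency, min_contexts) {
  freq <- list()
  ctxs <- list()
  for (f in corpus) {
    for (it in f$items) {
      if (it$excluded != "none" || is.null(it$code)) next
      k <- paste(sort(unclass(it$code)), collapse = " ")
      freq[[k]] <- (freq[[k]] %||% 0L) + 1L
      ctxs[[k]] <- union(ctxs[[k]], f$context)
    }
  }
  keep <- character()
  for (k in names(freq)) {
    if (freq[[k]] >= min_frequency && length(ctxs[[k]]) >= min_contexts) {
      keep <- c(keep, k)
    }
  }
  sort(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two labeled sets with a prescribed size/mutual structure
sets_with_mutual <- function(size_a, size_b, mutual,
                             labels = c("A", "B")) {
  shared <- sprintf("C01%05d", seq_len(mutual))
  only_a <- sprintf("C02%05d", seq_len(size_a - mutual))
  only_b <- sprintf("C03%05d", seq_len(size_b - mutual))
  list(concept_set(labels[1], c(shared, only_a)),
       concept_set(labels[2], c(shared, only_b)))
}

# build a form quickly from a vector of keys (NA = uncoded item)
form_from_keys <- function(form_id, context, keys) {
  items <- lapply(seq_along(keys), function(i) {
    annotated_item(sprintf("I%04d", i),
                   code = if (is.na(keys[i])) NULL else keys[i])
  })
  form_document(form_id, context = context, items = items)
}
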