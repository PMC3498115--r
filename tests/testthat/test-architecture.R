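test_that("zero-noise synthetic proteins of all six classes are recovered", {
  m <- test_model()
  specs <- dplyr::bind_rows(lapply(
    c("long_type", "short_type", "truncated", "partial_only",
      "multidomain", "apicortin"),
    function(cl) synth_spec(cl, n = 4)
  ))
  ds <- generate_dataset(specs, m, seed = 401)
  calls <- classify_proteins(ds$records, m, annotations = ds$annotations)
  expect_equal(calls$label, ds$truth$label)
  expect_equal(calls$n_partial_copies[ds$truth$label == "partial_only"],
               ds$truth$n_partial_copies[ds$truth$label == "partial_only"])
  expect_equal(calls$n_p25_copies[ds$truth$label == "multidomain"],
               ds$truth$n_p25_copies[ds$truth$label == "multidomain"])
  expect_true(all(calls$has_ntail[ds$truth$label == "long_type"]))
  expect_true(all(calls$has_extension[ds$truth$label == "long_type"]))
  # classification is total: every record got exactly one label
  expect_true(all(calls$label %in% SUBFAMILY_LABELS))
})

test_that("architecture rules handle the documented special cases", {
  m <- test_model()
  # random background: no qualifying hits, label none
  set.seed(402)
  expect_equal(classify_architecture(random_seq(300), m)$label, "none")
  # three planted partial copies -> partial_only with 3 copies
  sp <- synth_spec("partial_only", n_partial_copies = 3, seed = 403)
  g <- generate_class_sequence(sp, m)
  call <- classify_architecture(g$record$sequence, m)
  expect_equal(call$label, "partial_only")
  expect_equal(call$n_partial_copies, 3L)
  expect_equal(call$has_rossmann[[1]], c(TRUE, TRUE, TRUE))
  # partial core + DCX marker annotation -> apicortin
  ga <- generate_class_sequence(synth_spec("apicortin", seed = 404), m)
  expect_equal(
    classify_architecture(ga$record$sequence, m,
                          foreign = ga$annotations[, c("name", "start", "end")]
    )$label,
    "apicortin"
  )
  # the same sequence without its annotation is partial-only evidence
  expect_equal(classify_architecture(ga$record$sequence, m)$label,
               "partial_only")
  # apicortin precedence over a long-type span triggers a warning
  long_with_partial <- paste0(long_consensus(with_ntail = FALSE),
                              strrep("A", 15), consensus_of("partial_core"))
  expect_warning(
    call <- classify_architecture(
      long_with_partial, m,
      foreign = tibble::tibble(name = "DCX", start = 1L, end = 10L)
    ),
    "apicortin"
  )
  expect_equal(call$label, "apicortin")
})

test_that("short-type vs truncated uses core affinity plus taxon", {
  m <- test_model()
  trunc_seq <- generate_class_sequence(synth_spec("truncated", seed = 405), m)
  short_seq <- generate_class_sequence(synth_spec("short_type", seed = 406), m)
  # metazoan taxon + high core affinity -> truncated
  expect_equal(
    classify_architecture(trunc_seq$record$sequence, m,
                          taxon = "Drosophila melanogaster")$label,
    "truncated"
  )
  # same sequence but a protist taxon can never be truncated
  expect_equal(
    classify_architecture(trunc_seq$record$sequence, m,
                          taxon = "Tetrahymena thermophila")$label,
    "short_type"
  )
  # divergent (short-type) core stays short even in a metazoan
  expect_equal(
    classify_architecture(short_seq$record$sequence, m,
                          taxon = "Drosophila melanogaster")$label,
    "short_type"
  )
  # without any taxon the call defaults to short_type
  expect_equal(classify_architecture(trunc_seq$record$sequence, m)$label,
               "short_type")
})

test_that("copy counting and tail detection follow their contracts", {
  expect_equal(count_domain_copies(tibble::tibble(start = integer(0),
                                                  end = integer(0))), 0L)
  expect_equal(count_domain_copies(tibble::tibble(start = c(1L, 40L),
                                                  end = c(31L, 70L))), 2L)
  # copies separated by a single residue are still two copies
  expect_equal(count_domain_copies(tibble::tibble(start = c(1L, 33L),
                                                  end = c(31L, 63L))), 2L)
  expect_error(count_domain_copies(tibble::tibble(start = c(1L, 20L),
                                                  end = c(31L, 50L))),
               "overlap")
  seq <- random_seq(120)
  expect_true(detect_nterminal_tail(seq, tibble::tibble(start = 51L)))
  expect_false(detect_nterminal_tail(seq, tibble::tibble(start = 1L)))
  expect_false(detect_nterminal_tail(seq, tibble::tibble(start = 40L)))  # 39 precede
  expect_true(detect_nterminal_tail(seq, tibble::tibble(start = 41L)))   # 40 precede
})

test_that("alignment statistics match hand computations and the DP oracle", {
  expect_equal(pairwise_align_stats("MKRILVW", "MKRILVW")$identity, 100)
  expect_equal(pairwise_align_stats("MKRILVW", "MKRILVW")$similarity, 100)
  st <- pairwise_align_stats("AAAA", "AAAT")
  expect_equal(st$identity, 75)
  expect_equal(st$similarity, 75)  # A/T are in different similarity groups
  # within-group substitutions earn similarity but not identity credit
  st2 <- pairwise_align_stats("ILKD", "LLRE")
  expect_equal(st2$identity, 25)
  expect_equal(st2$similarity, 100)
  # score equals the Gotoh oracle on random pairs (gaps included)
  set.seed(407)
  for (rep in 1:12) {
    a <- random_seq(sample(5:30, 1))
    b <- random_seq(sample(5:30, 1))
    expect_equal(pairwise_align_stats(a, b)$score, oracle_align_score(a, b),
                 tolerance = 1e-9)
  }
  # gapless-by-construction pairs: identity equals direct column comparison
  set.seed(408)
  for (rep in 1:8) {
    a <- random_seq(30)
    ac <- strsplit(a, "")[[1]]
    flip <- sample(30, 6)
    for (i in flip) ac[i] <- sample(setdiff(AA_ALPHABET, ac[i]), 1)
    b <- paste(ac, collapse = "")
    expect_equal(pairwise_align_stats(a, b)$identity, 100 * (30 - 6) / 30)
    expect_equal(pairwise_align_stats(a, b)$score, oracle_align_score(a, b))
  }
})

test_that("reciprocal best hits equal the brute-force double argmax", {
  # identical singletons pair with themselves
  x <- tibble::tibble(id = "x", sequence = "MKRILVWMKR")
  expect_equal(reciprocal_best_hits(x, x)$id_a, "x")
  # 3x3 orthologs at ~5% divergence: the three planted pairs, nothing else
  set.seed(409)
  base <- replicate(3, random_seq(80))
  mutate5 <- function(s) {
    a <- strsplit(s, "")[[1]]
    for (i in sample(80, 4)) a[i] <- sample(setdiff(AA_ALPHABET, a[i]), 1)
    paste(a, collapse = "")
  }
  set_a <- tibble::tibble(id = c("a1", "a2", "a3"), sequence = base)
  set_b <- tibble::tibble(id = c("b1", "b2", "b3"),
                          sequence = vapply(base, mutate5, character(1)))
  got <- reciprocal_best_hits(set_a, set_b)
  expect_equal(got$id_a, c("a1", "a2", "a3"))
  expect_equal(got$id_b, c("b1", "b2", "b3"))
  # asymmetric score table: a's best is b, but b's best is c -> a excluded
  tab <- matrix(c(9, 5,
                  8, 1,
                  10, 2), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "c", "d"), c("b", "e")))
  fake_scorer <- function(x, y) tab[x, y]
  sa <- tibble::tibble(id = rownames(tab), sequence = rownames(tab))
  sb <- tibble::tibble(id = colnames(tab), sequence = colnames(tab))
  got2 <- reciprocal_best_hits(sa, sb, scorer = fake_scorer)
  want2 <- oracle_rbh(tab)
  expect_equal(got2$id_a, want2$id_a)
  expect_equal(got2$id_b, want2$id_b)
  expect_false("a" %in% got2$id_a)  # b's best is d, not a
  # random score tables match the oracle, ties broken lexicographically
  set.seed(410)
  for (rep in 1:6) {
    tab <- matrix(sample(1:5, 12, replace = TRUE), nrow = 4,
                  dimnames = list(paste0("a", 1:4), paste0("b", 1:3)))
    sa <- tibble::tibble(id = rownames(tab), sequence = rownames(tab))
    sb <- tibble::tibble(id = colnames(tab), sequence = colnames(tab))
    got <- suppressMessages(
      reciprocal_best_hits(sa, sb, scorer = function(x, y) tab[x, y]))
    want <- oracle_rbh(tab)
    expect_equal(got$id_a, want$id_a)
    expect_equal(got$id_b, want$id_b)
  }
})
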