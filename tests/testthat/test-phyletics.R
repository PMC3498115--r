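test_that("taxon assignment matches the published supergroup placements", {
  out <- assign_taxon(tibble::tibble(species = c(
    "Babesia bovis", "Homo sapiens", "Thecamonas trahens", "Unknown thing"
  )))
  expect_equal(out$supergroup,
               c("Chromalveolata", "Opisthokonta", "Apusozoa", "unassigned"))
  expect_equal(out$megagroup[1:3], c("photosynthetic", "unikonts", "unikonts"))
  expect_match(out$path[[1]], "Alveolata")
  expect_match(out$path[[2]], "Vertebrata")
})

test_that("tabulating the packaged fixtures reproduces the printed census cells", {
  d2 <- tabulate_distribution(fixture_calls("T2_truncated"))
  # 21 arthropod truncated TPPPs; the excluded flatworm row is footnoted
  expect_equal(taxon_count(d2, "Arthropoda", "truncated"), 21)
  expect_equal(taxon_count(d2, "Metazoa", "truncated"), 21)
  fn <- attr(d2, "footnotes")
  expect_true("GAA47940" %in% fn$id)
  expect_true("EFZ11240" %in% fn$id)  # questionable but still counted

  d3 <- tabulate_distribution(fixture_calls("T3_multidomain"))
  expect_equal(glance(d3)$multidomain, 18)
  expect_equal(taxon_count(d3, "Chloroplastida", "multidomain"), 10)
  expect_equal(taxon_count(d3, "Stramenopiles", "multidomain"), 6)
  expect_equal(taxon_count(d3, "Heterolobosea", "multidomain"), 2)

  d4 <- tabulate_distribution(fixture_calls("T4_partial"))
  expect_equal(taxon_count(d4, "Excavata", "partial_only"), 6)
  expect_equal(taxon_count(d4, "Excavata", "partial_only", est = TRUE), 3)
  # the stramenopile partial rows are tabulated, not dropped
  expect_equal(taxon_count(d4, "Stramenopiles", "partial_only"), 5)
})

test_that("distribution marginals are consistent for generated call sets", {
  set.seed(501)
  species_pool <- load_taxonomy()$species
  labels <- setdiff(SUBFAMILY_LABELS, "none")
  calls <- tibble::tibble(
    id = sprintf("R%03d", 1:80),
    species = sample(species_pool, 80, replace = TRUE),
    label = sample(labels, 80, replace = TRUE),
    is_est = sample(c(TRUE, FALSE), 80, replace = TRUE, prob = c(0.2, 0.8))
  )
  d <- tabulate_distribution(calls)
  m <- distribution_margins(d)
  for (lab in labels) {
    # supergroup totals = sum over their leaf rows
    per_sg <- tapply(d[[lab]], d$supergroup, sum)
    for (sg in names(per_sg)) {
      expect_equal(m$supergroup[[lab]][m$supergroup$supergroup == sg],
                   unname(per_sg[[sg]]))
    }
    # grand total = sum over megagroup rows
    expect_equal(m$grand[[lab]], sum(m$megagroup[[lab]]))
    expect_equal(m$grand[[lab]], sum(d[[lab]]))
    # ESTs never exceed totals
    expect_true(all(d[[paste0(lab, "_est")]] <= d[[lab]]))
  }
  expect_equal(sum(vapply(labels, function(l) m$grand[[l]], numeric(1))), 80)
})

test_that("none-labelled and empty inputs are handled explicitly", {
  empty <- tabulate_distribution(tibble::tibble(species = character(0),
                                                label = character(0)))
  expect_equal(nrow(empty), 0L)
  expect_equal(glance(empty)$long_type, 0)
  with_none <- tabulate_distribution(tibble::tibble(
    id = c("a", "b"), species = c("Homo sapiens", "Homo sapiens"),
    label = c("long_type", "none")
  ))
  expect_equal(glance(with_none)$long_type, 1)
  expect_equal(nrow(attr(with_none, "diagnostics")), 1L)
})

test_that("rendering uses the total (est) convention and tidy() round-trips", {
  d4 <- tabulate_distribution(fixture_calls("T4_partial"))
  lines <- render_distribution(d4)
  expect_true(any(grepl("2 \\(2\\)", lines)))  # Jakobida: 2 records, both ESTs
  td <- tidy(d4)
  expect_equal(sum(td$n), sum(glance(d4)[setdiff(SUBFAMILY_LABELS, "none")]))
  expect_true(all(td$n_est <= td$n))
})
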