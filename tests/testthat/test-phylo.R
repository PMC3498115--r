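test_that("identity distances behave like distances", {
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("MKRILVWA", "MKRILVWA", "MKRILVWT")
  )
  d <- distance_matrix(recs)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 - 87.5 / 100)  # 7/8 identical columns
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_error(distance_matrix(recs[c(1, 1, 2), ]), "duplicate")
  expect_error(distance_matrix(recs[1:2, ]), "at least 3")
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers the generating topology from additive distances", {
  skip_if_not_installed("phangorn")
  set.seed(701)
  for (n in c(4, 5, 6, 7, 8)) {
    for (rep in 1:4) {
      true_tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
      d <- ape::cophenetic.phylo(true_tree)
      d <- d[order(rownames(d)), order(colnames(d))]
      got <- nj_tree(d)
      expect_equal(phangorn::RF.dist(ape::unroot(true_tree), got), 0)
    }
  }
})

test_that("label order does not change the unrooted NJ topology", {
  skip_if_not_installed("phangorn")
  set.seed(702)
  true_tree <- ape::rtree(6, br = function(k) stats::runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(true_tree)
  base <- nj_tree(d)
  for (rep in 1:5) {
    perm <- sample(nrow(d))
    got <- nj_tree(d[perm, perm])
    expect_equal(phangorn::RF.dist(base, got), 0)
  }
})

test_that("nj_tree validates input and clamps negative branch lengths", {
  bad <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
  # a triangle-violating matrix gives one taxon a negative branch -> clamped
  d <- matrix(c(0, 1, 0.2,
                1, 0, 0.3,
                0.2, 0.3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- nj_tree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
  # newick round trip preserves the leaf set
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  expect_setequal(ape::read.tree(f)$tip.label, letters[1:3])
})

test_that("monophyly testing follows its edge-separation definition", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_true(is_monophyletic(tr, c("a", "b"), outgroup = "e"))
  expect_false(is_monophyletic(tr, c("a", "c"), outgroup = "e"))
  expect_true(is_monophyletic(tr, "a", outgroup = "e"))               # singleton
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d"), outgroup = "e"))
  expect_error(is_monophyletic(tr, c("a", "z"), outgroup = "e"), "unknown")
  expect_error(is_monophyletic(tr, c("a", "e"), outgroup = "e"), "outgroup")
})

test_that("synthetic subfamilies reproduce the expected clade structure", {
  m <- test_model()
  specs <- dplyr::bind_rows(
    synth_spec("long_type", n = 5, substitution_rate = 0.02),
    synth_spec("truncated", n = 4, substitution_rate = 0.02),
    synth_spec("short_type", n = 4, substitution_rate = 0.02)
  )
  ds <- generate_dataset(specs, m, seed = 703)
  tr <- suppressWarnings(nj_tree(distance_matrix(ds$records)))
  trunc_ids <- grep("^TRUNC", ds$records$id, value = TRUE)
  long_ids <- grep("^LONG", ds$records$id, value = TRUE)
  short_ids <- grep("^SHORT", ds$records$id, value = TRUE)
  # truncated TPPPs form their own clade near the long-type proteins,
  # and short-type proteins separate from long + truncated
  expect_true(is_monophyletic(tr, trunc_ids, outgroup = short_ids[[1]]))
  expect_true(is_monophyletic(tr, c(long_ids, trunc_ids),
                              outgroup = short_ids[[1]]))
  expect_false(is_monophyletic(tr, c(short_ids, trunc_ids),
                               outgroup = long_ids[[1]]))
})
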