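test_that("scanning a segment's own consensus yields one perfect hit", {
  m <- test_model()
  for (seg in names(m$segments)) {
    hits <- scan_profile(m$segments[[seg]]$consensus, m, seg)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, 1L)
    expect_equal(hits$normalized_score, 1, tolerance = 1e-12)
    expect_equal(hits$tier, "strong")
  }
})

test_that("profile scan agrees with the brute-force enumeration oracle", {
  m <- test_model()
  set.seed(301)
  for (rep in 1:12) {
    n <- sample(20:60, 1)
    seq <- random_seq(n)
    # plant a partial core in half the cases so hits actually occur
    if (rep %% 2 == 0 && n >= 31) {
      k <- sample(seq_len(n - 30), 1)
      seq <- paste0(substr(seq, 1, k - 1), consensus_of("partial_core"),
                    substr(seq, k + 31, n))
    }
    for (thr in c(0, 0.3, 0.55, 0.9)) {
      for (seg in c("partial_core", "extension")) {
        got <- scan_profile(seq, m, seg, min_normalized = thr)
        want <- oracle_scan(seq, m, seg, thr)
        expect_equal(got$start, want$start)
        expect_equal(got$score, want$score, tolerance = 1e-10)
        expect_equal(got$normalized_score, want$normalized_score,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("planted segments are recovered at their planted offsets", {
  m <- test_model()
  set.seed(302)
  for (k in c(1L, 17L, 120L, 301L)) {
    bg <- random_seq(400)
    seq <- paste0(substr(bg, 1, k - 1), consensus_of("core"),
                  substr(bg, k, 400))
    hits <- scan_profile(seq, m, "core", 0.8)
    expect_equal(hits$start[which.max(hits$score)], k)
  }
  # two copies separated by a 20-residue linker: both found, non-overlapping
  two <- paste0(consensus_of("partial_core"), strrep("A", 20),
                consensus_of("partial_core"))
  hits <- scan_profile(two, m, "partial_core", 0.8)
  expect_equal(hits$start, c(1L, 52L))
  expect_equal(count_domain_copies(hits), 2L)
})

test_that("random background yields no hits at the strong threshold", {
  m <- test_model()
  set.seed(303)
  seq <- random_seq(500)
  expect_equal(nrow(scan_profile(seq, m, "core", 0.8)), 0L)
  expect_equal(nrow(scan_profile(seq, m, "partial_core", 0.8)), 0L)
})

test_that("raising min_normalized never increases the number of hits", {
  m <- test_model()
  set.seed(304)
  seq <- paste0(random_seq(30), consensus_of("partial_core"), random_seq(30),
                consensus_of("partial_core"), random_seq(30))
  thresholds <- seq(0, 1, by = 0.1)
  counts <- vapply(thresholds, function(thr)
    nrow(scan_profile(seq, m, "partial_core", thr)), integer(1))
  expect_true(all(diff(counts) <= 0))
  # a segment longer than the sequence is an empty result, not an error
  expect_equal(nrow(scan_profile("MKR", m, "core")), 0L)
})

test_that("motif matcher equals the 9-mer enumeration oracle", {
  expect_equal(find_rossmann_motifs("GAGAGAAGR")$start, 1L)
  expect_equal(nrow(find_rossmann_motifs("AAAAAAAAA")), 0L)
  expect_equal(nrow(find_rossmann_motifs("")), 0L)
  # overlapping matches are all reported
  seq_overlap <- "GAGAGAGGRAGR"
  expect_equal(find_rossmann_motifs(seq_overlap)$start, oracle_motifs(seq_overlap))
  set.seed(305)
  for (rep in 1:5) {
    # G/R-rich alphabet so matches actually happen
    seq <- paste(sample(c("G", "R", "A"), 1000, replace = TRUE,
                        prob = c(0.45, 0.3, 0.25)), collapse = "")
    expect_equal(find_rossmann_motifs(seq)$start, oracle_motifs(seq))
  }
})

test_that("extension detection requires room and scores the next 14 residues", {
  m <- test_model()
  seq <- paste0(consensus_of("partial_core"), consensus_of("extension"))
  motif <- find_rossmann_motifs(seq)[1, ]
  reg <- detect_extension(seq, motif, m)
  expect_equal(reg$start, motif$end + 1L)
  expect_equal(reg$end - reg$start + 1L, 14L)
  expect_equal(reg$normalized_score, 1, tolerance = 1e-12)
  # motif at the very end of the sequence: no room, no region
  seq2 <- consensus_of("partial_core")
  motif2 <- find_rossmann_motifs(seq2)[1, ]
  expect_null(detect_extension(seq2, motif2, m))
  # random continuation scores below threshold
  set.seed(306)
  seq3 <- paste0(consensus_of("partial_core"), random_seq(14))
  expect_null(detect_extension(seq3, find_rossmann_motifs(seq3)[1, ], m))
})

test_that("fragment measurement recovers planted prefix lengths exactly", {
  m <- test_model()
  long <- paste0(consensus_of("core"), consensus_of("partial_core"))
  set.seed(307)
  for (flen in c(70L, 85L, 101L, 126L, 140L)) {
    lead <- random_seq(12)
    tail_seq <- random_seq(40)
    # generator boundary guarantee: next residue differs from next column
    nxt <- substr(long, flen + 1, flen + 1)
    if (substr(tail_seq, 1, 1) == nxt) {
      tail_seq <- paste0("C", substr(tail_seq, 2, nchar(tail_seq)))
    }
    seq <- paste0(lead, substr(long, 1, flen), tail_seq)
    fr <- measure_fragments(seq, m)
    expect_equal(nrow(fr), 1L)
    expect_equal(fr$start, 13L)
    expect_equal(fr$length, flen)
  }
  # the full long domain measures 150 aa
  fr <- measure_fragments(long_consensus(), m)
  expect_equal(fr$length, 150L)
})
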