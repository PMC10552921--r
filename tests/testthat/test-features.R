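cfg <- ltr_config()

# hand-built element: 300 bp LTRs, internal region under our control
feature_fixture <- function(internal, ltr_len = 300, seed = 31) {
  set.seed(seed)
  ltr <- paste0("TG", rand_seq(ltr_len - 4), "CA")
  s <- paste0(rand_seq(1000), ltr, internal, ltr, rand_seq(1000))
  start <- 1000L
  end <- start + 2L * ltr_len + nchar(internal)
  list(
    genome = tibble::tibble(seq_id = "s1", residues = s, length = nchar(s)),
    elements = tibble::tibble(
      element_id = "e1", seq_id = "s1", start = start, end = end,
      strand = "+", ltr5_start = start, ltr5_end = start + ltr_len,
      ltr3_start = end - ltr_len, ltr3_end = end,
      tsd_left = NA_character_, tsd_right = NA_character_,
      terminal_motif = "TGCA", ltr_similarity = 1)
  )
}

pyr_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
}

test_that("an exact tRNA-tail complement is found with its offset", {
  trnas <- synthetic_trnas(n = 3, seed = 8)
  tail18 <- substr(trnas$residues[1], nchar(trnas$residues[1]) - 17,
                   nchar(trnas$residues[1]))
  pbs_site <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tail18)))
  set.seed(32)
  internal <- paste0("CCT", pbs_site, rand_seq(1500))
  fx <- feature_fixture(internal)
  hit <- find_pbs(fx$elements, fx$genome, trnas, cfg)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$trna_id, trnas$seq_id[1])
  expect_equal(hit$match_len, 18L)
  expect_equal(hit$offset_from_5ltr, 3L)
  expect_equal(hit$start, 300L + 3L)   # element-local
  expect_equal(hit$end, 300L + 21L)
})

test_that("random internal sequence produces no PBS call", {
  set.seed(33)
  fx <- feature_fixture(rand_seq(1500))
  trnas <- synthetic_trnas(n = 8, seed = 9)
  expect_equal(nrow(find_pbs(fx$elements, fx$genome, trnas, cfg)), 0)
})

test_that("PBS ties go to the smallest offset", {
  trnas <- synthetic_trnas(n = 2, seed = 10)
  tails <- substr(trnas$residues, nchar(trnas$residues) - 17,
                  nchar(trnas$residues))
  sites <- vapply(tails, function(t) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(t)))
  }, character(1))
  # tRNA 2's site at offset 3, tRNA 1's at offset 9 inside a 30 bp window:
  # the sites overlap, so interleave pyrimidine spacers to keep both exact
  internal <- paste0("CCT", sites[2], pyr_seq(40, 1), sites[1],
                     rand_seq(1200))
  fx <- feature_fixture(internal)
  wide <- ltr_config(pbs_search_window = 100)
  hit <- find_pbs(fx$elements, fx$genome, trnas, wide)
  expect_equal(hit$offset_from_5ltr, 3L)
  expect_equal(hit$trna_id, trnas$seq_id[2])
})

test_that("PBS errors on an unusably short tRNA set", {
  fx <- feature_fixture(rand_seq(1000), seed = 35)
  expect_error(find_pbs(fx$elements, fx$genome,
                        c(t1 = "ACGT"), cfg), "shorter than")
  expect_error(find_pbs(fx$elements, fx$genome, character(0), cfg), "empty")
})

test_that("a pure purine tract near the 3' LTR is recovered exactly", {
  set.seed(36)
  ppt <- "AGGAAAGGGGAGGA"  # 14 bp, all purine
  internal <- paste0(rand_seq(1500), pyr_seq(31, 2), ppt, pyr_seq(5, 3))
  fx <- feature_fixture(internal)
  hit <- find_ppt(fx$elements, fx$genome, cfg)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$purine_fraction, 1.0)
  expect_equal(hit$offset_from_3ltr, 5L)
  local_start <- 300L + nchar(internal) - 14L - 5L
  expect_equal(hit$start, local_start)
  expect_equal(hit$end, local_start + 14L)
})

test_that("a pyrimidine-rich window yields no PPT", {
  internal <- paste0(rand_seq(1500), pyr_seq(50, 4))
  set.seed(37)
  fx <- feature_fixture(internal)
  expect_equal(nrow(find_ppt(fx$elements, fx$genome, cfg)), 0)
})

test_that("equal-scoring purine tracts resolve to the rightmost", {
  tract <- strrep("AG", 6)  # 12 bp pure purine
  internal <- paste0(rand_seq(1500), pyr_seq(10, 5), tract, pyr_seq(8, 6),
                     tract, pyr_seq(6, 7))
  set.seed(38)
  fx <- feature_fixture(internal)
  hit <- find_ppt(fx$elements, fx$genome, cfg)
  expect_equal(hit$offset_from_3ltr, 6L)  # the right-hand copy
})

test_that("simulated PBS/PPT implants are recovered with exact spans", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 2e5,
                         implants = default_implants(5), seed = 5)
  f <- annotate_features(sim$elements, sim$genome, sim$trnas, cfg)
  expect_equal(
    f$pbs[order(f$pbs$element_id), c("element_id", "start", "end")],
    sim$pbs[order(sim$pbs$element_id), c("element_id", "start", "end")])
  expect_equal(
    f$ppt[order(f$ppt$element_id), c("element_id", "start", "end")],
    sim$ppt[order(sim$ppt$element_id), c("element_id", "start", "end")])
  # stored purine fractions recompute from sequence
  for (i in seq_len(nrow(f$ppt))) {
    e <- sim$elements[match(f$ppt$element_id[i], sim$elements$element_id), ]
    seq <- substr(sim$genome$residues[1], e$start + f$ppt$start[i] + 1,
                  e$start + f$ppt$end[i])
    frac <- mean(strsplit(seq, "")[[1]] %in% c("A", "G"))
    expect_equal(frac, f$ppt$purine_fraction[i])
  }
})
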