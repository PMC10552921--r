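cfg_default <- ltr_config()

test_that("repeat-free background yields no seed pairs", {
  set.seed(11)
  g <- tibble::tibble(seq_id = "s1", residues = rand_seq(1e5), length = 1e5L)
  expect_equal(nrow(find_seed_pairs(g, cfg_default)), 0)
})

test_that("an implanted exact direct repeat is found as one maximal seed", {
  set.seed(12)
  unit <- rand_seq(300)
  s <- paste0(rand_seq(2000), unit, rand_seq(4000), unit, rand_seq(2000))
  g <- tibble::tibble(seq_id = "s1", residues = s, length = nchar(s))
  seeds <- find_seed_pairs(g, cfg_default)
  expect_equal(nrow(seeds), 1)  # contained sub-seeds suppressed
  expect_equal(seeds$pos_a, 2000L)
  expect_equal(seeds$pos_b, 2000L + 300L + 4000L)
  expect_equal(seeds$seed_len, 300L)
})

test_that("seed separation must lie inside [d, D]", {
  set.seed(13)
  unit <- rand_seq(200)
  s <- paste0(rand_seq(1000), unit, rand_seq(500), unit, rand_seq(1000))
  g <- tibble::tibble(seq_id = "s1", residues = s, length = nchar(s))
  expect_equal(nrow(find_seed_pairs(g, cfg_default)), 0)  # 700 < d = 1000
  wide <- ltr_config(d = 300)
  expect_equal(nrow(find_seed_pairs(g, wide)), 1)
})

# build a genome holding one full cassette with known coordinates
implant_genome <- function(ltr5, ltr3, internal_len = 2000, tsd = "ACGTA",
                           flank = 3000, seed = 99) {
  set.seed(seed)
  internal <- rand_seq(internal_len)
  s <- paste0(rand_seq(flank), tsd, ltr5, internal, ltr3, tsd,
              rand_seq(flank))
  list(
    genome = tibble::tibble(seq_id = "s1", residues = s, length = nchar(s)),
    start = flank + nchar(tsd),
    end = flank + nchar(tsd) + nchar(ltr5) + internal_len + nchar(ltr3)
  )
}

test_that("extension rejects short or diverged LTR pairs with reason codes", {
  set.seed(21)
  # LTR pair of length 80 with l = 100 -> too short
  ltr <- paste0("TG", rand_seq(76), "CA")
  gi <- implant_genome(ltr, ltr, internal_len = 1500)
  seeds <- find_seed_pairs(gi$genome, cfg_default)
  ext <- extend_and_align(seeds, gi$genome, cfg_default)
  expect_equal(nrow(ext$candidates), 0)
  expect_true(all(ext$rejected$reason == "ltr_length"))

  # a substitution every 25th base (identity ~0.96) against a stricter
  # threshold: the pair still seeds (conserved runs beat the seed length)
  # and extends over its full length, but fails the similarity check
  ltr <- paste0("TG", rand_seq(296), "CA")
  ch <- strsplit(ltr, "")[[1]]
  mut_at <- seq(10, 290, by = 25)
  ch[mut_at] <- chartr("ACGT", "CAUG", ch[mut_at])  # transversions
  ch[mut_at] <- sub("U", "T", ch[mut_at])
  ltr3 <- paste(ch, collapse = "")
  gi <- implant_genome(ltr, ltr3, seed = 101)
  strict <- ltr_config(S = 0.97)
  seeds <- find_seed_pairs(gi$genome, strict)
  ext <- extend_and_align(seeds, gi$genome, strict)
  expect_equal(nrow(ext$candidates), 0)
  expect_true("similarity" %in% ext$rejected$reason)
})

test_that("a mildly diverged implanted pair is accepted with high similarity", {
  set.seed(22)
  ltr <- paste0("TG", rand_seq(296), "CA")
  ltr3 <- mutate_k2p(ltr, 0.02, seed = 6, protect = c(1, 2, 299, 300))
  gi <- implant_genome(ltr, ltr3)
  ext <- extend_and_align(find_seed_pairs(gi$genome, cfg_default),
                          gi$genome, cfg_default)
  expect_equal(nrow(ext$candidates), 1)
  expect_gte(ext$candidates$ltr_similarity, 0.97)
})

test_that("structural filter demands matching TSDs and the TG...CA motif", {
  set.seed(23)
  ltr <- paste0("TG", rand_seq(296), "CA")

  good <- implant_genome(ltr, ltr, tsd = "ACGTA")
  out <- structural_filter(
    extend_and_align(find_seed_pairs(good$genome, cfg_default),
                     good$genome, cfg_default)$candidates,
    good$genome, cfg_default)
  expect_equal(nrow(out$elements), 1)
  expect_equal(out$elements$tsd_left, "ACGTA")
  expect_equal(out$elements$tsd_right, "ACGTA")
  expect_equal(out$elements$terminal_motif, "TGCA")
  expect_equal(out$elements$start, good$start)
  expect_equal(out$elements$end, good$end)

  # mismatched flanks: ACGTA / ACGTT
  set.seed(24)
  internal <- rand_seq(2000)
  s <- paste0(rand_seq(3000), "ACGTA", ltr, internal, ltr, "ACGTT",
              rand_seq(3000))
  g <- tibble::tibble(seq_id = "s1", residues = s, length = nchar(s))
  out <- structural_filter(
    extend_and_align(find_seed_pairs(g, cfg_default), g, cfg_default)$candidates,
    g, cfg_default)
  expect_equal(nrow(out$elements), 0)
  expect_true(all(out$rejected$reason == "tsd"))

  # inverted termini CA...TG fail the motif check, pass when it is off
  bad_ltr <- paste0("CA", rand_seq(296), "TG")
  gi <- implant_genome(bad_ltr, bad_ltr, tsd = "ACGTA")
  cands <- extend_and_align(find_seed_pairs(gi$genome, cfg_default),
                            gi$genome, cfg_default)$candidates
  out <- structural_filter(cands, gi$genome, cfg_default)
  expect_equal(nrow(out$elements), 0)
  expect_equal(out$rejected$reason, "motif")
  no_motif <- ltr_config(motif_check = FALSE)
  out2 <- structural_filter(cands, gi$genome, no_motif)
  expect_equal(nrow(out2$elements), 1)
  expect_equal(out2$elements$terminal_motif, "CATG")
})

test_that("detection on a simulated genome recovers every implant exactly", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 3e5,
                         implants = default_implants(7), seed = 3)
  el <- detect_elements(sim$genome, cfg_default)
  expect_equal(nrow(el), nrow(sim$elements))
  expect_setequal(el$start, sim$elements$start)
  expect_setequal(el$end, sim$elements$end)
  expect_setequal(el$ltr5_end, sim$elements$ltr5_end)
  expect_setequal(el$ltr3_start, sim$elements$ltr3_start)
  expect_equal(el$tsd_left[order(el$start)],
               sim$elements$tsd_left[order(sim$elements$start)])
  # ids are assigned in coordinate order
  expect_equal(el$element_id, sprintf("LTRRT_%05d", seq_len(nrow(el))))
})

test_that("element spans never overlap after resolution", {
  sim <- simulate_genome(n_seqs = 2, seq_len = 2e5,
                         implants = default_implants(8), seed = 4)
  el <- detect_elements(sim$genome, cfg_default)
  for (sid in unique(el$seq_id)) {
    e <- el[el$seq_id == sid, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})
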