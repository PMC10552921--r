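cfg <- ltr_config()

mk_lib <- function(seqs) {
  tibble::tibble(element_id = names(seqs), header = names(seqs),
                 residues = unname(seqs), length = nchar(unname(seqs)))
}

test_that("redundant library extracts spans with strand handling", {
  set.seed(81)
  s <- rand_seq(5000)
  g <- tibble::tibble(seq_id = "s1", residues = s, length = 5000L)
  el <- tibble::tibble(
    element_id = c("p", "m"), seq_id = "s1",
    start = c(100L, 2000L), end = c(600L, 2400L),
    strand = c("+", "-"),
    ltr5_start = c(100L, 2000L), ltr5_end = c(150L, 2050L),
    ltr3_start = c(550L, 2350L), ltr3_end = c(600L, 2400L),
    tsd_left = NA_character_, tsd_right = NA_character_,
    terminal_motif = NA_character_, ltr_similarity = NA_real_)
  lib <- build_redundant_library(el, g)
  expect_equal(lib$length, c(500L, 400L))
  expect_equal(lib$residues[1], substr(s, 101, 600))
  expect_equal(lib$residues[2],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(s, 2001, 2400)))))
  expect_match(lib$header[2], "\\(-\\)")

  expect_warning(empty <- build_redundant_library(el[0, ], g), "no elements")
  expect_equal(nrow(empty), 0)
  bad <- el[1, ]; bad$end <- 9000L
  expect_error(build_redundant_library(bad, g), "outside")
})

test_that("identical sequences collapse to one cluster at identity 1", {
  set.seed(82)
  s <- rand_seq(5000)
  out <- cluster_greedy(mk_lib(c(a = s, b = s)), S = 0.9, cfg)
  expect_equal(nrow(out$nonredundant), 1)
  expect_equal(out$clusters$identity, 1.0)
  expect_false(out$clusters$member_id %in% out$nonredundant$element_id &&
                 out$clusters$member_id == out$clusters$centroid_id)
})

test_that("mutually dissimilar sequences stay singletons", {
  set.seed(83)
  lib <- mk_lib(c(a = rand_seq(1000), b = rand_seq(1000),
                  c = rand_seq(1000)))
  out <- cluster_greedy(lib, S = 0.9, cfg)
  expect_equal(nrow(out$nonredundant), 3)
  expect_equal(nrow(out$clusters), 0)
})

test_that("a 5% mutant joins its source while a 20% mutant stays out", {
  set.seed(84)
  a <- rand_seq(5000)
  b <- mutate_k2p(a, 0.05, seed = 20)   # ~4.8% sites differ
  c <- mutate_k2p(a, 0.24, seed = 21)   # ~20% sites differ
  id_ab <- alignment_identity(a, b)
  id_ac <- alignment_identity(a, c)
  expect_gt(id_ab, 0.9)
  expect_lt(id_ac, 0.9)
  out <- cluster_greedy(mk_lib(c(A = a, B = b, C = c)), S = 0.9, cfg)
  expect_equal(sort(out$nonredundant$element_id), c("A", "C"))
  expect_equal(out$clusters$centroid_id, "A")
  expect_equal(out$clusters$member_id, "B")
  expect_equal(out$clusters$identity, id_ab)
})

test_that("membership invariant: every member realigns to >= S identity", {
  set.seed(85)
  # planted groups: 4 masters, 4 near-copies each, plus 4 loners
  masters <- replicate(4, rand_seq(500))
  seqs <- character(0)
  for (i in 1:4) {
    seqs[paste0("m", i)] <- masters[i]
    for (j in 1:3) {
      seqs[paste0("m", i, "_", j)] <- mutate_k2p(masters[i], 0.03)
    }
  }
  for (i in 1:4) seqs[paste0("lone", i)] <- rand_seq(480)
  out <- cluster_greedy(mk_lib(seqs), S = 0.9, cfg)
  expect_equal(nrow(out$nonredundant), 8)  # 4 groups + 4 loners
  for (i in seq_len(nrow(out$clusters))) {
    re_id <- alignment_identity(
      seqs[[out$clusters$member_id[i]]],
      seqs[[out$clusters$centroid_id[i]]])
    expect_equal(re_id, out$clusters$identity[i])
    expect_gte(re_id, 0.9)
  }
})

test_that("when all pairwise identities sit below S nothing merges", {
  set.seed(86)
  seqs <- setNames(replicate(8, rand_seq(300)), paste0("s", 1:8))
  ids <- utils::combn(8, 2)
  all_below <- all(apply(ids, 2, function(p) {
    alignment_identity(seqs[[p[1]]], seqs[[p[2]]]) < 0.9
  }))
  expect_true(all_below)
  out <- cluster_greedy(mk_lib(seqs), S = 0.9, cfg)
  expect_equal(nrow(out$nonredundant), 8)
})

test_that("permuting equal-length input keeps the membership invariant", {
  set.seed(87)
  a <- rand_seq(400)
  seqs <- c(x = a, y = mutate_k2p(a, 0.04), z = mutate_k2p(a, 0.04))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    out <- cluster_greedy(mk_lib(seqs[perm]), S = 0.9, cfg)
    for (i in seq_len(nrow(out$clusters))) {
      expect_gte(alignment_identity(seqs[[out$clusters$member_id[i]]],
                                    seqs[[out$clusters$centroid_id[i]]]),
                 0.9)
    }
    expect_lte(nrow(out$nonredundant), 3)
  }
})

test_that("library FASTA round-trips through the header dialect", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 1.5e5,
                         implants = default_implants(3), seed = 16)
  cl <- classify_elements(sim$elements, sim$domains, sim$pbs, sim$ppt, cfg)
  lib <- build_redundant_library(sim$elements, sim$genome, cl)
  path <- withr::local_tempfile(fileext = ".fa")
  write_library_fasta(lib, path)
  back <- read_library_fasta(path)
  expect_equal(back$element_id, lib$element_id)
  expect_equal(back$residues, lib$residues)
  expect_equal(back$start, sim$elements$start)
  expect_equal(back$end, sim$elements$end)
  expect_equal(back$class_string,
               classification_string(cl$category, cl$superfamily, cl$clade))
})
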