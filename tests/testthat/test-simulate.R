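test_that("K2P mutation is deterministic, bounded, and dose-accurate", {
  set.seed(61)
  s <- rand_seq(10000)
  expect_identical(mutate_k2p(s, 0), s)
  expect_identical(mutate_k2p(s, 0.1, seed = 1), mutate_k2p(s, 0.1, seed = 1))
  expect_error(mutate_k2p(s, 0.8), "0.75")
  expect_error(mutate_k2p(s, -0.1), "0.75")

  # realized substitution fraction within 3 binomial SE of expectation
  true_K <- 0.05
  m <- mutate_k2p(s, true_K, seed = 2)
  p_sub <- {  # total per-site substitution probability at this divergence
    rho <- 2
    e4 <- exp(-2 * true_K / (rho + 1))
    e2 <- exp(-(2 * rho + 1) * true_K / (rho + 1))
    (1 / 4 + 1 / 4 * e4 - 1 / 2 * e2) + (1 / 2 - 1 / 2 * e4)
  }
  diff_frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  se <- sqrt(p_sub * (1 - p_sub) / 10000)
  expect_lt(abs(diff_frac - p_sub), 3 * se)

  # protected positions never change
  m <- mutate_k2p(s, 0.5, seed = 3, protect = 1:100)
  expect_identical(substr(m, 1, 100), substr(s, 1, 100))
})

test_that("simulation is reproducible and internally consistent", {
  a <- simulate_genome(n_seqs = 1, seq_len = 1e5,
                       implants = default_implants(3), seed = 11)
  b <- simulate_genome(n_seqs = 1, seq_len = 1e5,
                       implants = default_implants(3), seed = 11)
  expect_identical(a$genome$residues, b$genome$residues)
  expect_identical(a$elements, b$elements)

  s <- a$genome$residues[1]
  for (i in seq_len(nrow(a$elements))) {
    e <- a$elements[i, ]
    # terminal motif and TSD as recorded
    expect_equal(substr(s, e$start + 1, e$start + 2), "TG")
    expect_equal(substr(s, e$end - 1, e$end), "CA")
    expect_equal(substr(s, e$start - nchar(e$tsd_left) + 1, e$start),
                 e$tsd_left)
    expect_equal(substr(s, e$end + 1, e$end + nchar(e$tsd_right)),
                 e$tsd_right)
  }

  # zero divergence -> identical LTR copies
  e <- a$elements[1, ]
  expect_identical(substr(s, e$ltr5_start + 1, e$ltr5_end),
                   substr(s, e$ltr3_start + 1, e$ltr3_end))

  # PBS spans hold the reverse complement of the named tRNA tail
  for (i in seq_len(nrow(a$pbs))) {
    h <- a$pbs[i, ]
    e <- a$elements[match(h$element_id, a$elements$element_id), ]
    site <- substr(s, e$start + h$start + 1, e$start + h$end)
    trna <- a$trnas$residues[match(h$trna_id, a$trnas$seq_id)]
    tail18 <- substr(trna, nchar(trna) - 17, nchar(trna))
    expect_equal(
      site,
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail18))))
  }

  # PPT spans are pure purine
  for (i in seq_len(nrow(a$ppt))) {
    h <- a$ppt[i, ]
    e <- a$elements[match(h$element_id, a$elements$element_id), ]
    site <- substr(s, e$start + h$start + 1, e$start + h$end)
    expect_true(all(strsplit(site, "")[[1]] %in% c("A", "G")))
  }
})

test_that("diverged implants carry the divergence only in the 3' LTR", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 1e5,
                         implants = default_implants(2, true_K = 0.1),
                         seed = 12)
  s <- sim$genome$residues[1]
  e <- sim$elements[1, ]
  ltr5 <- substr(s, e$ltr5_start + 1, e$ltr5_end)
  ltr3 <- substr(s, e$ltr3_start + 1, e$ltr3_end)
  expect_false(identical(ltr5, ltr3))
  # conserved termini survive mutation
  expect_equal(substr(ltr3, 1, 2), "TG")
  expect_equal(substr(ltr3, nchar(ltr3) - 1, nchar(ltr3)), "CA")
  # recorded similarity matches a direct per-site comparison
  expect_equal(e$ltr_similarity,
               mean(strsplit(ltr5, "")[[1]] == strsplit(ltr3, "")[[1]]))
})

test_that("implants that cannot fit raise an error", {
  expect_error(
    simulate_genome(n_seqs = 1, seq_len = 2e4,
                    implants = default_implants(6), seed = 1),
    "fit")
})

test_that("truth files are valid inputs for the rest of the toolkit", {
  sim <- simulate_genome(n_seqs = 2, seq_len = 1e5,
                         implants = default_implants(4), seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))

  g <- read_fasta(paths[["genome"]])
  expect_identical(g$residues, sim$genome$residues)
  back <- read_element_gff3(paths[["elements"]])
  expect_equal(back$elements, sim$elements)
  expect_equal(
    dplyr::arrange(back$domains, element_id, start),
    dplyr::arrange(sim$domains, element_id, start))
  expect_equal(
    dplyr::arrange(back$pbs, element_id), dplyr::arrange(sim$pbs, element_id))
  expect_equal(
    dplyr::arrange(back$ppt, element_id), dplyr::arrange(sim$ppt, element_id))
  genes <- read_gff3_genes(paths[["genes"]])
  expect_setequal(genes$gene_id, sim$genes$gene_id)
  doms <- read_domain_tsv(paths[["domains"]])
  expect_equal(dplyr::arrange(doms, element_id, start),
               dplyr::arrange(sim$domains, element_id, start))
})

test_that("truth ids map onto detected ids by overlap", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 2e5,
                         implants = default_implants(4), seed = 14)
  det <- detect_elements(sim$genome, ltr_config())
  mp <- map_truth_ids(sim$elements, det)
  expect_equal(nrow(mp), 4)
  expect_false(any(is.na(mp$detected_id)))
  expect_equal(mp$overlap_bp,
               sim$elements$end - sim$elements$start)  # exact recovery
})
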