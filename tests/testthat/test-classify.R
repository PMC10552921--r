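cfg <- ltr_config()

mk_hits <- function(domains, starts = NULL, sf = NA_character_,
                    clade = NA_character_, len = 300L) {
  if (is.null(starts)) starts <- seq_along(domains) * 1000L
  tibble::tibble(element_id = "e1", domain = domains,
                 start = as.integer(starts),
                 end = as.integer(starts + len),
                 superfamily = sf, clade = clade)
}

test_that("domain order sorts by position, reverses on minus strand, drops OTHER", {
  h <- mk_hits(c("RT", "GAG", "INT", "PROT", "RH"),
               starts = c(2000, 500, 3800, 1200, 3000))
  expect_equal(domain_order(h, "+")$order,
               c("GAG", "PROT", "RT", "RH", "INT"))
  expect_equal(domain_order(h, "-")$order,
               c("INT", "RH", "RT", "PROT", "GAG"))
  expect_equal(domain_order(mk_hits(character(0)))$order, character(0))

  with_other <- mk_hits(c("GAG", "OTHER", "RT"), starts = c(100, 500, 900))
  expect_equal(domain_order(with_other, "+")$order, c("GAG", "RT"))

  dup <- mk_hits(c("GAG", "GAG", "RT"), starts = c(100, 600, 1200))
  expect_equal(domain_order(dup, "+")$order, c("GAG", "RT"))
})

test_that("overlapping core hits keep the longer and record a warning token", {
  h <- tibble::tibble(element_id = "e1", domain = c("RT", "RH"),
                      start = c(100L, 200L), end = c(700L, 500L),
                      superfamily = NA_character_, clade = NA_character_)
  od <- domain_order(h, "+")
  expect_equal(od$order, "RT")
  expect_match(od$warnings, "overlap_dropped:RH")
})

classify1 <- function(order, pbs = TRUE, ppt = TRUE, total = 5000,
                      internal = 4000, sf = character(0),
                      clade = character(0), cfg. = cfg) {
  classify_element(order, pbs, ppt, total, internal,
                   superfamily_labels = sf, clade_labels = clade, cfg = cfg.)
}

test_that("the cascade reproduces the canonical templates", {
  expect_equal(classify1(c("GAG", "PROT", "INT", "RT", "RH"))$category,
               "AUTON_COPIA")
  expect_equal(classify1(c("GAG", "PROT", "RT", "RH", "INT"))$category,
               "AUTON_GYPSY")
  # full Gypsy order but PPT missing -> non-autonomous Gypsy
  expect_equal(classify1(c("GAG", "PROT", "RT", "RH", "INT"),
                         ppt = FALSE)$category, "NONAUTON_GYPSY")
  expect_equal(classify1("GAG")$category, "TR_GAG")
  expect_equal(classify1(c("PROT", "RT", "RH", "INT"))$category, "BARE2")
  expect_equal(classify1(character(0), total = 650,
                         internal = 300)$category, "TRIM")
  expect_equal(classify1(character(0), total = 5600,
                         internal = 5000)$category, "LARD")
  expect_equal(classify1(character(0), total = 3000,
                         internal = 2000)$category, "UNKNOWN")
})

test_that("non-autonomous superfamily resolves by vote, then INT position", {
  expect_equal(classify1(c("GAG", "RT", "RH", "INT"))$category,
               "NONAUTON_GYPSY")  # INT after RH
  expect_equal(classify1(c("GAG", "INT", "RT", "RH"))$category,
               "NONAUTON_COPIA")  # INT before RT
  # label vote overrides nothing here but decides when positions cannot
  expect_equal(classify1(c("GAG", "RT"), sf = c("Copia", "Copia"))$category,
               "NONAUTON_COPIA")
  got <- classify1(c("GAG", "RT"))
  expect_equal(got$category, "UNKNOWN")
  expect_match(got$rule_trace, "undecidable")
})

test_that("clade is the majority label, ties unset", {
  got <- classify1(c("GAG", "PROT", "INT", "RT", "RH"),
                   clade = c("Ale", "Ale", "Ale", "SIRE", NA))
  expect_equal(got$clade, "Ale")
  got <- classify1(c("GAG", "RT"), clade = c("Ale", "Tekay"))
  expect_true(is.na(got$clade))
})

test_that("autonomy can be relaxed to domains only", {
  relaxed <- ltr_config(autonomy_requires_pbs_ppt = FALSE)
  expect_equal(classify1(c("GAG", "PROT", "RT", "RH", "INT"), pbs = FALSE,
                         ppt = FALSE, cfg. = relaxed)$category,
               "AUTON_GYPSY")
})

all_orders <- local({
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  doms <- c("GAG", "PROT", "INT", "RT", "RH")
  out <- list(character(0))
  for (k in 1:5) {
    for (subset in utils::combn(doms, k, simplify = FALSE)) {
      out <- c(out, perms(subset))
    }
  }
  out
})

test_that("the cascade is total and only canonical orders become autonomous", {
  regimes <- list(c(total = 650, internal = 300),
                  c(total = 3000, internal = 2000),
                  c(total = 6000, internal = 5000))
  canonical <- list(c("GAG", "PROT", "RT", "RH", "INT"),
                    c("GAG", "PROT", "INT", "RT", "RH"))
  n_checked <- 0
  for (ord in all_orders) {
    for (pbs in c(TRUE, FALSE)) {
      for (ppt in c(TRUE, FALSE)) {
        for (rg in regimes) {
          got <- classify1(ord, pbs, ppt, rg[["total"]], rg[["internal"]])
          expect_length(got$category, 1)
          expect_true(got$category %in% c(
            "AUTON_GYPSY", "AUTON_COPIA", "NONAUTON_GYPSY",
            "NONAUTON_COPIA", "LARD", "TRIM", "TR_GAG", "BARE2", "UNKNOWN"))
          expect_true(nzchar(got$rule_trace))
          is_auto <- got$category %in% c("AUTON_GYPSY", "AUTON_COPIA")
          should_auto <- pbs && ppt &&
            (identical(ord, canonical[[1]]) || identical(ord, canonical[[2]]))
          expect_equal(is_auto, should_auto)
          n_checked <- n_checked + 1
        }
      }
    }
  }
  expect_equal(n_checked, 326 * 2 * 2 * 3)
})

test_that("classify_elements ties the pieces together per element", {
  sim <- simulate_genome(n_seqs = 1, seq_len = 3e5,
                         implants = default_implants(7), seed = 6)
  cl <- classify_elements(sim$elements, sim$domains, sim$pbs, sim$ppt, cfg)
  truth <- sim$classifications
  m <- match(cl$element_id, truth$element_id)
  expect_equal(cl$category, truth$category[m])
  expect_equal(cl$superfamily, truth$superfamily[m])
  expect_true(all(nzchar(cl$rule_trace)))
})
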