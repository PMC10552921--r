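# Synthetic-genome simulator. Implants LTR-RT cassettes of chosen template
# structure into i.i.d. random background and emits complete truth
# annotations, so every downstream stage can be validated without external
# data. LTR copies diverge by K2P substitutions only (no indels — matching
# the dating model); the terminal TG/CA dinucleotides of each LTR are
# exempt from mutation, mirroring their conservation in real elements. The
# polypurine tract is embedded in a pyrimidine pad filling its search
# window, so the truth span is the unique maximal tract by construction.

TEMPLATE_ENUM <- c("AUTON_GYPSY", "AUTON_COPIA", "NONAUTON_GYPSY",
                   "NONAUTON_COPIA", "LARD", "TRIM", "TR_GAG", "BARE2")

TEMPLATE_DOMAINS <- list(
  AUTON_GYPSY = c("GAG", "PROT", "RT", "RH", "INT"),
  AUTON_COPIA = c("GAG", "PROT", "INT", "RT", "RH"),
  NONAUTON_GYPSY = c("GAG", "RT", "RH", "INT"),
  NONAUTON_COPIA = c("GAG", "INT", "RT", "RH"),
  LARD = character(0), TRIM = character(0),
  TR_GAG = "GAG", BARE2 = c("PROT", "RT", "RH", "INT")
)

TEMPLATE_SUPERFAMILY <- c(
  AUTON_GYPSY = "Gypsy", AUTON_COPIA = "Copia",
  NONAUTON_GYPSY = "Gypsy", NONAUTON_COPIA = "Copia",
  LARD = NA, TRIM = NA, TR_GAG = NA, BARE2 = NA
)

GYPSY_CLADES <- c("Tekay", "Athila", "Retand", "Reina", "CRM")
COPIA_CLADES <- c("Ale", "SIRE", "Ivana", "Tork", "Angela")

# default template geometries; distances between LTR starts
# (ltr_len + internal_len) all sit inside the default [d, D] = [1000, 15000]
# except TRIM, whose miniature geometry needs a smaller d to be detectable
TEMPLATE_GEOMETRY <- list(
  AUTON_GYPSY = c(ltr = 300, internal = 2000),
  AUTON_COPIA = c(ltr = 220, internal = 1500),
  NONAUTON_GYPSY = c(ltr = 300, internal = 2900),
  NONAUTON_COPIA = c(ltr = 250, internal = 1000),
  LARD = c(ltr = 200, internal = 3800),
  TRIM = c(ltr = 120, internal = 400),
  TR_GAG = c(ltr = 200, internal = 900),
  BARE2 = c(ltr = 150, internal = 5200)
)

#' Implant specifications
#'
#' `implant_spec()` builds one implant description; `default_implants()`
#' cycles `n` implants over the seven default templates that are
#' detectable under the default distance bounds (all but TRIM, whose
#' miniature geometry puts its LTR separation below the default minimum
#' distance `d`).
#'
#' @param template One of the structural templates
#'   (`r paste(TEMPLATE_ENUM, collapse = ", ")`).
#' @param ltr_len,internal_len Geometry in bp (defaults per template).
#' @param true_K Expected K2P divergence simulated between the LTR copies.
#' @param tsd_len Target-site-duplication length (bp).
#' @param with_pbs,with_ppt Implant a PBS / PPT.
#' @param trna_id Named tRNA used for the PBS (`NA` = first available).
#' @return A one-row tibble (or, for `default_implants()`, `n` rows).
#' @export
implant_spec <- function(template, ltr_len = NULL, internal_len = NULL,
                         true_K = 0, tsd_len = 5, with_pbs = TRUE,
                         with_ppt = TRUE, trna_id = NA_character_) {
  template <- match.arg(template, TEMPLATE_ENUM)
  geo <- TEMPLATE_GEOMETRY[[template]]
  if (is.null(ltr_len)) ltr_len <- geo[["ltr"]]
  if (is.null(internal_len)) internal_len <- geo[["internal"]]
  if (template == "TRIM" && 2 * ltr_len + internal_len > 1000) {
    abort("implant_spec: TRIM template must not exceed 1000 bp in total")
  }
  tibble(template = template, ltr_len = as.integer(ltr_len),
         internal_len = as.integer(internal_len), true_K = true_K,
         tsd_len = as.integer(tsd_len), with_pbs = with_pbs,
         with_ppt = with_ppt, trna_id = trna_id)
}

#' @rdname implant_spec
#' @param n Number of implants.
#' @param true_K Divergence applied to every implant.
#' @param templates Templates to cycle over.
#' @export
default_implants <- function(n = 50, true_K = 0,
                             templates = setdiff(TEMPLATE_ENUM, "TRIM")) {
  list_rbind(map(seq_len(n), function(i) {
    implant_spec(templates[(i - 1) %% length(templates) + 1],
                 true_K = true_K)
  }))
}

#' Synthetic tRNA set
#'
#' Random tRNA-like sequences with plant-database-style ids; purely
#' synthetic stand-ins for a real tRNA library.
#'
#' @param n Number of tRNAs.
#' @param len Sequence length (nt).
#' @param seed Optional RNG seed.
#' @return A tibble `seq_id`, `residues`.
#' @export
synthetic_trnas <- function(n = 8, len = 76, seed = NULL) {
  aas <- c("Met", "Lys", "Arg", "Gly", "Trp", "Asn", "Ser", "Ile",
           "Leu", "Pro", "Thr", "Val")
  gen <- function() {
    tibble(seq_id = paste0("tRNA-", aas[((seq_len(n) - 1) %% length(aas)) + 1],
                           "-", seq_len(n)),
           residues = vapply(seq_len(n), function(i) random_dna(len),
                             character(1)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Mutate a sequence under the Kimura two-parameter model
#'
#' Each site is substituted independently with the exact K2P column
#' probabilities for divergence `true_K` and transition/transversion ratio
#' `ts_tv_ratio` (expected observed ts/tv at small divergence), so the
#' expected K2P distance between input and output equals `true_K`.
#' Substitutions only — no indels.
#'
#' @param seq Character scalar over `A,C,G,T` (N left untouched).
#' @param true_K Target divergence, `0 <= true_K < 0.75`.
#' @param ts_tv_ratio Transition/transversion ratio (default 2).
#' @param seed Optional seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @param protect Integer positions (1-based) never mutated.
#' @return The mutated sequence.
#' @export
mutate_k2p <- function(seq, true_K, ts_tv_ratio = 2, seed = NULL,
                       protect = integer(0)) {
  if (!(true_K >= 0 && true_K < 0.75)) {
    abort("mutate_k2p: true_K must lie in [0, 0.75)")
  }
  run <- function() {
    if (true_K == 0) return(seq)
    ch <- seq_chars(seq)
    n <- length(ch)
    # alpha = 2*rho*beta gives observed ts/tv -> rho at small distance;
    # with d = (alpha + 2 beta) t the column probabilities are
    #   P(ts) = 1/4 + 1/4 e4 - 1/2 e2,  P(tv) = 1/2 - 1/2 e4
    # where e4 = exp(-2d/(rho+1)), e2 = exp(-(2 rho + 1) d / (rho + 1))
    rho <- ts_tv_ratio
    e4 <- exp(-2 * true_K / (rho + 1))
    e2 <- exp(-(2 * rho + 1) * true_K / (rho + 1))
    p_ts <- 1 / 4 + 1 / 4 * e4 - 1 / 2 * e2
    p_tv <- 1 / 2 - 1 / 2 * e4
    u <- stats::runif(n)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    std <- ch %in% c("A", "C", "G", "T")
    do_ts <- std & u < p_ts
    do_tv <- std & u >= p_ts & u < p_ts + p_tv
    pick <- stats::runif(n) < 0.5
    out <- ch
    out[do_ts] <- ts_map[ch[do_ts]]
    out[do_tv & pick] <- tv1[ch[do_tv & pick]]
    out[do_tv & !pick] <- tv2[ch[do_tv & !pick]]
    if (length(protect)) out[protect] <- ch[protect]
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# build one implant cassette; returns the cassette string plus truth
# feature tables in cassette-local coordinates (0-based, excluding TSDs)
build_cassette <- function(spec, trnas, domain_len = 200) {
  ltr_len <- spec$ltr_len
  if (ltr_len < 10) abort("simulate_genome: ltr_len too short")
  ltr <- paste0("TG", random_dna(ltr_len - 4), "CA")
  protect <- c(1L, 2L, ltr_len - 1L, ltr_len)
  ltr3 <- mutate_k2p(ltr, spec$true_K, protect = protect)

  doms <- TEMPLATE_DOMAINS[[spec$template]]
  internal_len <- spec$internal_len
  pbs_len <- 18L; pbs_gap <- 3L
  ppt_len <- 14L; ppt_gap <- 5L; ppt_window <- 50L
  need <- (if (spec$with_pbs) pbs_gap + pbs_len else 0L) + 10L +
    length(doms) * domain_len + (if (spec$with_ppt) ppt_window else 0L)
  if (internal_len < need) {
    abort(sprintf("simulate_genome: internal_len %d too small for template %s (needs %d)",
                  internal_len, spec$template, need))
  }
  pieces <- character(0)
  cursor <- 0L
  pbs_truth <- NULL; dom_truth <- list()
  push <- function(s) {
    pieces <<- c(pieces, s); cursor <<- cursor + nchar(s)
  }
  trna_id <- spec$trna_id
  if (spec$with_pbs) {
    if (is.na(trna_id)) trna_id <- trnas$seq_id[order(trnas$seq_id)][1]
    t_seq <- trnas$residues[match(trna_id, trnas$seq_id)]
    if (is.na(t_seq)) abort(paste0("simulate_genome: unknown tRNA ", trna_id))
    tail18 <- substr(t_seq, nchar(t_seq) - pbs_len + 1, nchar(t_seq))
    push(random_dna(pbs_gap))
    pbs_truth <- list(start = cursor, len = pbs_len, trna_id = trna_id)
    push(revcomp_chr(tail18))
  }
  push(random_dna(10))
  sf <- TEMPLATE_SUPERFAMILY[[spec$template]]
  clade <- if (is.na(sf)) NA_character_ else if (sf == "Gypsy") {
    sample(GYPSY_CLADES, 1)
  } else sample(COPIA_CLADES, 1)
  for (d in doms) {
    dom_truth[[length(dom_truth) + 1]] <- list(domain = d, start = cursor,
                                               len = domain_len)
    push(random_dna(domain_len))
  }
  tail_len <- if (spec$with_ppt) ppt_window else 0L
  push(random_dna(internal_len - cursor - tail_len))
  ppt_truth <- NULL
  if (spec$with_ppt) {
    pyr <- function(k) paste(sample(c("C", "T"), k, TRUE), collapse = "")
    push(pyr(ppt_window - ppt_len - ppt_gap))
    ppt_truth <- list(start = cursor, len = ppt_len)
    push(paste(sample(c("A", "G"), ppt_len, TRUE), collapse = ""))
    push(pyr(ppt_gap))
  }
  internal <- paste(pieces, collapse = "")
  stopifnot(nchar(internal) == internal_len)

  sim_sim <- mean(seq_chars(ltr) == seq_chars(ltr3))
  list(
    cassette = paste0(ltr, internal, ltr3),
    ltr_len = ltr_len, internal_len = internal_len,
    ltr_similarity = sim_sim,
    pbs = pbs_truth, ppt = ppt_truth, domains = dom_truth,
    superfamily = sf, clade = clade
  )
}

#' Simulate a genome with implanted LTR-RT elements
#'
#' Background bases are i.i.d. at the stated GC; each implant cassette is
#' `TSD - 5'LTR - internal - 3'LTR - TSD` with the requested features, the
#' 3' LTR mutated to expected K2P divergence `true_K`. Implants are spread
#' across evenly sized slots with at least 1 kb of background on each side
#' (an error if they cannot fit). Gene records are placed both at random
#' and in controlled relation to elements (containing an element, or 100 bp
#' downstream of one) so gene-context calls have known answers.
#'
#' @param n_seqs Number of sequences.
#' @param seq_len Length of each sequence (bp).
#' @param gc GC content of the background.
#' @param implants Implant tibble from [default_implants()] /
#'   [implant_spec()]; distributed round-robin over sequences.
#' @param gene_density Random genes per Mb (in addition to the controlled
#'   placements).
#' @param seed RNG seed; the single global seed for the whole simulation.
#' @param trnas tRNA tibble; defaults to [synthetic_trnas()] drawn inside
#'   the same seeded stream.
#' @param domain_len Length of each implanted domain placeholder (bp).
#' @param low_complexity_run If positive, length of a poly-A run spiked
#'   into the background of the first sequence (stress test for the seed
#'   stage).
#' @return An `ltr_sim` object: list with `genome`, `elements`, `domains`,
#'   `pbs`, `ppt`, `classifications`, `ages` (`element_id`, `true_K`),
#'   `genes`, `trnas`, `seed`, `params`.
#' @export
simulate_genome <- function(n_seqs = 1, seq_len = 2e6, gc = 0.4,
                            implants = default_implants(), gene_density = 5,
                            seed = 1, trnas = NULL, domain_len = 200,
                            low_complexity_run = 0) {
  slen <- as.integer(seq_len)
  withr::with_seed(seed, {
    if (is.null(trnas)) trnas <- synthetic_trnas()
    seq_ids <- sprintf("chr%d", seq_len(n_seqs))
    per_seq <- split(seq_len(nrow(implants)),
                     rep_len(seq_len(n_seqs), nrow(implants)))
    genome_rows <- list()
    el <- list(); dom <- list(); pbs <- list(); ppt <- list()
    cls <- list(); ages <- list(); genes <- list()
    eid <- 0L
    for (si in seq_len(n_seqs)) {
      idx <- per_seq[[as.character(si)]]
      if (si > length(per_seq) || is.null(idx)) idx <- integer(0)
      n_imp <- length(idx)
      pieces <- character(0); cursor <- 0L
      push <- function(s) {
        pieces <<- c(pieces, s); cursor <<- cursor + nchar(s)
      }
      if (n_imp > 0) {
        slot <- slen %/% n_imp
        for (k in seq_len(n_imp)) {
          spec <- implants[idx[k], ]
          cas <- build_cassette(spec, trnas, domain_len)
          cas_len <- nchar(cas$cassette) + 2L * spec$tsd_len
          free <- slot - cas_len - 2000L
          if (free < 0) {
            abort("simulate_genome: implants do not fit with 1 kb spacing")
          }
          target <- (k - 1L) * slot + 1000L + sample.int(free + 1L, 1) - 1L
          push(random_dna(target - cursor, gc))
          tsd <- random_dna(spec$tsd_len, gc)
          push(tsd)
          eid <- eid + 1L
          id <- sprintf("SIM_%05d", eid)
          start <- cursor
          push(cas$cassette)
          end <- cursor
          push(tsd)
          el[[eid]] <- tibble(
            element_id = id, seq_id = seq_ids[si],
            start = start, end = end, strand = "+",
            ltr5_start = start, ltr5_end = start + cas$ltr_len,
            ltr3_start = end - cas$ltr_len, ltr3_end = end,
            tsd_left = tsd, tsd_right = tsd, terminal_motif = "TGCA",
            ltr_similarity = cas$ltr_similarity
          )
          off <- cas$ltr_len  # internal features recorded element-locally
          for (dt in cas$domains) {
            dom[[length(dom) + 1]] <- tibble(
              element_id = id, domain = dt$domain,
              start = off + dt$start, end = off + dt$start + dt$len,
              superfamily = cas$superfamily, clade = cas$clade)
          }
          if (!is.null(cas$pbs)) {
            pbs[[length(pbs) + 1]] <- tibble(
              element_id = id, start = off + cas$pbs$start,
              end = off + cas$pbs$start + cas$pbs$len,
              trna_id = cas$pbs$trna_id, match_len = cas$pbs$len,
              offset_from_5ltr = as.integer(cas$pbs$start))
          }
          if (!is.null(cas$ppt)) {
            ppt[[length(ppt) + 1]] <- tibble(
              element_id = id, start = off + cas$ppt$start,
              end = off + cas$ppt$start + cas$ppt$len,
              purine_fraction = 1.0,
              offset_from_3ltr = as.integer(
                cas$internal_len - (cas$ppt$start + cas$ppt$len)))
          }
          cls[[eid]] <- tibble(
            element_id = id, category = spec$template,
            superfamily = ifelse(is.na(cas$superfamily), "unknown",
                                 cas$superfamily),
            clade = cas$clade)
          ages[[eid]] <- tibble(element_id = id, true_K = spec$true_K)
          # controlled gene placements for gene-context truth
          if (k %% 5 == 1) {
            genes[[length(genes) + 1]] <- tibble(
              gene_id = paste0(id, "_host_gene"), seq_id = seq_ids[si],
              start = start - 200L, end = end + 200L, strand = "+")
          } else if (k %% 5 == 2) {
            genes[[length(genes) + 1]] <- tibble(
              gene_id = paste0(id, "_near_gene"), seq_id = seq_ids[si],
              start = end + spec$tsd_len + 100L,
              end = end + spec$tsd_len + 500L, strand = "+")
          }
        }
      }
      push(random_dna(slen - cursor, gc))
      s <- paste(pieces, collapse = "")
      if (si == 1 && low_complexity_run > 0) {
        # overwrite a background stretch near the end with poly-A
        p0 <- slen - low_complexity_run - 100L
        s <- paste0(substr(s, 1, p0), strrep("A", low_complexity_run),
                    substr(s, p0 + low_complexity_run + 1, slen))
      }
      genome_rows[[si]] <- tibble(seq_id = seq_ids[si], residues = s,
                                  length = nchar(s))
      # random background genes
      n_rand <- as.integer(round(gene_density * slen / 1e6))
      if (n_rand > 0) {
        gs <- sort(sample.int(slen - 2000L, n_rand))
        genes[[length(genes) + 1]] <- tibble(
          gene_id = sprintf("%s_rgene_%04d", seq_ids[si], seq_len(n_rand)),
          seq_id = seq_ids[si], start = gs, end = gs + 1500L, strand = "+")
      }
    }
    structure(list(
      genome = list_rbind(genome_rows),
      elements = validate_elements(list_rbind(c(list(empty_elements()), el))),
      domains = list_rbind(c(list(empty_domains()), dom)),
      pbs = list_rbind(c(list(empty_pbs()), pbs)),
      ppt = list_rbind(c(list(empty_ppt()), ppt)),
      classifications = list_rbind(c(
        list(tibble(element_id = character(), category = character(),
                    superfamily = character(), clade = character())), cls)),
      ages = list_rbind(c(
        list(tibble(element_id = character(), true_K = double())), ages)),
      genes = list_rbind(c(
        list(tibble(gene_id = character(), seq_id = character(),
                    start = integer(), end = integer(),
                    strand = character())), genes)),
      trnas = trnas, seed = seed,
      params = list(n_seqs = n_seqs, seq_len = slen, gc = gc,
                    gene_density = gene_density, domain_len = domain_len)
    ), class = "ltr_sim")
  })
}

#' @export
print.ltr_sim <- function(x, ...) {
  cat(sprintf("<ltr_sim> %d sequence(s), %d implanted element(s), seed %d\n",
              nrow(x$genome), nrow(x$elements), x$seed))
  invisible(x)
}

#' @rdname simulate_genome
#' @param x An `ltr_sim` object.
#' @param ... Unused.
#' @export
glance.ltr_sim <- function(x, ...) {
  tibble(n_seqs = nrow(x$genome), total_bp = sum(x$genome$length),
         n_elements = nrow(x$elements), n_genes = nrow(x$genes),
         seed = x$seed)
}

#' Write a simulation and its truth files to a directory
#'
#' Emits `genome.fa`, `trnas.fa`, `truth_elements.gff3` (elements with
#' features and classifications), `genes.gff3`, `truth_domains.tsv` and
#' `truth_ages.tsv` — all valid inputs for the rest of the toolkit.
#'
#' @param sim An `ltr_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    trnas = file.path(dir, "trnas.fa"),
    elements = file.path(dir, "truth_elements.gff3"),
    genes = file.path(dir, "genes.gff3"),
    domains = file.path(dir, "truth_domains.tsv"),
    ages = file.path(dir, "truth_ages.tsv")
  )
  write_fasta(sim$genome, paths["genome"])
  write_fasta(sim$trnas, paths["trnas"])
  write_element_gff3(sim$elements, paths["elements"], domains = sim$domains,
                     pbs = sim$pbs, ppt = sim$ppt,
                     classifications = sim$classifications)
  write_gff3_genes(sim$genes, paths["genes"])
  write_domain_tsv(sim$domains, paths["domains"])
  write_tsv_plain(sim$ages, paths["ages"])
  paths
}

#' Map truth element ids onto detected element ids
#'
#' Matches two element tables by genomic overlap (same `seq_id`, largest
#' shared span), e.g. simulator truth against detector output, so truth
#' feature tables can be re-keyed to detected ids.
#'
#' @param truth,detected Element tibbles.
#' @return A tibble `truth_id`, `detected_id` (`NA` where unmatched),
#'   `overlap_bp`.
#' @export
map_truth_ids <- function(truth, detected) {
  rows <- map(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    d <- detected[detected$seq_id == t$seq_id, ]
    ov <- pmin(d$end, t$end) - pmax(d$start, t$start)
    best <- if (nrow(d) && max(ov) > 0) which.max(ov) else NA_integer_
    tibble(truth_id = t$element_id,
           detected_id = if (is.na(best)) NA_character_ else
             d$element_id[best],
           overlap_bp = if (is.na(best)) 0L else as.integer(ov[best]))
  })
  list_rbind(c(list(tibble(truth_id = character(),
                           detected_id = character(),
                           overlap_bp = integer())), rows))
}
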