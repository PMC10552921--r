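# Insertion-age estimation. The two LTRs of an element are identical at
# insertion time and diverge neutrally afterwards, so the Kimura
# two-parameter distance K between the 5' and 3' LTR, divided by twice the
# per-site per-year substitution rate r, dates the insertion: T = K / (2 r).

#' Align the two LTRs of each element
#'
#' Global (end-to-end) affine-gap alignment of the 5' versus 3' LTR
#' sequence of every element, followed by per-column divergence counting.
#' Columns with a gap or an `N` in either row are excluded from
#' `aligned_sites` (complete deletion). Transitions are A<->G and C<->T;
#' every other differing pair is a transversion.
#'
#' @param elements Element tibble.
#' @param genome Genome tibble from [read_fasta()].
#' @param cfg An [ltr_config()] (alignment scoring).
#' @return A tibble `element_id`, `aligned_sites`, `transitions`,
#'   `transversions`.
#' @export
align_ltrs <- function(elements, genome, cfg = ltr_config()) {
  rows <- map(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    a <- genome_subseq(genome, e$seq_id, e$ltr5_start, e$ltr5_end)
    b <- genome_subseq(genome, e$seq_id, e$ltr3_start, e$ltr3_end)
    aln <- align_global(a, b, cfg$match, cfg$mismatch, cfg$gap_open,
                        cfg$gap_extend)
    cnt <- count_divergence(aln$aligned_a, aln$aligned_b)
    mutate(cnt, element_id = e$element_id, .before = 1)
  })
  if (!length(rows)) {
    return(tibble(element_id = character(), aligned_sites = integer(),
                  transitions = integer(), transversions = integer()))
  }
  list_rbind(rows)
}

#' Count transitions and transversions in an aligned pair
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return A one-row tibble `aligned_sites`, `transitions`, `transversions`.
#' @export
count_divergence <- function(aligned_a, aligned_b) {
  ca <- seq_chars(toupper(aligned_a))
  cb <- seq_chars(toupper(aligned_b))
  if (length(ca) != length(cb)) {
    abort("count_divergence: rows have different lengths")
  }
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  # same purine/pyrimidine class and different base -> transition
  cls_a <- ca %in% c("A", "G")
  cls_b <- cb %in% c("A", "G")
  ts <- diff & (cls_a == cls_b)
  tibble(aligned_sites = length(ca),
         transitions = sum(ts),
         transversions = sum(diff & !ts))
}

#' Kimura two-parameter distance
#'
#' Completes a divergence-count table with the transition proportion `P`,
#' transversion proportion `Q` and the K2P distance
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) get `K = NA` and
#' `flag = "saturated"`; they are never aged.
#'
#' @param div A tibble with `aligned_sites`, `transitions`, `transversions`
#'   (e.g. from [align_ltrs()]).
#' @return The input with columns `P`, `Q`, `K`, `flag` added.
#' @export
k2p <- function(div) {
  if (any(div$aligned_sites <= 0)) {
    abort("k2p: aligned_sites must be positive")
  }
  P <- div$transitions / div$aligned_sites
  Q <- div$transversions / div$aligned_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- w1 <= 0 | w2 <= 0
  K <- ifelse(sat, NA_real_, -0.5 * log(w1 * sqrt(w2)))
  mutate(div, P = P, Q = Q, K = K,
         flag = ifelse(sat, "saturated", "ok"))
}

#' Insertion age from K
#'
#' `T = K / (2 r)` in years, with `r` the neutral substitution rate in
#' substitutions/site/year; `T_mya = T / 1e6`.
#'
#' @param K Numeric vector of K2P distances (NA allowed for saturated
#'   pairs).
#' @param r Substitution rate (> 0), typically `cfg$R`.
#' @return A tibble `K`, `r`, `T`, `T_mya`.
#' @export
estimate_age <- function(K, r) {
  if (is.null(r) || !is.numeric(r) || length(r) != 1 || r <= 0) {
    abort("estimate_age: the substitution rate r must be a positive number")
  }
  T_years <- K / (2 * r)
  tibble(K = K, r = r, T = T_years, T_mya = T_years / 1e6)
}

#' Full age table for a set of elements
#'
#' Chains [align_ltrs()], [k2p()] and [estimate_age()].
#'
#' @inheritParams align_ltrs
#' @param r Substitution rate (substitutions/site/year).
#' @return A tibble `element_id`, `aligned_sites`, `transitions`,
#'   `transversions`, `P`, `Q`, `K`, `r`, `T`, `T_mya`, `flag`.
#' @export
estimate_ages <- function(elements, genome, r, cfg = ltr_config()) {
  div <- k2p(align_ltrs(elements, genome, cfg))
  age <- estimate_age(div$K, r)
  mutate(div, r = age$r, T = age$T, T_mya = age$T_mya) |>
    select("element_id", "aligned_sites", "transitions", "transversions",
           "P", "Q", "K", "r", "T", "T_mya", "flag")
}

#' Write an age table as TSV
#'
#' @param ages Age tibble from [estimate_ages()].
#' @param path Output path.
#' @export
write_age_tsv <- function(ages, path) write_tsv_plain(ages, path)
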