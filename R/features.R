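# PBS and PPT annotation inside the internal region. The primer binding
# site sits just downstream of the 5' LTR and is complementary to the 3'
# tail of a host tRNA; the polypurine tract is a purine-rich run just
# upstream of the 3' LTR. Minus-strand elements are scanned on the reverse
# complement so both features stay adjacent to their biological LTR.

PURINES <- c("A", "G")

element_internal_seq <- function(e, genome) {
  s <- genome_subseq(genome, e$seq_id, e$start, e$end)
  if (identical(e$strand, "-")) s <- revcomp_chr(s)
  s
}

# element-local LTR bounds on the element strand
local_ltr_bounds <- function(e) {
  len <- e$end - e$start
  if (identical(e$strand, "-")) {
    list(ltr5_end = e$end - e$ltr3_start, ltr3_start = e$end - e$ltr5_end,
         total = len)
  } else {
    list(ltr5_end = e$ltr5_end - e$start, ltr3_start = e$ltr3_start - e$start,
         total = len)
  }
}

#' Find the primer binding site of each element
#'
#' Scans the window starting at the 5' LTR end (element strand) for the
#' longest ungapped stretch matching the reverse complement of the
#' 3'-terminal `cfg$tRNA_tail_len` nucleotides of any tRNA, allowing up to
#' `cfg$pbs_max_mismatch` mismatches. The best hit (longest match, then
#' smallest offset from the LTR, then lexicographically smallest tRNA id)
#' is reported when it reaches `cfg$min_pbs_match`.
#'
#' @param elements Element tibble.
#' @param genome Genome tibble.
#' @param trnas tRNA tibble (`seq_id`, `residues`) or named character
#'   vector; each tRNA must be at least `cfg$tRNA_tail_len` long.
#' @param cfg An [ltr_config()].
#' @return PBS tibble (`element_id`, `start`, `end` element-local,
#'   `trna_id`, `match_len`, `offset_from_5ltr`), zero rows for elements
#'   without a qualifying hit.
#' @export
find_pbs <- function(elements, genome, trnas, cfg = ltr_config()) {
  if (is.data.frame(trnas)) trnas <- setNames(trnas$residues, trnas$seq_id)
  if (!length(trnas)) abort("find_pbs: empty tRNA set")
  short <- nchar(trnas) < cfg$tRNA_tail_len
  if (any(short)) {
    abort(sprintf("find_pbs: tRNA %s shorter than tail length %d",
                  names(trnas)[short][1], cfg$tRNA_tail_len))
  }
  tails <- substr(trnas, nchar(trnas) - cfg$tRNA_tail_len + 1, nchar(trnas))
  patterns <- vapply(tails, revcomp_chr, character(1))
  pat_order <- order(names(patterns))
  rows <- map(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    b <- local_ltr_bounds(e)
    internal <- element_internal_seq(e, genome)
    win_end <- min(b$ltr5_end + cfg$pbs_search_window, b$ltr3_start)
    if (win_end <= b$ltr5_end) return(NULL)
    window <- substr(internal, b$ltr5_end + 1, win_end)
    wch <- seq_chars(window)
    best <- NULL
    for (t in pat_order) {
      pch <- seq_chars(patterns[t])
      hit <- longest_mismatch_run(wch, pch, cfg$pbs_max_mismatch)
      if (is.null(hit) || hit$len < cfg$min_pbs_match) next
      if (is.null(best) || hit$len > best$len ||
          (hit$len == best$len && hit$offset < best$offset)) {
        best <- c(hit, list(trna_id = names(patterns)[t]))
      }
    }
    if (is.null(best)) return(NULL)
    tibble(element_id = e$element_id,
           start = b$ltr5_end + best$offset,
           end = b$ltr5_end + best$offset + best$len,
           trna_id = best$trna_id,
           match_len = as.integer(best$len),
           offset_from_5ltr = as.integer(best$offset))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_pbs())
  list_rbind(rows)
}

# longest ungapped run between window chars w and pattern chars p with at
# most k mismatches; earliest window offset wins ties
longest_mismatch_run <- function(w, p, k) {
  best <- NULL
  nw <- length(w); np <- length(p)
  for (i in seq_len(nw)) {          # window start
    for (j in seq_len(np)) {        # pattern start
      mism <- 0L; len <- 0L
      while (i + len <= nw && j + len <= np) {
        a <- w[i + len]; b <- p[j + len]
        if (a != b || a == "N") {
          mism <- mism + 1L
          if (mism > k) break
        }
        len <- len + 1L
      }
      if (len > 0 && (is.null(best) || len > best$len ||
                      (len == best$len && (i - 1L) < best$offset))) {
        best <- list(len = len, offset = i - 1L)
      }
    }
  }
  best
}

#' Find the polypurine tract of each element
#'
#' Scans the window upstream of the 3' LTR (element strand) for the best
#' purine tract: candidate windows must be at least `cfg$ppt_min_len` long,
#' have purine (A/G) fraction at least `cfg$ppt_min_purine`, and start and
#' end on a purine (the canonical trimmed form). The window with the most
#' purines wins; ties go to the rightmost (closest to the 3' LTR), then the
#' longer window.
#'
#' @inheritParams find_pbs
#' @return PPT tibble (`element_id`, `start`, `end` element-local,
#'   `purine_fraction`, `offset_from_3ltr`).
#' @export
find_ppt <- function(elements, genome, cfg = ltr_config()) {
  rows <- map(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    b <- local_ltr_bounds(e)
    internal <- element_internal_seq(e, genome)
    win_start <- max(b$ltr3_start - cfg$ppt_search_window, b$ltr5_end)
    if (b$ltr3_start <= win_start) return(NULL)
    window <- substr(internal, win_start + 1, b$ltr3_start)
    wch <- seq_chars(window)
    pur <- wch %in% PURINES
    n <- length(wch)
    best <- NULL
    for (s in seq_len(n)) {
      if (!pur[s]) next
      run_pur <- 0L
      for (t in s:n) {
        if (pur[t]) run_pur <- run_pur + 1L
        len <- t - s + 1L
        if (!pur[t] || len < cfg$ppt_min_len) next
        frac <- run_pur / len
        if (frac < cfg$ppt_min_purine) next
        if (is.null(best) || run_pur > best$np ||
            (run_pur == best$np && t > best$t) ||
            (run_pur == best$np && t == best$t && len > best$len)) {
          best <- list(np = run_pur, s = s, t = t, len = len, frac = frac)
        }
      }
    }
    if (is.null(best)) return(NULL)
    tibble(element_id = e$element_id,
           start = win_start + best$s - 1L,
           end = win_start + best$t,
           purine_fraction = best$frac,
           offset_from_3ltr = as.integer(b$ltr3_start - (win_start + best$t)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_ppt())
  list_rbind(rows)
}

#' Annotate PBS and PPT for a set of elements
#'
#' @inheritParams find_pbs
#' @return A list with tibbles `pbs` and `ppt`.
#' @export
annotate_features <- function(elements, genome, trnas, cfg = ltr_config()) {
  list(pbs = find_pbs(elements, genome, trnas, cfg),
       ppt = find_ppt(elements, genome, cfg))
}
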