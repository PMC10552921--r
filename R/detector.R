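# Structural detection of intact LTR-RT candidates. Candidates are seeded
# by exact forward repeats of length >= M whose separation (distance
# between the putative 5' and 3' LTR starts) lies in [d, D], extended along
# their diagonal with X-drop scoring, polished at the boundaries using the
# target-site duplication and the TG...CA terminal motif, and accepted only
# when the LTR pair passes the length bounds and the global-alignment
# similarity threshold S. LTR copies are assumed to diverge by
# substitution, so extension never needs to leave the seed diagonal; the
# final similarity is still computed by full affine-gap alignment.

BASE_CODE <- local({
  x <- rep(NA_integer_, 128)
  x[utf8ToInt("A")] <- 0L; x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L; x[utf8ToInt("T")] <- 3L
  x
})

#' Find exact-repeat seed pairs
#'
#' Scans one genome sequence for maximal exact forward repeats of length at
#' least `cfg$M` whose separation lies in `[cfg$d, cfg$D]`. Windows
#' containing `N` never seed. Seeds wholly contained in a longer seed on
#' the same diagonal are suppressed.
#'
#' @param genome Genome tibble (one or more sequences).
#' @param cfg An [ltr_config()].
#' @return A tibble `seq_id`, `pos_a`, `pos_b` (0-based starts,
#'   `pos_a < pos_b`), `seed_len`.
#' @export
find_seed_pairs <- function(genome, cfg = ltr_config()) {
  out <- map(seq_len(nrow(genome)), function(i) {
    find_seed_pairs_one(genome$seq_id[i], genome$residues[i], cfg)
  })
  list_rbind(c(list(empty_seeds()), out))
}

empty_seeds <- function() {
  tibble(seq_id = character(), pos_a = integer(), pos_b = integer(),
         seed_len = integer())
}

find_seed_pairs_one <- function(seq_id, s, cfg) {
  M <- cfg$M
  n <- nchar(s)
  if (n < M) return(empty_seeds())
  b <- as.numeric(BASE_CODE[utf8ToInt(s)])
  # exact 2-bit packing of each M-window into a double (M <= 26 keeps the
  # value under 2^53, collision-free)
  if (M > 26) abort("find_seed_pairs: M > 26 unsupported by the hash packing")
  h <- as.numeric(stats::filter(b, 4^(0:(M - 1)), sides = 1))
  h <- h[M:n]                       # h[k] = window starting at k-1 (0-based)
  pos <- which(!is.na(h))
  if (!length(pos)) return(empty_seeds())
  hv <- h[pos]
  ord <- order(hv, pos)
  hv <- hv[ord]; pv <- pos[ord]
  grp_new <- c(TRUE, hv[-1] != hv[-length(hv)])
  grp_id <- cumsum(grp_new)
  sizes <- tabulate(grp_id)
  multi <- which(sizes >= 2)
  if (!length(multi)) return(empty_seeds())
  pa <- integer(0); pb <- integer(0)
  idx_by_grp <- split(pv, grp_id)
  for (g in multi) {
    p <- idx_by_grp[[g]]            # ascending starts (1-based)
    for (a in seq_len(length(p) - 1)) {
      lo <- p[a] + cfg$d; hi <- p[a] + cfg$D
      sel <- p[(a + 1):length(p)]
      sel <- sel[sel >= lo & sel <= hi]
      if (length(sel)) {
        pa <- c(pa, rep(p[a], length(sel)))
        pb <- c(pb, sel)
      }
    }
  }
  if (!length(pa)) return(empty_seeds())
  seeds <- tibble(seq_id = seq_id, pos_a = pa - 1L, pos_b = pb - 1L)
  # merge runs of consecutive k-mer pairs on the same diagonal into maximal
  # exact matches
  seeds <- arrange(seeds, .data$pos_b - .data$pos_a, .data$pos_a)
  diag <- seeds$pos_b - seeds$pos_a
  new_run <- c(TRUE, diff(seeds$pos_a) != 1L | diff(diag) != 0L)
  run_id <- cumsum(new_run)
  seeds |>
    mutate(run = run_id) |>
    group_by(.data$run) |>
    summarise(seq_id = .data$seq_id[1],
              seed_len = max(.data$pos_a) - min(.data$pos_a) + cfg$M,
              pos_a = min(.data$pos_a), pos_b = min(.data$pos_b),
              .groups = "drop") |>
    select("seq_id", "pos_a", "pos_b", "seed_len") |>
    arrange(.data$pos_a, .data$pos_b)
}

# X-drop extension along a fixed diagonal: step scores cfg$match /
# cfg$mismatch (N always mismatches), stop once the score falls cfg$xdrop
# below its running maximum, return the arg-max extension length (0 when no
# positive-scoring extension exists)
xdrop_extend <- function(ca, cb, cfg) {
  m <- min(length(ca), length(cb))
  if (m == 0) return(0L)
  ca <- ca[1:m]; cb <- cb[1:m]
  step <- ifelse(ca == cb & ca != "N" & cb != "N", cfg$match, cfg$mismatch)
  cums <- cumsum(step)
  runmax <- cummax(cums)
  cut <- which(runmax - cums > cfg$xdrop)[1]
  upto <- if (is.na(cut)) m else cut - 1L
  if (upto < 1) return(0L)
  best <- which.max(cums[1:upto])
  if (cums[best] > 0) best else 0L
}

#' Extend seed pairs into LTR-pair candidates
#'
#' Seeds sharing a diagonal are pooled per putative element, extended
#' outwards with X-drop scoring, and turned into candidate elements. A
#' candidate is rejected (with a reason code) when the putative LTR length
#' falls outside `[cfg$l, cfg$L]` (`"ltr_length"`) or when the
#' global-alignment identity of the LTR pair is below `cfg$S`
#' (`"similarity"`).
#'
#' @param seeds Seed tibble from [find_seed_pairs()].
#' @param genome Genome tibble.
#' @param cfg An [ltr_config()].
#' @return A list with `candidates` (tibble `seq_id`, `start`, `end`,
#'   `diag`, `ltr_len`, `ltr_similarity`) and `rejected` (tibble with
#'   `reason`).
#' @export
extend_and_align <- function(seeds, genome, cfg = ltr_config()) {
  cands <- list(); rejects <- list()
  for (sid in unique(seeds$seq_id)) {
    s <- genome$residues[match(sid, genome$seq_id)]
    n <- nchar(s)
    ch <- seq_chars(s)
    sd <- arrange(seeds[seeds$seq_id == sid, ],
                  .data$pos_b - .data$pos_a, .data$pos_a)
    diag <- sd$pos_b - sd$pos_a
    # pool seeds on a diagonal separated by less than the max LTR length
    new_cl <- c(TRUE, diff(diag) != 0L |
                  (sd$pos_a[-1] - (sd$pos_a + sd$seed_len)[-nrow(sd)]) > cfg$L)
    cl <- cumsum(new_cl)
    for (k in unique(cl)) {
      part <- sd[cl == k, ]
      dg <- part$pos_b[1] - part$pos_a[1]
      a0 <- min(part$pos_a); a1 <- max(part$pos_a + part$seed_len)
      b0 <- a0 + dg
      # leftward extension (compare positions a0-i vs b0-i)
      max_left <- min(a0, b0 - a1, cfg$L)   # never cross into the other LTR
      extL <- if (max_left > 0) {
        ia <- a0 - seq_len(max_left); ib <- b0 - seq_len(max_left)
        xdrop_extend(ch[ia + 1L], ch[ib + 1L], cfg)
      } else 0L
      # rightward extension from the seed-cover end
      b1 <- a1 + dg
      max_right <- min(n - b1, b0 - a1, cfg$L)
      extR <- if (max_right > 0) {
        ia <- a1 + seq_len(max_right) - 1L; ib <- b1 + seq_len(max_right) - 1L
        xdrop_extend(ch[ia + 1L], ch[ib + 1L], cfg)
      } else 0L
      ltr_start <- a0 - extL
      ltr_len <- (a1 + extR) - ltr_start
      cand <- tibble(seq_id = sid, start = ltr_start,
                     end = ltr_start + dg + ltr_len,
                     diag = dg, ltr_len = ltr_len,
                     ltr_similarity = NA_real_)
      if (ltr_len < cfg$l || ltr_len > cfg$L || ltr_len > dg) {
        rejects[[length(rejects) + 1]] <- mutate(cand, reason = "ltr_length")
        next
      }
      ident <- alignment_identity(
        substr(s, ltr_start + 1, ltr_start + ltr_len),
        substr(s, ltr_start + dg + 1, ltr_start + dg + ltr_len),
        cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend)
      cand$ltr_similarity <- ident
      if (ident < cfg$S) {
        rejects[[length(rejects) + 1]] <- mutate(cand, reason = "similarity")
      } else {
        cands[[length(cands) + 1]] <- cand
      }
    }
  }
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  diag = integer(), ltr_len = integer(),
                  ltr_similarity = double())
  list(candidates = list_rbind(c(list(empty), cands)),
       rejected = list_rbind(c(list(mutate(empty, reason = character())),
                               rejects)))
}

# interleaved offsets 0, 1, -1, 2, -2, ...
wiggle_offsets <- function(w) {
  if (w == 0) return(0L)
  c(0L, as.integer(rbind(seq_len(w), -seq_len(w))))
}

#' Structural filtering: TSD and terminal motif
#'
#' Accepts candidates flanked by identical direct repeats of length
#' `[cfg$tsd_min, cfg$tsd_max]` (the target site duplication) immediately
#' outside both LTRs, and, unless `cfg$motif_check` is off, starting with
#' `TG` and ending with `CA`. Boundaries are polished within
#' `cfg$boundary_wiggle` bp: the closest boundary pair satisfying motif and
#' TSD wins (longest TSD first). Rejections carry reason `"motif"`,
#' `"tsd"`, `"ltr_length"` or `"similarity"`.
#'
#' @param candidates Candidate tibble from [extend_and_align()].
#' @param genome Genome tibble.
#' @param cfg An [ltr_config()].
#' @return A list with `elements` (validated element tibble, ids unset) and
#'   `rejected`.
#' @export
structural_filter <- function(candidates, genome, cfg = ltr_config()) {
  kept <- list(); rejects <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    s <- genome$residues[match(cand$seq_id, genome$seq_id)]
    n <- nchar(s)
    dg <- cand$diag
    offs <- wiggle_offsets(cfg$boundary_wiggle)
    start_ok <- cand$start + offs
    start_ok <- start_ok[start_ok - cfg$tsd_max >= 0 & start_ok < n]
    end_ok <- cand$end + offs
    end_ok <- end_ok[end_ok + cfg$tsd_max <= n & end_ok > 0]
    # search boundary pairs for a TSD (closest shift first, longest TSD)
    # that also carries the terminal motif when the motif check is on
    found <- NULL
    for (st in start_ok) {
      for (en in end_ok) {
        len <- (en - st) - dg
        if (len < cfg$l || len > cfg$L || len > dg) next
        for (ts in seq(cfg$tsd_max, cfg$tsd_min)) {
          left <- substr(s, st - ts + 1, st)
          if (grepl("N", left, fixed = TRUE)) next
          if (left != substr(s, en + 1, en + ts)) next
          if (cfg$motif_check &&
              (substr(s, st + 1, st + 2) != "TG" ||
               substr(s, en - 1, en) != "CA")) next
          found <- list(start = st, end = en, len = len, tsd = left)
          break
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      # attribute the failure at the candidate's own boundaries (within a
      # few bp, covering extension overshoot): a missing terminal motif
      # there is a motif rejection, anything else a TSD one
      near <- -3:3
      st_near <- cand$start + near; en_near <- cand$end + near
      st_near <- st_near[st_near >= 0 & st_near + 2 <= n]
      en_near <- en_near[en_near - 2 >= 0 & en_near <= n]
      motif_bad <- cfg$motif_check &&
        (!any(substring(s, st_near + 1, st_near + 2) == "TG") ||
           !any(substring(s, en_near - 1, en_near) == "CA"))
      rejects[[length(rejects) + 1]] <-
        mutate(cand, reason = if (motif_bad) "motif" else "tsd")
      next
    }
    ltr5 <- substr(s, found$start + 1, found$start + found$len)
    ltr3 <- substr(s, found$start + dg + 1, found$start + dg + found$len)
    ident <- alignment_identity(ltr5, ltr3, cfg$match, cfg$mismatch,
                                cfg$gap_open, cfg$gap_extend)
    if (ident < cfg$S) {
      rejects[[length(rejects) + 1]] <- mutate(cand, reason = "similarity")
      next
    }
    motif <- paste0(substr(ltr5, 1, 2),
                    substr(ltr3, found$len - 1, found$len))
    kept[[length(kept) + 1]] <- tibble(
      element_id = NA_character_, seq_id = cand$seq_id,
      start = as.integer(found$start), end = as.integer(found$end),
      strand = "+",
      ltr5_start = as.integer(found$start),
      ltr5_end = as.integer(found$start + found$len),
      ltr3_start = as.integer(found$start + dg),
      ltr3_end = as.integer(found$end),
      tsd_left = found$tsd, tsd_right = found$tsd,
      terminal_motif = motif, ltr_similarity = ident
    )
  }
  empty_rej <- tibble(seq_id = character(), start = integer(),
                      end = integer(), diag = integer(),
                      ltr_len = integer(), ltr_similarity = double(),
                      reason = character())
  list(elements = list_rbind(c(list(empty_elements()), kept)),
       rejected = list_rbind(c(list(empty_rej), rejects)))
}

# keep the best of overlapping element spans: higher similarity, then
# longer, then leftmost
resolve_overlaps <- function(elements) {
  if (nrow(elements) < 2) return(elements)
  out <- list()
  for (sid in unique(elements$seq_id)) {
    e <- elements[elements$seq_id == sid, ]
    e <- e[order(-e$ltr_similarity, -(e$end - e$start), e$start), ]
    taken_s <- integer(0); taken_e <- integer(0)
    keep <- logical(nrow(e))
    for (i in seq_len(nrow(e))) {
      if (!any(e$start[i] < taken_e & e$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, e$start[i]); taken_e <- c(taken_e, e$end[i])
      }
    }
    out[[sid]] <- e[keep, ]
  }
  arrange(list_rbind(out), .data$seq_id, .data$start)
}

#' Detect intact LTR-RT elements in a genome
#'
#' Full structural detection: [find_seed_pairs()], [extend_and_align()],
#' [structural_filter()], overlap resolution (best similarity, then longer,
#' then leftmost), and stable element-id assignment in `(seq_id, start)`
#' order.
#'
#' @param genome Genome tibble from [read_fasta()].
#' @param cfg An [ltr_config()].
#' @return A validated element tibble.
#' @export
detect_elements <- function(genome, cfg = ltr_config()) {
  seeds <- find_seed_pairs(genome, cfg)
  if (nrow(seeds) == 0) return(empty_elements())
  ext <- extend_and_align(seeds, genome, cfg)
  filt <- structural_filter(ext$candidates, genome, cfg)
  el <- resolve_overlaps(filt$elements)
  # duplicate structures can survive as identical rows; keep the first
  el <- el[!duplicated(el[, c("seq_id", "start", "end")]), ]
  el$element_id <- sprintf("LTRRT_%05d", seq_len(nrow(el)))
  validate_elements(el)
}
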