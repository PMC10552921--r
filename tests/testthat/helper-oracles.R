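# Independent oracles used across the suite. These deliberately take the
# slowest, most literal route (exhaustive enumeration, per-base loops,
# closed forms written out) so they share no code path with the package.

# exhaustive global alignment score by recursion over all alignments,
# affine gaps (open/extend as positive penalties), N never matches
oracle_nw_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  # state: 0 = no open gap, 1 = gap open in a-row, 2 = gap open in b-row
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(ca)) { # ca[i] against a gap
      cost <- if (state == 1) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(cb)) {
      cost <- if (state == 2) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# literal per-column divergence classifier
oracle_divergence <- function(aligned_a, aligned_b) {
  ca <- strsplit(toupper(aligned_a), "")[[1]]
  cb <- strsplit(toupper(aligned_b), "")[[1]]
  sites <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% c("A", "C", "G", "T"))) next
    if (!(y %in% c("A", "C", "G", "T"))) next
    sites <- sites + 1L
    if (x == y) next
    pair <- paste(sort(c(x, y)), collapse = "")
    if (pair == "AG" || pair == "CT") ts <- ts + 1L else tv <- tv + 1L
  }
  list(aligned_sites = sites, transitions = ts, transversions = tv)
}

# closed-form K2P on counts, written independently
oracle_k2p_K <- function(sites, ts, tv) {
  P <- ts / sites; Q <- tv / sites
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

# Jukes-Cantor closed form on the pooled substitution proportion
oracle_jc_K <- function(sites, ts, tv) {
  p <- (ts + tv) / sites
  -3 / 4 * log(1 - 4 * p / 3)
}

# per-base confusion-count loop
oracle_confusion <- function(truth, pred, seq_lengths) {
  tp <- fp <- fn <- tn <- 0L
  for (sid in names(seq_lengths)) {
    len <- seq_lengths[[sid]]
    in_t <- logical(len); in_p <- logical(len)
    t <- truth[truth$seq_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(t))) {
      if (t$end[i] > t$start[i]) in_t[(t$start[i] + 1):t$end[i]] <- TRUE
    }
    p <- pred[pred$seq_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      if (p$end[i] > p$start[i]) in_p[(p$start[i] + 1):p$end[i]] <- TRUE
    }
    tp <- tp + sum(in_t & in_p); fp <- fp + sum(!in_t & in_p)
    fn <- fn + sum(in_t & !in_p); tn <- tn + sum(!in_t & !in_p)
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# brute-force all-pairs gene relation scan
oracle_relations <- function(elements, genes, U, X) {
  out <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    found <- FALSE
    g_all <- genes[genes$seq_id == e$seq_id, , drop = FALSE]
    g_all <- g_all[order(g_all$start, g_all$end), , drop = FALSE]
    for (j in seq_len(nrow(g_all))) {
      g <- g_all[j, ]
      rel <- NULL; dist <- 0L
      if (g$start <= e$start && g$end >= e$end) rel <- "WITHIN_GENE"
      else if (e$start <= g$start && e$end >= g$end) rel <- "CONTAINS_GENE"
      else if (g$start < e$end && g$end > e$start) rel <- "PARTIAL_OVERLAP"
      else if (g$end <= e$start) {
        dist <- e$start - g$end
        if (dist <= U) rel <- "NEAR_UPSTREAM"
      } else {
        dist <- g$start - e$end
        if (dist <= X) rel <- "NEAR_DOWNSTREAM"
      }
      if (!is.null(rel)) {
        out[[length(out) + 1]] <- data.frame(
          element_id = e$element_id, gene_id = g$gene_id, relation = rel,
          distance_bp = as.integer(dist), stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found) {
      out[[length(out) + 1]] <- data.frame(
        element_id = e$element_id, gene_id = NA_character_,
        relation = "INTERGENIC", distance_bp = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# type-7 quantile written out: h = (n-1) p + 1
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# random interval fixture on a small genome
random_interval_set <- function(n, len) {
  if (n == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer()))
  }
  start <- sample.int(len - 1L, n, replace = TRUE) - 1L
  width <- sample.int(max(1L, len %/% 5L), n, replace = TRUE)
  data.frame(seq_id = "s1", start = start,
             end = pmin(start + width, len))
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
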