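# Summary statistics and density tracks: five-number boxplot summaries
# (type-7 quantiles, Tukey 1.5*IQR whiskers clamped to the data) for
# element length and insertion age, plus windowed gene/element density
# tracks for ideogram-style plots.

#' Boxplot summary of a numeric vector
#'
#' Quartiles use linear interpolation (quantile type 7); whiskers extend to
#' the most extreme data point within 1.5 IQR of the quartiles; points
#' beyond the whiskers are outliers.
#'
#' @param values Numeric vector, `n >= 1`, NAs dropped.
#' @return A one-row tibble `n`, `min`, `q1`, `median`, `q3`, `max`, `iqr`,
#'   `lower_whisker`, `upper_whisker` and a list-column `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("boxplot_summary: no values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble(
    n = length(values), min = min(values), q1 = q[1], median = q[2],
    q3 = q[3], max = max(values), iqr = iqr,
    lower_whisker = min(values[inside]),
    upper_whisker = max(values[inside]),
    outliers = list(sort(values[!inside]))
  )
}

#' Windowed gene / element density tracks
#'
#' Tiles every sequence with windows of `W` bp (the last window may be
#' short) and counts features per window. In `"overlap"` mode (default) a
#' feature is counted in every window it overlaps by at least one base; in
#' `"midpoint"` mode only in the window holding its midpoint, so window
#' counts sum exactly to the feature count.
#'
#' @param genes,elements Tibbles with `seq_id`, `start`, `end`.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param W Window size (bp, >= 1000).
#' @param mode `"overlap"` or `"midpoint"`.
#' @return A tibble `seq_id`, `window_start`, `window_end`, `gene_count`,
#'   `element_count`.
#' @export
density_track <- function(genes, elements, seq_lengths, W = 100000,
                          mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  if (W < 1000) abort("density_track: W must be >= 1000")
  count_one <- function(tbl, sid, n_win, len) {
    cnt <- integer(n_win)
    t <- tbl[tbl$seq_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(t))) {
      if (mode == "overlap") {
        w0 <- t$start[i] %/% W
        w1 <- (t$end[i] - 1L) %/% W
      } else {
        w0 <- w1 <- ((t$start[i] + t$end[i] - 1L) %/% 2L) %/% W
      }
      w0 <- max(w0, 0L); w1 <- min(w1, n_win - 1L)
      if (w0 <= w1) cnt[(w0 + 1):(w1 + 1)] <- cnt[(w0 + 1):(w1 + 1)] + 1L
    }
    cnt
  }
  rows <- imap(as.list(seq_lengths), function(len, sid) {
    n_win <- max(1L, as.integer(ceiling(len / W)))
    ws <- (seq_len(n_win) - 1L) * W
    tibble(seq_id = sid, window_start = ws,
           window_end = pmin(ws + W, as.integer(len)),
           gene_count = count_one(genes, sid, n_win, len),
           element_count = count_one(elements, sid, n_win, len))
  })
  list_rbind(rows)
}

#' Ideogram data: density tracks of the longest sequences
#'
#' Selects the `N` longest sequences and returns their density windows in
#' long format; this is the exact table behind [plot_density_ideogram()],
#' written alongside any rendering so results remain verifiable without
#' image comparison.
#'
#' @param track A tibble from [density_track()].
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param N Number of sequences to keep (longest first); must not exceed
#'   the number of sequences.
#' @return The filtered track in long format (`seq_id`, `window_start`,
#'   `window_end`, `feature`, `count`).
#' @export
ideogram_data <- function(track, seq_lengths, N) {
  if (N > length(seq_lengths)) {
    abort("ideogram_data: N exceeds the number of sequences")
  }
  keep <- names(sort(seq_lengths, decreasing = TRUE))[seq_len(N)]
  track |>
    filter(.data$seq_id %in% keep) |>
    tidyr::pivot_longer(c("gene_count", "element_count"),
                        names_to = "feature", values_to = "count") |>
    mutate(feature = sub("_count$", "", .data$feature))
}

#' Plot a density ideogram
#'
#' Heat-strip ideogram of gene and element density per window, one facet
#' row per sequence.
#'
#' @param track A tibble from [density_track()].
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param N Number of sequences (longest first) to render.
#' @return A ggplot object.
#' @export
plot_density_ideogram <- function(track, seq_lengths, N = length(seq_lengths)) {
  d <- ideogram_data(track, seq_lengths, N)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$window_start + .data$window_end) / 2e6,
                                  y = .data$feature, fill = .data$count)) +
    ggplot2::geom_tile(ggplot2::aes(width = (.data$window_end - .data$window_start) / 1e6)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$seq_id)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "count") +
    ggplot2::theme_minimal()
}

#' Boxplot of element lengths
#'
#' @param elements Element tibble.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(elements) {
  d <- tibble(length = elements$end - elements$start)
  ggplot2::ggplot(d, ggplot2::aes(x = "LTR-RT", y = .data$length)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "element length (bp)") +
    ggplot2::theme_minimal()
}

#' Boxplot of insertion ages
#'
#' Saturated elements (undefined K) are dropped.
#'
#' @param ages Age tibble from [estimate_ages()].
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(ages) {
  d <- ages[ages$flag == "ok" & !is.na(ages$T_mya), ]
  ggplot2::ggplot(d, ggplot2::aes(x = "LTR-RT", y = .data$T_mya)) +
    ggplot2::geom_boxplot(fill = "darkorange", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "insertion age (Mya)") +
    ggplot2::theme_minimal()
}
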