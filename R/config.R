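#' Pipeline configuration
#'
#' Collects every tunable threshold used across the toolkit. All coordinates
#' and lengths are base pairs; similarity and identity values are fractions
#' in (0, 1]. The defaults mirror a typical intact-element run on a plant
#' genome: LTR length in \[100, 7000\] bp, LTR starts separated by
#' \[1000, 15000\] bp, LTR pair similarity at least 0.85, exact-match seed
#' length 20 bp.
#'
#' @param l,L Minimum / maximum LTR length (bp).
#' @param d,D Minimum / maximum distance between the 5' and 3' LTR start
#'   positions (bp).
#' @param S Similarity threshold, fraction in (0, 1]. Used both for the LTR
#'   pair identity filter and, by default, for library clustering.
#' @param M Minimum length of an exact match seed pair (bp, >= 10).
#' @param U,X Distances upstream / downstream of an element within which a
#'   gene counts as "near" (bp).
#' @param W Density window size for ideogram tracks (bp).
#' @param R Neutral substitution rate in substitutions/site/year, used for
#'   insertion-age estimation (T = K / 2R). No default: rates differ
#'   strongly between species, so the user must supply one.
#' @param N Number of sequences (longest first) rendered on the ideogram.
#' @param threads Worker count for per-sequence parallelism.
#' @param tsd_min,tsd_max Accepted target-site-duplication lengths (bp).
#' @param motif_check Require the TG...CA terminal motif (logical).
#' @param trim_max_len Maximum total element length for the TRIM class (bp).
#' @param lard_min_internal Minimum internal-region length for LARD (bp).
#' @param tRNA_tail_len Length of the tRNA 3' tail matched by the PBS (nt).
#' @param pbs_search_window,ppt_search_window Search window downstream of the
#'   5' LTR (PBS) and upstream of the 3' LTR (PPT), bp.
#' @param min_pbs_match Minimum PBS match length (nt).
#' @param pbs_max_mismatch Mismatches tolerated in the PBS match.
#' @param ppt_min_len Minimum PPT length (bp).
#' @param ppt_min_purine Minimum purine fraction of a PPT window.
#' @param autonomy_requires_pbs_ppt If `TRUE` (default) an element is only
#'   called autonomous when PBS and PPT are both present in addition to the
#'   full canonical domain order; `FALSE` relaxes the call to domains only.
#' @param chimera_policy `"overlap"` (any gene overlap is a chimera) or
#'   `"within"` (only elements fully inside a gene).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring. `gap_open`
#'   and `gap_extend` are positive penalties.
#' @param xdrop Score drop-off terminating seed extension.
#' @param boundary_wiggle Half-width (bp) of the TSD/motif boundary search
#'   during structural filtering.
#' @param passthrough Named list of flags accepted for compatibility but not
#'   interpreted (e.g. external domain-scanner settings).
#'
#' @return A list of class `ltr_config`.
#' @export
ltr_config <- function(l = 100, L = 7000, d = 1000, D = 15000, S = 0.85,
                       M = 20, U = 500, X = 500, W = 100000, R = NULL,
                       N = 10, threads = 1,
                       tsd_min = 4, tsd_max = 6, motif_check = TRUE,
                       trim_max_len = 1000, lard_min_internal = 3500,
                       tRNA_tail_len = 18,
                       pbs_search_window = 30, ppt_search_window = 50,
                       min_pbs_match = 12, pbs_max_mismatch = 1,
                       ppt_min_len = 10, ppt_min_purine = 0.8,
                       autonomy_requires_pbs_ppt = TRUE,
                       chimera_policy = c("overlap", "within"),
                       match = 2, mismatch = -3, gap_open = 5,
                       gap_extend = 2, xdrop = 20, boundary_wiggle = 20,
                       passthrough = list()) {
  cfg <- list(
    l = as.integer(l), L = as.integer(L), d = as.integer(d),
    D = as.integer(D), S = S, M = as.integer(M), U = as.integer(U),
    X = as.integer(X), W = as.integer(W), R = R, N = as.integer(N),
    threads = as.integer(threads), tsd_min = as.integer(tsd_min),
    tsd_max = as.integer(tsd_max), motif_check = isTRUE(motif_check),
    trim_max_len = as.integer(trim_max_len),
    lard_min_internal = as.integer(lard_min_internal),
    tRNA_tail_len = as.integer(tRNA_tail_len),
    pbs_search_window = as.integer(pbs_search_window),
    ppt_search_window = as.integer(ppt_search_window),
    min_pbs_match = as.integer(min_pbs_match),
    pbs_max_mismatch = as.integer(pbs_max_mismatch),
    ppt_min_len = as.integer(ppt_min_len),
    ppt_min_purine = ppt_min_purine,
    autonomy_requires_pbs_ppt = isTRUE(autonomy_requires_pbs_ppt),
    chimera_policy = match.arg(chimera_policy),
    match = match, mismatch = mismatch, gap_open = gap_open,
    gap_extend = gap_extend, xdrop = xdrop,
    boundary_wiggle = as.integer(boundary_wiggle),
    passthrough = passthrough
  )
  if (cfg$l > cfg$L) abort("ltr_config: l must be <= L")
  if (cfg$d > cfg$D) abort("ltr_config: d must be <= D")
  if (!(cfg$S > 0 && cfg$S <= 1)) abort("ltr_config: S must lie in (0, 1]")
  if (cfg$M < 10) abort("ltr_config: M must be >= 10")
  if (cfg$ppt_min_len < 8) abort("ltr_config: ppt_min_len must be >= 8")
  bp <- c("l", "L", "d", "D", "U", "X", "W", "tsd_min", "tsd_max",
          "trim_max_len", "lard_min_internal", "tRNA_tail_len",
          "pbs_search_window", "ppt_search_window", "min_pbs_match",
          "ppt_min_len")
  bad <- bp[vapply(cfg[bp], function(x) x < 0L, logical(1))]
  if (length(bad)) abort(paste0("ltr_config: negative value for ", bad[1]))
  if (!is.null(cfg$R) && cfg$R <= 0) abort("ltr_config: R must be positive")
  structure(cfg, class = "ltr_config")
}

#' @export
print.ltr_config <- function(x, ...) {
  cat("<ltr_config>\n")
  keys <- setdiff(names(x), "passthrough")
  for (k in keys) {
    v <- x[[k]]
    cat(sprintf("  %-26s %s\n", k, if (is.null(v)) "<unset>" else format(v)))
  }
  if (length(x$passthrough)) {
    cat("  passthrough:", paste(names(x$passthrough), collapse = " "), "\n")
  }
  invisible(x)
}
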