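# Coordinate conventions: every interval stored by the package is 0-based
# half-open [start, end); GFF3 output is 1-based inclusive. Strand is one of
# "+", "-", ".".

#' Convert internal intervals to GFF coordinates
#'
#' Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive.
#' `from_gff_coords()` is the exact inverse.
#'
#' @param start,end Integer vectors, 0-based half-open (`0 <= start < end`).
#' @return A tibble with columns `start` and `end` in the target convention.
#' @export
#' @examples
#' to_gff_coords(0, 10)    # 1..10
#' from_gff_coords(1, 10)  # back to [0, 10)
to_gff_coords <- function(start, end) {
  check_interval(start, end)
  tibble(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname to_gff_coords
#' @export
from_gff_coords <- function(start, end) {
  if (any(start < 1L) || any(end < start)) {
    abort("from_gff_coords: need 1 <= start <= end")
  }
  tibble(start = as.integer(start) - 1L, end = as.integer(end))
}

check_interval <- function(start, end, what = "interval") {
  if (any(start < 0L)) abort(paste0(what, ": start must be >= 0"))
  if (any(end <= start)) abort(paste0(what, ": need start < end"))
  invisible(TRUE)
}

#' Internal region of an element
#'
#' The region between the end of the 5' LTR and the start of the 3' LTR, in
#' genome coordinates, 0-based half-open. A zero-length internal region
#' (adjacent LTRs) is returned with `empty = TRUE`; overlapping LTRs are an
#' error.
#'
#' @param elements An element tibble (see [validate_elements()]).
#' @return A tibble with `element_id`, `start`, `end`, `length`, `empty`.
#' @export
internal_region <- function(elements) {
  bad <- elements$ltr5_end > elements$ltr3_start
  if (any(bad)) {
    abort(paste0("internal_region: 5' and 3' LTRs overlap for element ",
                 elements$element_id[which(bad)[1]]))
  }
  tibble(
    element_id = elements$element_id,
    start = elements$ltr5_end,
    end = elements$ltr3_start,
    length = elements$ltr3_start - elements$ltr5_end,
    empty = elements$ltr3_start == elements$ltr5_end
  )
}

empty_elements <- function() {
  tibble(
    element_id = character(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    tsd_left = character(), tsd_right = character(),
    terminal_motif = character(), ltr_similarity = double()
  )
}

#' Validate an element table
#'
#' Checks the structural invariants of intact-element records: the element
#' span starts at the 5' LTR and ends at the 3' LTR, the 5' LTR precedes the
#' 3' LTR with a non-negative internal gap, TSD strings (when both present)
#' have equal length, and the terminal motif has four characters. Malformed
#' rows raise an error naming the violated rule and the offending element.
#'
#' @param elements A tibble with the element columns (`element_id`, `seq_id`,
#'   `start`, `end`, `strand`, `ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end`, `tsd_left`, `tsd_right`, `terminal_motif`,
#'   `ltr_similarity`).
#' @return The validated tibble, invisibly classed for printing.
#' @export
validate_elements <- function(elements) {
  elements <- as_tibble(elements)
  need <- names(empty_elements())
  missing_cols <- setdiff(need, names(elements))
  if (length(missing_cols)) {
    abort(paste0("elements: missing column(s) ", paste(missing_cols, collapse = ", ")))
  }
  fail <- function(rule, i) {
    abort(sprintf("elements: rule '%s' violated by element %s",
                  rule, elements$element_id[i]))
  }
  if (anyDuplicated(elements$element_id)) {
    abort("elements: duplicate element_id")
  }
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    if (!(e$start >= 0 && e$start < e$end)) fail("span_valid", i)
    if (e$ltr5_start != e$start) fail("ltr5_starts_span", i)
    if (e$ltr3_end != e$end) fail("ltr3_ends_span", i)
    if (!(e$ltr5_start < e$ltr5_end)) fail("ltr5_valid", i)
    if (!(e$ltr3_start < e$ltr3_end)) fail("ltr3_valid", i)
    if (e$ltr5_end > e$ltr3_start) fail("ltr_order", i)
    if (!is.na(e$tsd_left) && !is.na(e$tsd_right) &&
        nzchar(e$tsd_left) && nzchar(e$tsd_right) &&
        nchar(e$tsd_left) != nchar(e$tsd_right)) fail("tsd_equal_length", i)
    if (!is.na(e$terminal_motif) && nchar(e$terminal_motif) != 4) {
      fail("terminal_motif_4char", i)
    }
    if (!is.na(e$ltr_similarity) &&
        (e$ltr_similarity < 0 || e$ltr_similarity > 1)) fail("similarity_range", i)
  }
  elements
}
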