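# Element library construction: extract every element's genomic sequence
# into a redundant FASTA, then collapse it to a non-redundant library with
# a greedy length-sorted centroid clusterer (UCLUST-like semantics, but
# with exact global alignments: exactness over speed at desk scale).

#' Build the redundant element library
#'
#' One record per element: the plus-strand genomic span (reverse
#' complemented for minus-strand elements), with the library header
#' dialect `element_id#classification seq_id:start-end(strand)`.
#'
#' @param elements Element tibble.
#' @param genome Genome tibble.
#' @param classifications Optional classification tibble (headers fall back
#'   to `LTR/unknown/unknown`).
#' @return A tibble `element_id`, `header`, `residues`, `length`. Empty
#'   input yields an empty tibble with a warning.
#' @export
build_redundant_library <- function(elements, genome,
                                    classifications = NULL) {
  if (nrow(elements) == 0) {
    warn("build_redundant_library: no elements; empty library")
    return(tibble(element_id = character(), header = character(),
                  residues = character(), length = integer()))
  }
  cls <- rep("LTR/unknown/unknown", nrow(elements))
  if (!is.null(classifications) && nrow(classifications)) {
    m <- match(elements$element_id, classifications$element_id)
    has <- !is.na(m)
    cls[has] <- classification_string(classifications$category[m[has]],
                                      classifications$superfamily[m[has]],
                                      classifications$clade[m[has]])
  }
  seqs <- vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    genome_subseq(genome, e$seq_id, e$start, e$end, e$strand)
  }, character(1))
  tibble(
    element_id = elements$element_id,
    header = format_library_header(elements$element_id, cls,
                                   elements$seq_id, elements$start,
                                   elements$end, elements$strand),
    residues = seqs,
    length = nchar(seqs)
  )
}

#' Greedy centroid clustering of a sequence library
#'
#' Sequences are processed longest first (ties keep input order). Each
#' sequence is compared against existing centroids in discovery order and
#' joins the first one whose global-alignment identity (matches / columns,
#' gaps counted) reaches `S`; otherwise it founds a new cluster. A
#' length-ratio screen (`shorter/longer < S` implies identity `< S`) skips
#' hopeless alignments without changing the result.
#'
#' @param library A library tibble from [build_redundant_library()] (or any
#'   tibble with `element_id`, `residues`).
#' @param S Identity threshold in (0, 1].
#' @param cfg An [ltr_config()] (alignment scoring).
#' @return A list: `clusters` (tibble `centroid_id`, `member_id`,
#'   `identity`; centroids are not listed as their own members) and
#'   `nonredundant` (the centroid subset of `library`, discovery order).
#' @export
cluster_greedy <- function(library, S = cfg$S, cfg = ltr_config()) {
  if (!(S > 0 && S <= 1)) abort("cluster_greedy: S must lie in (0, 1]")
  n <- nrow(library)
  clusters <- tibble(centroid_id = character(), member_id = character(),
                     identity = double())
  if (n == 0) return(list(clusters = clusters, nonredundant = library))
  ord <- order(-library$length, seq_len(n))
  lib <- library[ord, ]
  centroid_idx <- integer(0)
  recs <- list()
  for (i in seq_len(n)) {
    len_i <- lib$length[i]
    joined <- FALSE
    for (c in centroid_idx) {
      len_c <- lib$length[c]
      if (min(len_i, len_c) / max(len_i, len_c) < S) next
      ident <- alignment_identity(lib$residues[i], lib$residues[c],
                                  cfg$match, cfg$mismatch, cfg$gap_open,
                                  cfg$gap_extend)
      if (ident >= S) {
        recs[[length(recs) + 1]] <- tibble(
          centroid_id = lib$element_id[c],
          member_id = lib$element_id[i], identity = ident)
        joined <- TRUE
        break
      }
    }
    if (!joined) centroid_idx <- c(centroid_idx, i)
  }
  if (length(recs)) clusters <- list_rbind(recs)
  list(clusters = clusters, nonredundant = lib[centroid_idx, ])
}

#' Write a library tibble as FASTA
#'
#' @param library Library tibble (`header`, `residues`).
#' @param path Output path.
#' @export
write_library_fasta <- function(library, path) {
  write_fasta(setNames(library$residues, library$header), path)
}

#' Read a library FASTA back
#'
#' @param path FASTA written by [write_library_fasta()].
#' @return A library tibble with parsed header fields attached.
#' @export
read_library_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  parsed <- parse_library_header(hdr)
  tibble(element_id = parsed$element_id, header = hdr,
         residues = unname(toupper(as.character(ss))),
         length = unname(nchar(as.character(ss))),
         class_string = parsed$class_string, seq_id = parsed$seq_id,
         start = parsed$start, end = parsed$end, strand = parsed$strand)
}
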