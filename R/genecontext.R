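# Gene-context calling: interval algebra between element spans and gene
# spans on the same sequence. "Upstream"/"downstream" are taken relative to
# the element's genomic orientation: a gene ending before the element start
# is upstream of the element.

RELATION_ENUM <- c("WITHIN_GENE", "CONTAINS_GENE", "PARTIAL_OVERLAP",
                   "NEAR_UPSTREAM", "NEAR_DOWNSTREAM", "INTERGENIC")

#' Relate elements to genes
#'
#' For every gene overlapping an element, or lying within `U` bp upstream /
#' `X` bp downstream of it, one record is emitted: containment either way
#' (`WITHIN_GENE` when the element lies inside the gene, checked first;
#' `CONTAINS_GENE` when the gene lies inside the element), else
#' `PARTIAL_OVERLAP`, else the nearest-edge distance relation. Elements
#' with no qualifying gene get a single `INTERGENIC` record. All qualifying
#' genes are reported, ordered by gene start.
#'
#' @param elements Element tibble.
#' @param genes Gene tibble from [read_gff3_genes()].
#' @param U,X Maximum upstream / downstream distance (bp); defaults from
#'   `cfg`.
#' @param cfg An [ltr_config()].
#' @return A tibble `element_id`, `gene_id`, `relation`, `distance_bp`
#'   (0 for overlap relations, `NA` for `INTERGENIC`).
#' @export
relate_elements <- function(elements, genes, U = cfg$U, X = cfg$X,
                            cfg = ltr_config()) {
  if (U < 0 || X < 0) abort("relate_elements: U and X must be >= 0")
  rows <- map(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    g <- genes[genes$seq_id == e$seq_id, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    recs <- list()
    for (j in seq_len(nrow(g))) {
      gs <- g$start[j]; ge <- g$end[j]
      rel <- NULL; dist <- 0L
      if (gs <= e$start && ge >= e$end) {
        rel <- "WITHIN_GENE"
      } else if (e$start <= gs && e$end >= ge) {
        rel <- "CONTAINS_GENE"
      } else if (gs < e$end && ge > e$start) {
        rel <- "PARTIAL_OVERLAP"
      } else if (ge <= e$start) {
        dist <- e$start - ge
        if (dist <= U) rel <- "NEAR_UPSTREAM"
      } else {
        dist <- gs - e$end
        if (dist <= X) rel <- "NEAR_DOWNSTREAM"
      }
      if (!is.null(rel)) {
        recs[[length(recs) + 1]] <- tibble(
          element_id = e$element_id, gene_id = g$gene_id[j],
          relation = rel, distance_bp = as.integer(dist))
      }
    }
    if (!length(recs)) {
      return(tibble(element_id = e$element_id, gene_id = NA_character_,
                    relation = "INTERGENIC", distance_bp = NA_integer_))
    }
    list_rbind(recs)
  })
  if (!length(rows)) {
    return(tibble(element_id = character(), gene_id = character(),
                  relation = character(), distance_bp = integer()))
  }
  list_rbind(rows)
}

#' Gene-chimera report
#'
#' Filters a gene-context table down to chimeras. Policy `"overlap"`
#' (default) counts any shared base; `"within"` restricts to elements fully
#' inside a gene.
#'
#' @param contexts Tibble from [relate_elements()].
#' @param policy `"overlap"` or `"within"`.
#' @return The chimera subset of `contexts`.
#' @export
gene_chimeras <- function(contexts, policy = c("overlap", "within")) {
  policy <- match.arg(policy)
  keep <- if (policy == "within") "WITHIN_GENE" else
    c("WITHIN_GENE", "CONTAINS_GENE", "PARTIAL_OVERLAP")
  contexts[contexts$relation %in% keep, , drop = FALSE]
}

#' Write gene contexts as TSV
#'
#' @param contexts Tibble from [relate_elements()].
#' @param path Output path.
#' @export
write_genecontext_tsv <- function(contexts, path) {
  write_tsv_plain(contexts, path)
}
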