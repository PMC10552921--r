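# Readers and writers. Genomes travel as tibbles (seq_id, residues, length);
# all tables are tibbles with 0-based half-open coordinates. GFF3 bytes are
# 1-based inclusive; the conversion happens only here.

IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Read a genome FASTA
#'
#' Residues are uppercased; IUPAC ambiguity codes are collapsed to `N`;
#' anything outside the IUPAC alphabet is also mapped to `N` and counted in
#' a warning. Duplicate record ids and empty files are errors.
#'
#' @param path FASTA file (wrapping irrelevant).
#' @return A tibble with `seq_id`, `residues` (over `A,C,G,T,N`) and
#'   `length`, carrying attribute `n_nonstandard` (count of non-IUPAC
#'   characters replaced).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(paste0("read_fasta: no records in ", path))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("read_fasta: duplicate sequence id '", ids[duplicated(ids)][1], "'"))
  }
  res <- toupper(as.character(ss))
  res <- chartr(paste(IUPAC_EXTRA, collapse = ""),
                strrep("N", length(IUPAC_EXTRA)), res)
  n_bad <- sum(vapply(res, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %notin% c("A", "C", "G", "T", "N"))
  }, double(1)))
  if (n_bad > 0) {
    warn(sprintf("read_fasta: %d non-IUPAC character(s) replaced with N", n_bad))
    res <- vapply(res, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[ch %notin% c("A", "C", "G", "T", "N")] <- "N"
      paste(ch, collapse = "")
    }, character(1))
  }
  out <- tibble(seq_id = unname(ids), residues = unname(res),
                length = nchar(unname(res)))
  attr(out, "n_nonstandard") <- n_bad
  out
}

`%notin%` <- function(x, table) !(x %in% table)

#' Write a FASTA file (60-column wrapping)
#'
#' @param x A genome tibble (`seq_id`, `residues`) or a named character
#'   vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.data.frame(x)) x <- setNames(x$residues, x$seq_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

genome_lengths <- function(genome) setNames(genome$length, genome$seq_id)

genome_subseq <- function(genome, seq_id, start, end, strand = "+") {
  row <- match(seq_id, genome$seq_id)
  if (is.na(row)) abort(paste0("unknown sequence id ", seq_id))
  if (start < 0 || end > genome$length[row]) {
    abort(sprintf("span [%d,%d) outside sequence %s", start, end, seq_id))
  }
  s <- substr(genome$residues[row], start + 1, end)
  if (identical(strand, "-")) revcomp_chr(s) else s
}

# -- gene GFF3 --------------------------------------------------------------

parse_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    abort(sprintf("GFF3 parse: line with %d column(s) (expected 9): '%s'",
                  nf[nf != 9][1], lines[which(nf != 9)[1]]))
  }
  fields
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read gene records from a GFF3 file
#'
#' Keeps rows whose feature type matches `feature_type`, converts
#' coordinates to the internal 0-based half-open convention and takes the
#' `ID` attribute as `gene_id` (falling back to a `seqid:start-end` locus
#' string). An empty result after filtering triggers a warning.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (column 3), default `"gene"`.
#' @return A tibble `gene_id`, `seq_id`, `start`, `end`, `strand`, in file
#'   order.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  fields <- parse_gff3_lines(path)
  keep <- vapply(fields, function(f) f[3] == feature_type, logical(1))
  fields <- fields[keep]
  if (!length(fields)) {
    warn(paste0("read_gff3_genes: no '", feature_type, "' features in ", path))
    return(tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  seqid <- vapply(fields, `[`, character(1), 1)
  start1 <- as.integer(vapply(fields, `[`, character(1), 4))
  end1 <- as.integer(vapply(fields, `[`, character(1), 5))
  strand <- vapply(fields, `[`, character(1), 7)
  attrs <- vapply(fields, `[`, character(1), 9)
  if (any(end1 < start1)) {
    abort("read_gff3_genes: record with end < start")
  }
  ids <- gff3_attr(attrs, "ID")
  fallback <- sprintf("%s:%d-%d", seqid, start1, end1)
  ids[is.na(ids)] <- fallback[is.na(ids)]
  iv <- from_gff_coords(start1, end1)
  tibble(gene_id = ids, seq_id = seqid, start = iv$start, end = iv$end,
         strand = strand)
}

#' Write gene records as GFF3
#'
#' @param genes Gene tibble (`gene_id`, `seq_id`, `start`, `end`, `strand`).
#' @param path Output path.
#' @param source Value for GFF3 column 2.
#' @export
write_gff3_genes <- function(genes, path, source = "ltrkit") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- arrange(genes, .data$seq_id, .data$start)
  gff <- to_gff_coords(g$start, g$end)
  writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$seq_id, source, gff$start, gff$end, g$strand,
                     g$gene_id), con)
  invisible(path)
}

# -- element GFF3 dialect ---------------------------------------------------

num17 <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

#' Write annotated elements as GFF3
#'
#' One `LTR_retrotransposon` parent row per element, with Sequence Ontology
#' child rows: `long_terminal_repeat` (x2), `target_site_duplication` (x2,
#' when recorded), `primer_binding_site`, `RR_tract` (the PPT) and
#' `protein_match` (domain hits). Children carry `Parent=`; classification
#' and insertion age ride as parent attributes. Rows are sorted by
#' `(seq_id, element start)` with each parent preceding its children.
#'
#' @param elements Element tibble.
#' @param path Output path.
#' @param domains,pbs,ppt Optional feature tibbles (element-local
#'   coordinates).
#' @param classifications Optional classification tibble.
#' @param ages Optional age tibble.
#' @param source GFF3 source column.
#' @export
write_element_gff3 <- function(elements, path, domains = NULL, pbs = NULL,
                               ppt = NULL, classifications = NULL,
                               ages = NULL, source = "ltrkit") {
  known <- elements$element_id
  for (tb in list(domains, pbs, ppt, classifications, ages)) {
    if (!is.null(tb) && nrow(tb) && any(tb$element_id %notin% known)) {
      abort("write_element_gff3: feature references unknown element id")
    }
  }
  cls <- if (!is.null(classifications) && nrow(classifications)) {
    setNames(classification_string(classifications$category,
                                   classifications$superfamily,
                                   classifications$clade),
             classifications$element_id)
  } else NULL
  age_mya <- if (!is.null(ages) && nrow(ages)) {
    setNames(ages$T_mya, ages$element_id)
  } else NULL

  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ord <- order(elements$seq_id, elements$start)
  for (i in ord) {
    e <- elements[i, ]
    off <- e$start
    row <- function(type, s0, e0, attrs) {
      g <- to_gff_coords(s0, e0)
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              e$seq_id, source, type, g$start, g$end, e$strand, attrs)
    }
    pa <- sprintf("ID=%s;ltr_similarity=%s", e$element_id,
                  num17(e$ltr_similarity))
    if (!is.na(e$tsd_left)) pa <- paste0(pa, ";tsd_left=", e$tsd_left)
    if (!is.na(e$tsd_right)) pa <- paste0(pa, ";tsd_right=", e$tsd_right)
    if (!is.na(e$terminal_motif)) pa <- paste0(pa, ";terminal_motif=", e$terminal_motif)
    if (!is.null(cls) && e$element_id %in% names(cls)) {
      pa <- paste0(pa, ";classification=", cls[[e$element_id]])
    }
    if (!is.null(age_mya) && e$element_id %in% names(age_mya)) {
      pa <- paste0(pa, ";age_mya=", num17(age_mya[[e$element_id]]))
    }
    out <- row("LTR_retrotransposon", e$start, e$end, pa)

    kid <- function(type, s0, e0, extra = "") {
      row(type, s0, e0, paste0("Parent=", e$element_id, extra))
    }
    kids <- character(0)
    ks <- integer(0)
    add <- function(line, s0) {
      kids <<- c(kids, line); ks <<- c(ks, s0)
    }
    add(kid("long_terminal_repeat", e$ltr5_start, e$ltr5_end), e$ltr5_start)
    add(kid("long_terminal_repeat", e$ltr3_start, e$ltr3_end), e$ltr3_start)
    if (!is.na(e$tsd_left) && nzchar(e$tsd_left)) {
      add(kid("target_site_duplication", e$start - nchar(e$tsd_left), e$start),
          e$start - nchar(e$tsd_left))
    }
    if (!is.na(e$tsd_right) && nzchar(e$tsd_right)) {
      add(kid("target_site_duplication", e$end, e$end + nchar(e$tsd_right)),
          e$end)
    }
    if (!is.null(pbs) && nrow(pbs)) {
      h <- pbs[pbs$element_id == e$element_id, ]
      for (j in seq_len(nrow(h))) {
        add(kid("primer_binding_site", off + h$start[j], off + h$end[j],
                sprintf(";trna_id=%s;match_len=%d;offset_from_5ltr=%d",
                        h$trna_id[j], h$match_len[j], h$offset_from_5ltr[j])),
            off + h$start[j])
      }
    }
    if (!is.null(ppt) && nrow(ppt)) {
      h <- ppt[ppt$element_id == e$element_id, ]
      for (j in seq_len(nrow(h))) {
        add(kid("RR_tract", off + h$start[j], off + h$end[j],
                sprintf(";purine_fraction=%s;offset_from_3ltr=%d",
                        num17(h$purine_fraction[j]), h$offset_from_3ltr[j])),
            off + h$start[j])
      }
    }
    if (!is.null(domains) && nrow(domains)) {
      h <- domains[domains$element_id == e$element_id, ]
      for (j in seq_len(nrow(h))) {
        extra <- sprintf(";domain=%s", h$domain[j])
        if (!is.na(h$superfamily[j])) extra <- paste0(extra, ";superfamily=", h$superfamily[j])
        if (!is.na(h$clade[j])) extra <- paste0(extra, ";clade=", h$clade[j])
        add(kid("protein_match", off + h$start[j], off + h$end[j], extra),
            off + h$start[j])
      }
    }
    writeLines(c(out, kids[order(ks)]), con)
  }
  invisible(path)
}

#' Read the element GFF3 dialect back into model tables
#'
#' Inverse of [write_element_gff3()].
#'
#' @param path GFF3 file written by [write_element_gff3()].
#' @return A list of tibbles: `elements`, `domains`, `pbs`, `ppt`,
#'   `classifications` (parsed from the classification attribute, when
#'   present) and `ages` (`element_id`, `T_mya`).
#' @export
read_element_gff3 <- function(path) {
  fields <- parse_gff3_lines(path)
  type <- vapply(fields, `[`, character(1), 3)
  seqid <- vapply(fields, `[`, character(1), 1)
  s1 <- as.integer(vapply(fields, `[`, character(1), 4))
  e1 <- as.integer(vapply(fields, `[`, character(1), 5))
  strand <- vapply(fields, `[`, character(1), 7)
  attrs <- vapply(fields, `[`, character(1), 9)
  iv <- from_gff_coords(s1, e1)

  pi <- which(type == "LTR_retrotransposon")
  ids <- gff3_attr(attrs[pi], "ID")
  parent <- gff3_attr(attrs, "Parent")
  el_start <- setNames(iv$start[pi], ids)
  el_seq <- setNames(seqid[pi], ids)

  ltr_rows <- which(type == "long_terminal_repeat")
  ltr_by <- split(ltr_rows, parent[ltr_rows])
  grab_ltr <- function(id, which_one) {
    rows <- ltr_by[[id]]
    rows <- rows[order(iv$start[rows])]
    rows[which_one]
  }
  elements <- tibble(
    element_id = ids,
    seq_id = unname(el_seq[ids]),
    start = iv$start[pi], end = iv$end[pi],
    strand = strand[pi],
    ltr5_start = vapply(ids, function(i) iv$start[grab_ltr(i, 1)], integer(1),
                        USE.NAMES = FALSE),
    ltr5_end = vapply(ids, function(i) iv$end[grab_ltr(i, 1)], integer(1),
                      USE.NAMES = FALSE),
    ltr3_start = vapply(ids, function(i) iv$start[grab_ltr(i, 2)], integer(1),
                        USE.NAMES = FALSE),
    ltr3_end = vapply(ids, function(i) iv$end[grab_ltr(i, 2)], integer(1),
                      USE.NAMES = FALSE),
    tsd_left = gff3_attr(attrs[pi], "tsd_left"),
    tsd_right = gff3_attr(attrs[pi], "tsd_right"),
    terminal_motif = gff3_attr(attrs[pi], "terminal_motif"),
    ltr_similarity = as.numeric(sub("^\\.$", NA,
                                    gff3_attr(attrs[pi], "ltr_similarity")))
  )
  local_tbl <- function(rows) {
    if (!length(rows)) return(NULL)
    id <- parent[rows]
    tibble(element_id = id,
           start = iv$start[rows] - unname(el_start[id]),
           end = iv$end[rows] - unname(el_start[id]),
           .rows_idx = rows)
  }
  pbs_rows <- local_tbl(which(type == "primer_binding_site"))
  pbs <- if (is.null(pbs_rows)) empty_pbs() else mutate(
    pbs_rows,
    trna_id = gff3_attr(attrs[.data$.rows_idx], "trna_id"),
    match_len = as.integer(gff3_attr(attrs[.data$.rows_idx], "match_len")),
    offset_from_5ltr = as.integer(gff3_attr(attrs[.data$.rows_idx],
                                            "offset_from_5ltr")),
    .rows_idx = NULL
  )
  ppt_rows <- local_tbl(which(type == "RR_tract"))
  ppt <- if (is.null(ppt_rows)) empty_ppt() else mutate(
    ppt_rows,
    purine_fraction = as.numeric(gff3_attr(attrs[.data$.rows_idx],
                                           "purine_fraction")),
    offset_from_3ltr = as.integer(gff3_attr(attrs[.data$.rows_idx],
                                            "offset_from_3ltr")),
    .rows_idx = NULL
  )
  dom_rows <- local_tbl(which(type == "protein_match"))
  domains <- if (is.null(dom_rows)) empty_domains() else mutate(
    dom_rows,
    domain = gff3_attr(attrs[.data$.rows_idx], "domain"),
    superfamily = gff3_attr(attrs[.data$.rows_idx], "superfamily"),
    clade = gff3_attr(attrs[.data$.rows_idx], "clade"),
    .rows_idx = NULL
  ) |> select("element_id", "domain", "start", "end", "superfamily", "clade")

  cls_str <- gff3_attr(attrs[pi], "classification")
  classifications <- if (all(is.na(cls_str))) NULL else {
    parsed <- parse_classification_string(cls_str)
    tibble(element_id = ids, parsed)
  }
  age_str <- gff3_attr(attrs[pi], "age_mya")
  ages <- if (all(is.na(age_str))) NULL else {
    tibble(element_id = ids, T_mya = as.numeric(age_str))
  }
  list(elements = elements, domains = domains, pbs = pbs, ppt = ppt,
       classifications = classifications, ages = ages)
}

empty_domains <- function() {
  tibble(element_id = character(), domain = character(),
         start = integer(), end = integer(),
         superfamily = character(), clade = character())
}
empty_pbs <- function() {
  tibble(element_id = character(), start = integer(), end = integer(),
         trna_id = character(), match_len = integer(),
         offset_from_5ltr = integer())
}
empty_ppt <- function() {
  tibble(element_id = character(), start = integer(), end = integer(),
         purine_fraction = double(), offset_from_3ltr = integer())
}

# -- domain-hit TSV ---------------------------------------------------------

DOMAIN_ENUM <- c("GAG", "PROT", "INT", "RT", "RH", "OTHER")

#' Read a domain-hit table
#'
#' Tab-separated with header `element_id, domain, start, end, superfamily,
#' clade`; coordinates are element-local, 1-based inclusive (the reporting
#' convention of external domain scanners) and are converted to the internal
#' 0-based half-open convention. Unknown domain names are mapped to `OTHER`
#' with a warning.
#'
#' @param path TSV file.
#' @return Domain tibble.
#' @export
read_domain_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("element_id", "domain", "start", "end", "superfamily", "clade")
  if (!all(need %in% names(df))) {
    abort("read_domain_tsv: header must contain element_id, domain, start, end, superfamily, clade")
  }
  if (nrow(df) == 0) return(empty_domains())
  bad <- df$domain %notin% DOMAIN_ENUM
  if (any(bad)) {
    warn(sprintf("read_domain_tsv: %d unknown domain name(s) mapped to OTHER", sum(bad)))
    df$domain[bad] <- "OTHER"
  }
  iv <- from_gff_coords(df$start, df$end)
  tibble(element_id = as.character(df$element_id), domain = df$domain,
         start = iv$start, end = iv$end,
         superfamily = as.character(df$superfamily),
         clade = as.character(df$clade))
}

#' @rdname read_domain_tsv
#' @param domains Domain tibble (internal coordinates).
#' @export
write_domain_tsv <- function(domains, path) {
  gff <- if (nrow(domains)) to_gff_coords(domains$start, domains$end) else
    tibble(start = integer(), end = integer())
  out <- data.frame(element_id = domains$element_id, domain = domains$domain,
                    start = gff$start, end = gff$end,
                    superfamily = domains$superfamily, clade = domains$clade)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.17g", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- library FASTA header dialect ------------------------------------------

#' Library FASTA headers
#'
#' `format_library_header()` renders `element_id#classification
#' seq_id:start-end(strand)` with GFF-style (1-based inclusive) coordinates;
#' `parse_library_header()` inverts it.
#'
#' @param element_id,class_string,seq_id,start,end,strand Header fields;
#'   `start`/`end` in internal 0-based half-open coordinates.
#' @return A character vector of headers, or for the parser a tibble with
#'   the fields (internal coordinates restored).
#' @export
format_library_header <- function(element_id, class_string, seq_id,
                                  start, end, strand) {
  gff <- to_gff_coords(start, end)
  sprintf("%s#%s %s:%d-%d(%s)", element_id, class_string, seq_id,
          gff$start, gff$end, strand)
}

#' @rdname format_library_header
#' @param header Character vector of headers.
#' @export
parse_library_header <- function(header) {
  m <- regmatches(header,
                  regexec("^(\\S+)#(\\S+) (\\S+):(\\d+)-(\\d+)\\(([+.-])\\)$",
                          header))
  bad <- lengths(m) == 0 | vapply(m, length, integer(1)) != 7
  if (any(bad)) abort(paste0("parse_library_header: malformed header '",
                             header[bad][1], "'"))
  iv <- from_gff_coords(as.integer(vapply(m, `[`, character(1), 5)),
                        as.integer(vapply(m, `[`, character(1), 6)))
  tibble(
    element_id = vapply(m, `[`, character(1), 2),
    class_string = vapply(m, `[`, character(1), 3),
    seq_id = vapply(m, `[`, character(1), 4),
    start = iv$start, end = iv$end,
    strand = vapply(m, `[`, character(1), 7)
  )
}
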