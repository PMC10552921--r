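# Rule-based classification of intact elements into autonomous and
# non-autonomous categories, superfamily and clade, driven by the order of
# internal protein domains. The two canonical autonomous layouts are
#   Gypsy: GAG-PROT-RT-RH-INT      Copia: GAG-PROT-INT-RT-RH
# (integrase after RNase H for Gypsy, before the reverse transcriptase for
# Copia); PBS and PPT presence completes the autonomous template.

CATEGORY_ENUM <- c("AUTON_GYPSY", "AUTON_COPIA", "NONAUTON_GYPSY",
                   "NONAUTON_COPIA", "LARD", "TRIM", "TR_GAG", "BARE2",
                   "UNKNOWN")
CORE_DOMAINS <- c("GAG", "PROT", "INT", "RT", "RH")
GYPSY_ORDER <- c("GAG", "PROT", "RT", "RH", "INT")
COPIA_ORDER <- c("GAG", "PROT", "INT", "RT", "RH")

#' Domain order of an element
#'
#' Sorts an element's domain hits by element-local start (reversed for
#' minus-strand elements so the order reads 5' to 3' on the element),
#' drops `OTHER` hits, collapses adjacent duplicates, and resolves
#' overlapping core-domain hits by keeping the longer one (recording a
#' warning token in the trace).
#'
#' @param hits Domain tibble for one element.
#' @param strand Element strand (`"+"`, `"-"`, `"."`).
#' @return A list with `order` (character vector of domain names, possibly
#'   empty) and `warnings` (character vector of trace tokens).
#' @export
domain_order <- function(hits, strand = "+") {
  warnings <- character(0)
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(order = character(0), warnings = warnings))
  }
  h <- arrange(hits, .data$start, .data$end)
  core <- h[h$domain %in% CORE_DOMAINS, ]
  # overlap resolution among core hits: keep the longer of each overlapping pair
  if (nrow(core) > 1) {
    keep <- rep(TRUE, nrow(core))
    for (i in seq_len(nrow(core) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):nrow(core)) {
        if (!keep[j]) next
        if (core$start[j] < core$end[i]) {  # overlap
          len_i <- core$end[i] - core$start[i]
          len_j <- core$end[j] - core$start[j]
          drop <- if (len_j > len_i) i else j
          keep[drop] <- FALSE
          warnings <- c(warnings,
                        sprintf("overlap_dropped:%s", core$domain[drop]))
          if (drop == i) break
        }
      }
    }
    core <- core[keep, ]
  }
  ord <- core$domain
  if (identical(strand, "-")) ord <- rev(ord)
  ord <- rle(ord)$values  # collapse adjacent duplicates
  list(order = ord, warnings = warnings)
}

#' Classify one element from its domain order and features
#'
#' Decision cascade (first match wins, every step appended to the rule
#' trace):
#' 1. Gypsy order + PBS + PPT -> autonomous Gypsy
#' 2. Copia order + PBS + PPT -> autonomous Copia
#' 3. has GAG and at least one of INT/RT/RH but not 1/2 -> non-autonomous,
#'    superfamily by majority of hit labels, tie broken by the position of
#'    INT relative to RT/RH, else unknown
#' 4. has at least one of PROT/INT/RT/RH and no GAG -> BARE-2
#' 5. GAG alone -> TR-GAG
#' 6. no domains, total length <= `trim_max_len` -> TRIM
#' 7. no domains, internal region >= `lard_min_internal` -> LARD
#' 8. otherwise unknown
#'
#' With `cfg$autonomy_requires_pbs_ppt = FALSE`, steps 1-2 need the
#' canonical order only.
#'
#' @param order Character vector from [domain_order()].
#' @param has_pbs,has_ppt Logical: PBS / PPT present.
#' @param total_len Element length including both LTRs (bp).
#' @param internal_len Internal region length (bp).
#' @param superfamily_labels,clade_labels Optional label vectors from the
#'   domain hits (majority vote).
#' @param cfg An [ltr_config()].
#' @param trace Initial trace tokens (e.g. from [domain_order()]).
#' @return A one-row tibble `category`, `superfamily`, `clade`,
#'   `rule_trace` (semicolon-joined).
#' @export
classify_element <- function(order, has_pbs, has_ppt, total_len,
                             internal_len, superfamily_labels = character(0),
                             clade_labels = character(0),
                             cfg = ltr_config(), trace = character(0)) {
  need_feats <- cfg$autonomy_requires_pbs_ppt
  feats_ok <- !need_feats || (has_pbs && has_ppt)
  vote <- function(labels) {
    labels <- labels[!is.na(labels) & nzchar(labels)]
    if (!length(labels)) return(NA_character_)
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
    names(tab)[1]
  }
  category <- NULL
  superfamily <- "unknown"

  if (identical(order, GYPSY_ORDER) && feats_ok) {
    trace <- c(trace, "R1:gypsy_order+pbs+ppt")
    category <- "AUTON_GYPSY"; superfamily <- "Gypsy"
  } else if (identical(order, COPIA_ORDER) && feats_ok) {
    trace <- c(trace, "R2:copia_order+pbs+ppt")
    category <- "AUTON_COPIA"; superfamily <- "Copia"
  } else if (length(order) > 0 && any(c("RT", "RH", "INT") %in% order) &&
             "GAG" %in% order) {
    sf <- vote(superfamily_labels)
    if (is.na(sf)) {
      pos_int <- match("INT", order)
      pos_rt <- match("RT", order)
      pos_rh <- match("RH", order)
      if (!is.na(pos_int) && !is.na(pos_rh) && pos_int > pos_rh) {
        sf <- "Gypsy"; trace <- c(trace, "R3:int_after_rh")
      } else if (!is.na(pos_int) && !is.na(pos_rt) && pos_int < pos_rt) {
        sf <- "Copia"; trace <- c(trace, "R3:int_before_rt")
      }
    } else {
      trace <- c(trace, "R3:label_vote")
    }
    if (identical(sf, "Gypsy")) {
      category <- "NONAUTON_GYPSY"; superfamily <- "Gypsy"
      trace <- c(trace, "R3:nonauton_gypsy")
    } else if (identical(sf, "Copia")) {
      category <- "NONAUTON_COPIA"; superfamily <- "Copia"
      trace <- c(trace, "R3:nonauton_copia")
    } else {
      category <- "UNKNOWN"
      trace <- c(trace, "R3:superfamily_undecidable")
    }
  } else if (length(order) > 0 &&
             any(c("PROT", "RT", "RH", "INT") %in% order) &&
             !("GAG" %in% order)) {
    trace <- c(trace, "R4:no_gag_with_pol_domain")
    category <- "BARE2"
  } else if (identical(order, "GAG")) {
    trace <- c(trace, "R5:gag_only")
    category <- "TR_GAG"
  } else if (length(order) == 0 && total_len <= cfg$trim_max_len) {
    trace <- c(trace, "R6:no_domains_short")
    category <- "TRIM"
  } else if (length(order) == 0 && internal_len >= cfg$lard_min_internal) {
    trace <- c(trace, "R7:no_domains_long_internal")
    category <- "LARD"
  } else {
    trace <- c(trace, "R8:fallthrough")
    category <- "UNKNOWN"
  }
  if (superfamily == "unknown" &&
      category %in% c("LARD", "TRIM", "TR_GAG", "BARE2")) {
    sf <- vote(superfamily_labels)
    if (!is.na(sf)) { superfamily <- sf; trace <- c(trace, "SF:label_vote") }
  }
  clade <- vote(clade_labels)
  tibble(category = category, superfamily = superfamily,
         clade = clade, rule_trace = paste(trace, collapse = ";"))
}

#' Classify a table of elements
#'
#' Applies [domain_order()] and [classify_element()] to every element.
#'
#' @param elements Element tibble.
#' @param domains Domain tibble (element-local coordinates).
#' @param pbs,ppt Feature tibbles.
#' @param cfg An [ltr_config()].
#' @return A tibble `element_id`, `category`, `superfamily`, `clade`,
#'   `rule_trace`.
#' @export
classify_elements <- function(elements, domains = empty_domains(),
                              pbs = empty_pbs(), ppt = empty_ppt(),
                              cfg = ltr_config()) {
  internal <- internal_region(elements)
  rows <- map(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    h <- domains[domains$element_id == e$element_id, ]
    od <- domain_order(h, e$strand)
    cl <- classify_element(
      order = od$order,
      has_pbs = e$element_id %in% pbs$element_id,
      has_ppt = e$element_id %in% ppt$element_id,
      total_len = e$end - e$start,
      internal_len = internal$length[i],
      superfamily_labels = h$superfamily,
      clade_labels = h$clade,
      cfg = cfg, trace = od$warnings
    )
    mutate(cl, element_id = e$element_id, .before = 1)
  })
  if (!length(rows)) {
    return(tibble(element_id = character(), category = character(),
                  superfamily = character(), clade = character(),
                  rule_trace = character()))
  }
  list_rbind(rows)
}

# -- classification string vocabulary --------------------------------------

CATEGORY_TOKEN <- c(
  AUTON_GYPSY = "autonomous", AUTON_COPIA = "autonomous",
  NONAUTON_GYPSY = "nonautonomous", NONAUTON_COPIA = "nonautonomous",
  LARD = "LARD", TRIM = "TRIM", TR_GAG = "TR-GAG", BARE2 = "BARE-2",
  UNKNOWN = "unknown"
)

#' Render / parse the closed classification vocabulary
#'
#' Strings look like `LTR/Gypsy/autonomous/Tekay` or
#' `LTR/unknown/TR-GAG`; the parser restores `category`, `superfamily`,
#' `clade`.
#'
#' @param category,superfamily,clade Classification fields.
#' @return Character vector of classification strings; the parser returns a
#'   tibble.
#' @export
classification_string <- function(category, superfamily, clade = NA) {
  token <- CATEGORY_TOKEN[category]
  base <- sprintf("LTR/%s/%s", superfamily, token)
  ifelse(is.na(clade), base, paste0(base, "/", clade))
}

#' @rdname classification_string
#' @param x Character vector of classification strings.
#' @export
parse_classification_string <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  parse1 <- function(p) {
    if (length(p) < 3 || p[1] != "LTR") {
      abort(paste0("parse_classification_string: malformed '", paste(p, collapse = "/"), "'"))
    }
    sf <- p[2]; token <- p[3]
    clade <- if (length(p) >= 4) p[4] else NA_character_
    category <- switch(token,
      autonomous = if (sf == "Gypsy") "AUTON_GYPSY" else "AUTON_COPIA",
      nonautonomous = if (sf == "Gypsy") "NONAUTON_GYPSY" else "NONAUTON_COPIA",
      LARD = "LARD", TRIM = "TRIM", `TR-GAG` = "TR_GAG", `BARE-2` = "BARE2",
      unknown = "UNKNOWN",
      abort(paste0("parse_classification_string: unknown token '", token, "'"))
    )
    tibble(category = category, superfamily = sf, clade = clade)
  }
  list_rbind(map(parts, parse1))
}

#' Write classifications as TSV
#'
#' @param classifications Classification tibble.
#' @param path Output path.
#' @export
write_classification_tsv <- function(classifications, path) {
  write_tsv_plain(classifications, path)
}
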