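# End-to-end orchestration: detector -> features -> (classify, age) ->
# gene context -> library -> stats, with per-sequence parallelism for the
# detection stage and deterministic merging (results sorted by seq_id then
# coordinate), so output bytes do not depend on the worker count.

#' Run the full annotation pipeline
#'
#' Stages run in order: structural detection, PBS/PPT annotation,
#' classification and insertion-age estimation, gene-context calling,
#' redundant and non-redundant library construction, summary statistics.
#' Detection is distributed over `cfg$threads` workers one sequence at a
#' time; results are merged in `(seq_id, start)` order so any thread count
#' produces byte-identical outputs. A JSON run manifest (config snapshot,
#' input checksums, stage timings, output list) is written on both success
#' and failure.
#'
#' @param genome Genome tibble from [read_fasta()], or a FASTA path.
#' @param out_dir Output directory (created if needed).
#' @param genes Optional gene tibble / GFF3 path; when absent the
#'   gene-context stage is skipped and the skip is recorded in the
#'   manifest.
#' @param trnas Optional tRNA tibble / FASTA path; when absent the PBS
#'   stage is skipped (PPT still runs).
#' @param domains Optional domain-hit tibble / TSV path (external
#'   domain-scanner results); when absent elements are classified on
#'   structure alone.
#' @param cfg An [ltr_config()]. `cfg$R` must be set for age estimation;
#'   when `NULL` the age stage is skipped and recorded.
#' @param cluster_S Identity threshold for the non-redundant library
#'   (defaults to `cfg$S`).
#' @return An `ltr_run` object (list of result tibbles plus the manifest).
#' @export
run_pipeline <- function(genome, out_dir, genes = NULL, trnas = NULL,
                         domains = NULL, cfg = ltr_config(),
                         cluster_S = cfg$S) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("ltrkit ", as.character(utils::packageVersion("ltrkit"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg)[setdiff(names(cfg), "passthrough")],
    inputs = list(), skipped = character(0), timings = list(),
    outputs = character(0), status = "running"
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  on.exit({
    if (identical(manifest$status, "running")) manifest$status <- "failed"
    flush_manifest()
  })

  take <- function(x, reader) {
    if (is.character(x) && length(x) == 1) {
      manifest$inputs[[basename(x)]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }
  genome <- take(genome, read_fasta)
  genes <- take(genes, read_gff3_genes)
  trnas <- take(trnas, read_fasta)
  domains <- take(domains, read_domain_tsv)
  if (!is.null(genes) && nrow(genes)) {
    unknown <- setdiff(unique(genes$seq_id), genome$seq_id)
    if (length(unknown)) {
      warn(paste0("run_pipeline: gene annotation references unknown sequence(s) ",
                  paste(unknown, collapse = ", "), "; those records are skipped"))
      genes <- genes[genes$seq_id %in% genome$seq_id, ]
    }
  }

  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # detection, one task per sequence; merge deterministically
  elements <- timed("detect", {
    per_seq <- parallel::mclapply(seq_len(nrow(genome)), function(i) {
      ext <- extend_and_align(find_seed_pairs(genome[i, ], cfg),
                              genome[i, ], cfg)
      det <- structural_filter(ext$candidates, genome[i, ], cfg)
      resolve_overlaps(det$elements)
    }, mc.cores = max(1L, cfg$threads))
    err <- vapply(per_seq, inherits, logical(1), "try-error")
    merged <- arrange(list_rbind(c(list(empty_elements()), per_seq)),
                      .data$seq_id, .data$start)
    merged <- merged[!duplicated(merged[, c("seq_id", "start", "end")]), ]
    merged$element_id <- sprintf("LTRRT_%05d", seq_len(nrow(merged)))
    validate_elements(merged)
  })

  feats <- timed("features", {
    ppt <- find_ppt(elements, genome, cfg)
    pbs <- if (is.null(trnas)) {
      manifest$skipped <- c(manifest$skipped, "pbs:no_trna_library")
      empty_pbs()
    } else find_pbs(elements, genome, trnas, cfg)
    list(pbs = pbs, ppt = ppt)
  })

  if (!is.null(domains) && nrow(domains)) {
    stray <- !(domains$element_id %in% elements$element_id)
    if (any(stray)) {
      warn(sprintf("run_pipeline: %d domain hit(s) reference unknown element ids and are ignored",
                   sum(stray)))
      domains <- domains[!stray, ]
    }
  }
  classifications <- timed("classify", {
    classify_elements(elements,
                      if (is.null(domains)) empty_domains() else domains,
                      feats$pbs, feats$ppt, cfg)
  })
  if (is.null(domains)) {
    manifest$skipped <- c(manifest$skipped, "domains:no_hit_table")
  }

  ages <- timed("age", {
    if (is.null(cfg$R)) {
      manifest$skipped <- c(manifest$skipped, "age:no_rate_R")
      NULL
    } else {
      estimate_ages(elements, genome, cfg$R, cfg)
    }
  })

  contexts <- timed("genecontext", {
    if (is.null(genes)) {
      manifest$skipped <- c(manifest$skipped, "genecontext:no_gene_annotation")
      NULL
    } else {
      relate_elements(elements, genes, cfg$U, cfg$X, cfg)
    }
  })

  lib <- timed("library", {
    redundant <- build_redundant_library(elements, genome, classifications)
    cl <- cluster_greedy(redundant, cluster_S, cfg)
    list(redundant = redundant, clusters = cl$clusters,
         nonredundant = cl$nonredundant)
  })

  stats_out <- timed("stats", {
    lens <- genome_lengths(genome)
    list(
      length_summary = if (nrow(elements)) {
        boxplot_summary(elements$end - elements$start)
      } else NULL,
      age_summary = if (!is.null(ages) && any(ages$flag == "ok")) {
        boxplot_summary(ages$T_mya[ages$flag == "ok"])
      } else NULL,
      density = density_track(
        if (is.null(genes)) empty_gene_tbl() else genes,
        elements, lens, cfg$W)
    )
  })

  # write everything
  out <- function(name) file.path(out_dir, name)
  write_element_gff3(elements, out("elements.gff3"), domains = domains,
                     pbs = feats$pbs, ppt = feats$ppt,
                     classifications = classifications, ages = ages)
  write_classification_tsv(classifications, out("classification.tsv"))
  write_tsv_plain(feats$pbs, out("pbs.tsv"))
  write_tsv_plain(feats$ppt, out("ppt.tsv"))
  if (!is.null(ages)) write_age_tsv(ages, out("age.tsv"))
  if (!is.null(contexts)) write_genecontext_tsv(contexts, out("genecontext.tsv"))
  write_library_fasta(lib$redundant, out("redundant_library.fa"))
  write_library_fasta(lib$nonredundant, out("nonredundant_library.fa"))
  write_tsv_plain(lib$clusters, out("clusters.tsv"))
  write_tsv_plain(stats_out$density, out("density_track.tsv"))
  ideo <- ideogram_data(stats_out$density, genome_lengths(genome),
                        min(cfg$N, nrow(genome)))
  write_tsv_plain(ideo, out("ideogram.tsv"))
  if (!is.null(stats_out$length_summary)) {
    write_tsv_plain(select(stats_out$length_summary, -"outliers"),
                    out("length_boxplot.tsv"))
  }
  if (!is.null(stats_out$age_summary)) {
    write_tsv_plain(select(stats_out$age_summary, -"outliers"),
                    out("age_boxplot.tsv"))
  }
  manifest$outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$status <- "ok"

  structure(list(
    elements = elements, pbs = feats$pbs, ppt = feats$ppt,
    classifications = classifications, ages = ages, contexts = contexts,
    library = lib, stats = stats_out, manifest = manifest,
    out_dir = out_dir
  ), class = "ltr_run")
}

empty_gene_tbl <- function() {
  tibble(gene_id = character(), seq_id = character(), start = integer(),
         end = integer(), strand = character())
}

#' @export
print.ltr_run <- function(x, ...) {
  cat(sprintf("<ltr_run> %d element(s); outputs in %s\n",
              nrow(x$elements), x$out_dir))
  if (nrow(x$classifications)) {
    print(dplyr::count(x$classifications, .data$category))
  }
  invisible(x)
}

#' Tidy / summarise a pipeline run
#'
#' `tidy()` returns one row per element with classification and age joined
#' on; `glance()` a one-row run summary.
#'
#' @param x An `ltr_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ltr_run <- function(x, ...) {
  out <- left_join(x$elements, x$classifications, by = "element_id")
  if (!is.null(x$ages)) {
    out <- left_join(out, select(x$ages, "element_id", "K", "T_mya", "flag"),
                     by = "element_id")
  }
  out
}

#' @rdname tidy.ltr_run
#' @export
glance.ltr_run <- function(x, ...) {
  tibble(
    n_elements = nrow(x$elements),
    n_autonomous = sum(x$classifications$category %in%
                         c("AUTON_GYPSY", "AUTON_COPIA")),
    n_gypsy = sum(x$classifications$superfamily == "Gypsy"),
    n_copia = sum(x$classifications$superfamily == "Copia"),
    n_clusters = nrow(x$library$nonredundant),
    mean_age_mya = if (!is.null(x$ages) && any(x$ages$flag == "ok")) {
      mean(x$ages$T_mya[x$ages$flag == "ok"])
    } else NA_real_,
    n_chimeric = if (!is.null(x$contexts)) {
      length(unique(gene_chimeras(x$contexts)$element_id))
    } else NA_integer_
  )
}
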