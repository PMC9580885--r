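#' Per-gene nutrient-cycle summary
#'
#' One row per key gene of each cycle (rows are emitted even when a gene has
#' no hits, so the overview always has the full cycle schema): total hit
#' count, number of bins harboring the gene, and the organism-depth
#' percentage. %O-depth is the coverage-weighted fraction of the community
#' encoding the gene: 100 times the summed mean depth of bins harboring it,
#' divided by the summed depth of all bins with coverage. Bins without a
#' coverage row are excluded from both numerator and denominator; with no
#' coverage table at all the column is `NA`.
#'
#' @param annotations Annotation data.frame (needs orf_id, bin_id, gene_label,
#'   cycle columns; non-key annotations are ignored here).
#' @param cycle_genes data.frame of the database's key genes: columns cycle,
#'   gene_label, ko_id, in declared cycle order.
#' @param coverage Named numeric vector from [load_coverage()], or `NULL`.
#' @return data.frame: cycle, gene_label, ko_id, n_hits, n_bins, o_depth_pct.
#' @export
summarize_genes <- function(annotations, cycle_genes, coverage = NULL) {
  stopifnot(all(c("cycle", "gene_label") %in% names(cycle_genes)))
  if (!"ko_id" %in% names(cycle_genes)) cycle_genes$ko_id <- NA_character_
  covered_total <- if (!is.null(coverage)) sum(coverage, na.rm = TRUE) else NA
  rows <- lapply(seq_len(nrow(cycle_genes)), function(i) {
    g <- cycle_genes[i, ]
    sel <- annotations$cycle == g$cycle & annotations$gene_label == g$gene_label
    a <- annotations[which(sel), , drop = FALSE]
    bins <- unique(a$bin_id)
    o_depth <- NA_real_
    if (!is.null(coverage) && covered_total > 0) {
      o_depth <- 100 * sum(coverage[bins], na.rm = TRUE) / covered_total
    }
    data.frame(cycle = g$cycle, gene_label = g$gene_label, ko_id = g$ko_id,
               n_hits = nrow(a), n_bins = length(bins),
               o_depth_pct = o_depth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll gene summaries up to processes
#'
#' A process (e.g. methanotrophy, nitrate reduction) is scored by the maximum
#' hit count over its member genes -- the abundance of a multi-subunit system
#' is what any single subunit was detected at -- except hydrogenase classes,
#' which are sums over their group profiles. Organism counts and %O-depth are
#' computed over the union of bins harboring any member gene.
#'
#' @param gene_rows Output of [summarize_genes()].
#' @param process_defs Named list: process -> list(genes = character vector,
#'   roll_up = "max"|"sum"). See [read_process_defs()].
#' @param annotations The annotation data.frame (for bin membership).
#' @param coverage Named coverage vector or `NULL`.
#' @return data.frame: process, roll_up, n_hits, n_orgs, o_depth_pct.
#' @export
rollup_process <- function(gene_rows, process_defs, annotations,
                           coverage = NULL) {
  covered_total <- if (!is.null(coverage)) sum(coverage, na.rm = TRUE) else NA
  rows <- lapply(names(process_defs), function(pn) {
    def <- process_defs[[pn]]
    roll <- if (!is.null(def$roll_up)) def$roll_up else "max"
    genes <- intersect(def$genes, gene_rows$gene_label)
    unknown <- setdiff(def$genes, gene_rows$gene_label)
    if (length(unknown))
      warning("process ", pn, ": unknown gene(s) skipped: ",
              paste(unknown, collapse = ", "))
    counts <- gene_rows$n_hits[match(genes, gene_rows$gene_label)]
    n_hits <- if (length(counts) == 0) 0L
      else if (roll == "sum") sum(counts) else max(counts)
    bins <- unique(annotations$bin_id[annotations$gene_label %in% genes])
    o_depth <- NA_real_
    if (!is.null(coverage) && covered_total > 0)
      o_depth <- 100 * sum(coverage[bins], na.rm = TRUE) / covered_total
    data.frame(process = pn, roll_up = roll, n_hits = n_hits,
               n_orgs = length(bins), o_depth_pct = o_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read process definitions
#'
#' YAML mapping process names to member gene labels and a roll-up rule, e.g.
#' ```yaml
#' Methanotrophy: {genes: [pmoA, pmoB, pmoC], roll_up: max}
#' FeFe hydrogenases: {genes: [FeFe-A, FeFe-B], roll_up: sum}
#' ```
#' The packaged default (`system.file("extdata", "processes.yaml", package =
#' "cyclescan")`) is a starting point; which genes define a process is an
#' analysis choice with direct impact on the results, so the file is meant to
#' be edited.
#'
#' @param path YAML file.
#' @return Named list usable by [rollup_process()].
#' @export
read_process_defs <- function(path) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(d) {
    list(genes = unlist(d$genes),
         roll_up = if (!is.null(d$roll_up)) d$roll_up else "max")
  })
}

#' Write the metagenome-level overview TSV
#'
#' One row per key gene, ordered by declared cycle order; abundance printed to
#' one decimal (internal math stays full precision), `NA` without coverage.
#' Output is byte-stable for identical inputs.
#'
#' @param gene_rows Output of [summarize_genes()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_overview <- function(gene_rows, path) {
  out <- gene_rows
  out$o_depth_pct <- ifelse(is.na(out$o_depth_pct), "NA",
                            sprintf("%.1f", out$o_depth_pct))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Krona text-import file
#'
#' Tab-separated count-then-hierarchy lines (`count TAB cycle TAB gene`),
#' importable by the standard Krona text importer (`ktImportText`). Genes
#' with zero hits are omitted; the summed counts equal the summed `n_hits`.
#'
#' @param gene_rows Output of [summarize_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_krona_text <- function(gene_rows, path) {
  hit <- gene_rows[gene_rows$n_hits > 0, , drop = FALSE]
  writeLines(sprintf("%d\t%s\t%s", hit$n_hits, hit$cycle, hit$gene_label),
             path)
  invisible(path)
}

#' Write per-bin KEGG-mapper TSVs
#'
#' For each bin, lines `orf_id TAB KO` for every annotation that carries a KO
#' number; KO-less profiles (e.g. hydrogenase groups) are excluded. The files
#' paste directly into the KEGG mapper web tool.
#'
#' @param annotations Annotation data.frame with bin_id and ko_id columns.
#' @param bin_ids All bin ids (bins without annotations get an empty file).
#' @param out_dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_kegg_mapper <- function(annotations, bin_ids, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(out_dir, paste0(bin_ids, ".kegg.tsv")), bin_ids)
  for (b in bin_ids) {
    a <- annotations[annotations$bin_id == b & !is.na(annotations$ko_id), ,
                     drop = FALSE]
    writeLines(sprintf("%s\t%s", a$orf_id, a$ko_id), paths[[b]])
  }
  invisible(paths)
}

#' Write a per-bin gene overview
#'
#' The per-bin analogue of [write_overview()]: hit counts restricted to one
#' bin.
#'
#' @param annotations Annotation data.frame.
#' @param cycle_genes Key-gene table as in [summarize_genes()].
#' @param bin_id The bin.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_bin_overview <- function(annotations, cycle_genes, bin_id, path) {
  a <- annotations[annotations$bin_id == bin_id, , drop = FALSE]
  rows <- summarize_genes(a, cycle_genes, coverage = NULL)
  rows$o_depth_pct <- NULL
  rows$n_bins <- NULL
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
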