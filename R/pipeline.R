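#' Build a clustered profile-HMM database
#'
#' Runs the full database-construction pipeline over a directory of KO-keyed
#' protein FASTA files: per-KO length filtering around the family mean,
#' de-replication, KO retention, greedy identity/coverage clustering,
#' small-cluster pooling, profile building (MAFFT + hmmbuild), and assembly
#' into nutrient-cycle subsets. Failures are isolated per KO; a failed KO is
#' recorded and the run continues.
#'
#' @param ko_dir Directory of `<KO>.faa` protein FASTA files.
#' @param cycles_path Cycle configuration file (see [read_cycle_config()]).
#' @param out_dir Output directory: `profiles/<Subset>.hmm` flat files,
#'   `manifest.tsv` (one row per profile) and `manifest.json` (summary).
#' @param cfg A [builder_config()].
#' @return Invisibly, the database summary list (`profiles`, `manifest`,
#'   `discarded`, `failed`, `missing`).
#' @export
run_build <- function(ko_dir, cycles_path, out_dir, cfg = builder_config()) {
  families <- read_ko_dir(ko_dir)
  cycle_config <- read_cycle_config(cycles_path)
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  staging <- tempfile("profiles")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  records <- list()
  hmm_stage <- character(0)
  discarded <- character(0)
  failed <- character(0)
  for (ko in names(families)) {
    res <- tryCatch({
      fam <- length_filter(families[[ko]], cfg)
      fam <- dereplicate(fam)
      if (!ko_retention(fam, cfg)) {
        discarded <- c(discarded, ko)
        NULL
      } else {
        clusters <- merge_small_clusters(cluster_family(fam, cfg), cfg)
        recs <- list()
        for (ci in seq_along(clusters)) {
          cl <- clusters[[ci]]
          if (length(cl$members) < 2) {
            warning("KO ", ko, ": pooled cluster with < 2 members dropped")
            next
          }
          stage <- file.path(staging, sprintf("%s_c%d.hmm", ko, ci - 1L))
          rec <- build_profile(cl, ci - 1L, stage)
          recs[[length(recs) + 1L]] <- rec
          hmm_stage[rec$profile_id] <- stage
        }
        recs
      }
    }, error = function(e) {
      warning("KO ", ko, " failed: ", conditionMessage(e))
      failed <<- c(failed, ko)
      NULL
    })
    if (!is.null(res)) records <- c(records, res)
  }
  if (length(records) == 0) stop("no profiles could be built from ", ko_dir)
  profiles <- do.call(rbind, records)
  asm <- assemble_subsets(profiles, cycle_config)
  profiles <- asm$profiles
  # concatenate staged profiles into one flat file per subset
  subset_files <- character(0)
  for (s in unique(profiles$subset)) {
    path <- file.path(out_dir, "profiles",
                      paste0(gsub(" ", "_", s), ".hmm"))
    file.create(path)
    for (pid in profiles$profile_id[profiles$subset == s])
      file.append(path, hmm_stage[[pid]])
    subset_files[s] <- path
  }
  # order rows by declared cycle order, then NonKey
  subset_order <- c(intersect(c(names(cycle_config), "NonKey"),
                              unique(profiles$subset)))
  profiles <- profiles[order(match(profiles$subset, subset_order),
                             profiles$ko_id, profiles$profile_id), ]
  rownames(profiles) <- NULL
  utils::write.table(profiles, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(subsets = asm$manifest, n_profiles = nrow(profiles),
                  discarded_kos = discarded, failed_kos = failed,
                  missing_kos = asm$missing, config = config_as_list(cfg))
  jsonlite::write_json(summary, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, manifest = asm$manifest,
                 discarded = discarded, failed = failed,
                 missing = asm$missing, dir = out_dir))
}

#' Load a profile database built by [run_build()]
#'
#' @param db_dir Database directory.
#' @return A list with `profiles` (the manifest table) and `hmm_files`
#'   (named subset -> flat-file path).
#' @export
load_profile_db <- function(db_dir) {
  manifest <- file.path(db_dir, "manifest.tsv")
  if (!file.exists(manifest))
    stop("no database manifest at ", manifest,
         "; run run_build() (or the build subcommand) first")
  profiles <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  subsets <- unique(profiles$subset)
  hmm_files <- setNames(
    file.path(db_dir, "profiles", paste0(gsub(" ", "_", subsets), ".hmm")),
    subsets)
  miss <- !file.exists(hmm_files)
  if (any(miss))
    stop("missing profile flat file(s): ",
         paste(hmm_files[miss], collapse = ", "))
  list(profiles = profiles, hmm_files = as.list(hmm_files), dir = db_dir)
}

# Key-gene table (cycle, gene_label, ko_id) in manifest order.
db_cycle_genes <- function(db) {
  p <- db$profiles[db$profiles$is_key_gene, , drop = FALSE]
  g <- unique(p[c("subset", "gene_label", "ko_id")])
  data.frame(cycle = g$subset, gene_label = g$gene_label,
             ko_id = ifelse(grepl("^K[0-9]{5}$", g$ko_id), g$ko_id,
                            NA_character_),
             stringsAsFactors = FALSE)
}

#' Annotate a directory of bins against a profile database
#'
#' The full gene-centric pipeline: bin discovery and size-based mode
#' selection, per-bin gene calling, two-phase HMM annotation with tiered
#' triage, and aggregation into per-gene/per-cycle overviews with
#' coverage-weighted abundance. Per-bin failures are isolated: a failing bin
#' is recorded in the run manifest and the remaining bins complete.
#'
#' @param in_dir Directory of bin FASTA files (an unbinned assembly is simply
#'   one more bin).
#' @param db_dir Database directory from [run_build()].
#' @param out_dir Output directory.
#' @param coverage_path Optional per-bin coverage TSV.
#' @param cfg A [run_config()].
#' @param process_defs Optional process definitions ([read_process_defs()]);
#'   when given, a process-level roll-up TSV is written.
#' @param user_hmm Optional character vector of user HMM flat files.
#' @param user_as_key Treat user profiles as an extra key subset (default
#'   `TRUE`) or merge into NonKey.
#' @param rrna_adapter Optional rRNA classifier command (see [detect_rrna()]).
#' @return Invisibly: `annotations`, `orfs`, `gene_rows`, `process_rows`,
#'   `bin_status`, `manifest`.
#' @export
run_annotate <- function(in_dir, db_dir, out_dir, coverage_path = NULL,
                         cfg = run_config(), process_defs = NULL,
                         user_hmm = character(0), user_as_key = TRUE,
                         rrna_adapter = NULL) {
  db <- load_profile_db(db_dir)
  db <- load_user_profiles(db, user_hmm, as_key = user_as_key)
  bins <- scan_bins(in_dir, cfg$intake)
  coverage <- NULL
  if (!is.null(coverage_path))
    coverage <- load_coverage(coverage_path, names(bins))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_ann <- list()
  all_orfs <- list()
  bin_status <- list()
  for (bid in names(bins)) {
    bin <- bins[[bid]]
    bin_dir <- file.path(out_dir, "bins", bid)
    status <- tryCatch({
      called <- call_genes(bin, bin_dir)
      orfs <- called$orfs
      partial <- orfs$orf_id[orfs$partial5 | orfs$partial3]
      res <- annotate_two_phase(called$proteins, db, cfg$triage,
                                cfg$run_scope, partial_orfs = partial)
      ann <- res$annotations
      ann$bin_id <- if (nrow(ann)) bid else character(0)
      write_hit_tables(res$all_hits, ann,
                       file.path(bin_dir, paste0(bid, ".all_hits.tsv")),
                       file.path(bin_dir, paste0(bid, ".best_hits.tsv")))
      write_gff3(orfs, ann, file.path(bin_dir, paste0(bid, ".gff3")))
      write_genbank(bin, orfs, ann, file.path(bin_dir, paste0(bid, ".gbk")))
      write_bin_overview(ann, db_cycle_genes(db), bid,
                         file.path(bin_dir, paste0(bid, ".overview.tsv")))
      if (!is.null(rrna_adapter) &&
          auxiliary_enabled(bin$total_len, cfg$intake)) {
        feats <- detect_rrna(bin, rrna_adapter)
        if (length(feats))
          Biostrings::writeXStringSet(
            feats, file.path(bin_dir, paste0(bid, ".rrna.fna")))
      }
      all_ann[[bid]] <- ann
      all_orfs[[bid]] <- orfs
      list(status = "ok", n_orfs = nrow(orfs), n_annotated = nrow(ann),
           mode = bin$mode)
    }, error = function(e) {
      warning("bin ", bid, " failed: ", conditionMessage(e))
      list(status = "failed", error = conditionMessage(e), mode = bin$mode)
    })
    bin_status[[bid]] <- status
  }
  annotations <- do.call(rbind, unname(all_ann))
  if (is.null(annotations)) {
    annotations <- cbind(empty_hits(), data.frame(
      small_protein = logical(0), ko_id = character(0),
      gene_label = character(0), cycle = character(0),
      bin_id = character(0), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, unname(all_orfs))
  cycle_genes <- db_cycle_genes(db)
  key_ann <- annotations[annotations$cycle %in% key_subset_names(), ,
                         drop = FALSE]
  gene_rows <- summarize_genes(key_ann, cycle_genes, coverage)
  write_overview(gene_rows, file.path(out_dir, "overview.tsv"))
  write_krona_text(gene_rows, file.path(out_dir, "krona.txt"))
  write_kegg_mapper(annotations, names(bins), file.path(out_dir, "kegg"))
  process_rows <- NULL
  if (!is.null(process_defs)) {
    process_rows <- rollup_process(gene_rows, process_defs, key_ann, coverage)
    utils::write.table(process_rows, file.path(out_dir, "processes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    config = config_as_list(cfg), db = db_dir, input = in_dir,
    coverage = if (is.null(coverage_path)) NA else coverage_path,
    bins = bin_status,
    totals = list(n_bins = length(bins),
                  n_failed = sum(vapply(bin_status, function(s)
                    s$status == "failed", logical(1))),
                  n_orfs = if (is.null(orfs)) 0L else nrow(orfs),
                  n_annotations = nrow(annotations)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotations = annotations, orfs = orfs,
                 gene_rows = gene_rows, process_rows = process_rows,
                 bin_status = bin_status, manifest = manifest))
}
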