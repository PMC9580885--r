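#' Database-builder configuration
#'
#' Operating constants for the profile database builder. Defaults implement the
#' published pipeline: per-KO length filtering to the 60--150% band around the
#' family mean, a minimum of three unique sequences per retained KO, greedy
#' clustering at 50% identity over 70% coverage, and pooling of clusters with
#' fewer than three members.
#'
#' @param len_lo_frac Lower length bound as a fraction of the family mean
#'   length (default 0.60). Sequences shorter than this are discarded.
#' @param len_hi_frac Upper length bound fraction (default 1.50).
#' @param min_unique_seqs Minimum number of unique sequences for a KO to be
#'   retained, and the fallback threshold for the length filter (default 3).
#' @param min_cluster_size Minimum members for a standalone cluster; smaller
#'   clusters are pooled (default 3).
#' @param cluster_min_id Minimum fractional identity of a member to its cluster
#'   representative (default 0.5).
#' @param cluster_min_cov Minimum alignment coverage of the shorter sequence
#'   (default 0.7).
#' @return A validated list of class `builder_config`.
#' @export
#' @examples
#' builder_config()
builder_config <- function(len_lo_frac = 0.60, len_hi_frac = 1.50,
                           min_unique_seqs = 3L, min_cluster_size = 3L,
                           cluster_min_id = 0.5, cluster_min_cov = 0.7) {
  stopifnot(len_lo_frac > 0, len_lo_frac < 1, len_hi_frac > 1,
            min_unique_seqs >= 2, min_cluster_size >= 1,
            cluster_min_id > 0, cluster_min_id <= 1,
            cluster_min_cov > 0, cluster_min_cov <= 1)
  structure(list(len_lo_frac = len_lo_frac, len_hi_frac = len_hi_frac,
                 min_unique_seqs = as.integer(min_unique_seqs),
                 min_cluster_size = as.integer(min_cluster_size),
                 cluster_min_id = cluster_min_id,
                 cluster_min_cov = cluster_min_cov),
            class = "builder_config")
}

#' Genome-intake configuration
#'
#' Bin-size band used to decide the gene-calling mode. Bins whose total length
#' falls inside `[min_single_bp, max_single_bp]` are treated as a single
#' trustworthy genome (gene calling in single mode); anything smaller or larger
#' is processed in meta mode. The upper bound also gates optional, slow
#' auxiliary analyses. Defaults: 0.5 Mbp (the minimum the gene caller needs in
#' single mode) and 15 Mbp (just above the largest known bacterial genome).
#' Both boundaries are inclusive.
#'
#' @param min_single_bp Lower bound in bp for single mode (default 500000).
#' @param max_single_bp Upper bound in bp (default 15000000).
#' @return A validated list of class `intake_config`.
#' @export
intake_config <- function(min_single_bp = 500000, max_single_bp = 15000000) {
  stopifnot(min_single_bp > 0, min_single_bp < max_single_bp)
  structure(list(min_single_bp = min_single_bp, max_single_bp = max_single_bp),
            class = "intake_config")
}

#' Hit-triage configuration
#'
#' The tiered e-value and size-difference thresholds applied to raw HMM hits.
#' Three e-values are in play: `e_prefilter` (1e-06) is the reporting ceiling
#' for every search and the only e-value applied to small proteins;
#' `e_key` (1e-100) applies when only the key-gene subsets are searched, where
#' the small database makes false positives likely; `e_full` (1e-50) applies
#' when the full metabolic database is included, where the presence of closer
#' homologs lowers the false-positive risk. Hits whose query length differs
#' from the profile model length by more than `size_frac` (20%) are removed as
#' motif-only matches; ORFs under `small_aa` (200) residues use the relaxed
#' `size_frac_small` (30%) bound instead, because short sequences cannot
#' accumulate enough bit score for the stringent tiers.
#'
#' @param e_prefilter Reporting e-value ceiling for raw hits (default 1e-06).
#' @param e_key Ceiling for key-gene-only runs (default 1e-100).
#' @param e_full Ceiling when the full database is searched (default 1e-50).
#' @param small_aa Small-protein threshold in residues (default 200).
#' @param size_frac Maximum fractional query/model length difference
#'   (default 0.20).
#' @param size_frac_small Small-protein size bound (default 0.30).
#' @return A validated list of class `triage_config`.
#' @export
#' @examples
#' triage_config()
#' triage_config(e_key = 1e-80) # relax the key-only tier
triage_config <- function(e_prefilter = 1e-06, e_key = 1e-100, e_full = 1e-50,
                          small_aa = 200L, size_frac = 0.20,
                          size_frac_small = 0.30) {
  stopifnot(e_key <= e_full, e_full <= e_prefilter, small_aa > 0,
            size_frac > 0, size_frac <= size_frac_small, size_frac_small < 1)
  structure(list(e_prefilter = e_prefilter, e_key = e_key, e_full = e_full,
                 small_aa = as.integer(small_aa), size_frac = size_frac,
                 size_frac_small = size_frac_small),
            class = "triage_config")
}

#' Composite run configuration
#'
#' Bundles the per-stage configurations with run-level options. Every default
#' equals the corresponding per-stage default and is echoed into the run
#' manifest so the effective values are always on record.
#'
#' @param builder A [builder_config()].
#' @param intake An [intake_config()].
#' @param triage A [triage_config()].
#' @param run_scope `"full"` (key subsets then the full metabolic database) or
#'   `"key_only"`.
#' @param threads Worker count; parallelism is at bin granularity and never
#'   changes results (outputs are merged in canonical bin/ORF order).
#' @param seed Integer seed for any randomized step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(builder = builder_config(), intake = intake_config(),
                       triage = triage_config(),
                       run_scope = c("full", "key_only"),
                       threads = 1L, seed = 1L) {
  run_scope <- match.arg(run_scope)
  stopifnot(inherits(builder, "builder_config"),
            inherits(intake, "intake_config"),
            inherits(triage, "triage_config"), threads >= 1)
  structure(list(builder = builder, intake = intake, triage = triage,
                 run_scope = run_scope, threads = as.integer(threads),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Flatten a config for the run manifest / log.
config_as_list <- function(cfg) {
  if (inherits(cfg, "run_config")) {
    c(lapply(cfg[c("builder", "intake", "triage")], unclass),
      cfg[c("run_scope", "threads", "seed")])
  } else {
    unclass(cfg)
  }
}

#' The eight key nutrient-cycle subset names
#'
#' Profiles flagged as key genes live in one of these subsets; everything else
#' goes to the automatic `NonKey` subset.
#' @return Character vector of subset names.
#' @export
key_subset_names <- function() {
  c("Nitrogen", "Methane", "Carbon fixation", "Hydrogenases", "C1",
    "Sulfur", "Oxidative phosphorylation", "Miscellaneous")
}
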