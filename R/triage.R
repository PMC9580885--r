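#' Prefilter raw hits on the reporting e-value
#'
#' Retains hits at or below the prefilter ceiling (1e-06 by default) -- the
#' weakest similarity the pipeline ever accepts -- preserving input order.
#' The search engine already reports at this ceiling; the explicit filter
#' makes the contract hold for hits from any source (e.g. user-parsed tables).
#'
#' @param hits Raw-hit data.frame (see [hmm_search()]).
#' @param cfg A [triage_config()].
#' @return The surviving rows of `hits`.
#' @export
prefilter <- function(hits, cfg = triage_config()) {
  hits[hits$evalue <= cfg$e_prefilter, , drop = FALSE]
}

#' Query/model size compatibility
#'
#' A hit survives only when the query ORF and the profile model length agree
#' within `max_frac`: `|query_len - target_len| / target_len <= max_frac`
#' (ceiling inclusive). Hits failing this clearly differ in size and merely
#' share sequence motifs.
#'
#' @param query_len ORF length in residues (vectorized).
#' @param target_len Profile model length in residues.
#' @param max_frac Maximum fractional difference (e.g. 0.20).
#' @return Logical vector.
#' @export
#' @examples
#' size_compatible(80, 100, 0.20)   # TRUE: exactly at the ceiling
#' size_compatible(79, 100, 0.20)   # FALSE
size_compatible <- function(query_len, target_len, max_frac) {
  stopifnot(all(query_len > 0), all(target_len > 0))
  abs(query_len - target_len) / target_len <= max_frac
}

#' Apply the tiered e-value and size filters
#'
#' For ORFs of at least `small_aa` residues, a hit survives when its e-value
#' passes the scope tier (`e_key` for key-only runs, `e_full` otherwise) and
#' its size difference is within `size_frac`. ORFs under `small_aa` residues
#' cannot build up enough bit score for those tiers, so they take the
#' small-protein path: only the prefilter e-value applies, with the relaxed
#' `size_frac_small` bound; survivors are flagged `small_protein`. ORFs
#' flagged partial at a contig edge are exempt from the upper size bound
#' (the lower bound still applies).
#'
#' @param hits Prefiltered raw-hit data.frame.
#' @param cfg A [triage_config()].
#' @param run_scope `"key_only"` or `"full"`; selects the stringent tier.
#' @param partial_orfs Optional character vector of orf_ids flagged partial.
#' @return The surviving rows with a logical `small_protein` column added.
#' @export
triage_hits <- function(hits, cfg = triage_config(),
                        run_scope = c("full", "key_only"),
                        partial_orfs = character(0)) {
  run_scope <- match.arg(run_scope)
  if (nrow(hits) == 0) {
    hits$small_protein <- logical(0)
    return(hits)
  }
  tier <- if (run_scope == "key_only") cfg$e_key else cfg$e_full
  small <- hits$query_len < cfg$small_aa
  frac <- ifelse(small, cfg$size_frac_small, cfg$size_frac)
  is_partial <- hits$orf_id %in% partial_orfs
  lower_ok <- hits$query_len >= hits$target_len * (1 - frac)
  upper_ok <- hits$query_len <= hits$target_len * (1 + frac) | is_partial
  size_ok <- lower_ok & upper_ok
  e_ok <- ifelse(small, hits$evalue <= cfg$e_prefilter, hits$evalue <= tier)
  out <- hits[e_ok & size_ok, , drop = FALSE]
  out$small_protein <- small[e_ok & size_ok]
  out
}

#' Resolve the best hit per ORF
#'
#' After all databases are queried, each ORF keeps the hit with the highest
#' bit score; ties break on lower e-value, then lexicographic profile id, so
#' the result is invariant under input reordering.
#'
#' @param hits Triaged hit data.frame.
#' @param profile_meta Optional database profile table (profile_id, ko_id,
#'   gene_label, subset); when given, those columns are joined onto the
#'   annotations.
#' @return One-row-per-ORF annotation data.frame, ordered by orf_id.
#' @export
select_best <- function(hits, profile_meta = NULL) {
  if (nrow(hits) > 0) {
    ord <- order(hits$orf_id, -hits$bitscore, hits$evalue, hits$profile_id)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$orf_id), , drop = FALSE]
  }
  if (!is.null(profile_meta)) {
    idx <- match(hits$profile_id, profile_meta$profile_id)
    hits$ko_id <- as.character(
      ifelse(grepl("^K[0-9]{5}$", profile_meta$ko_id[idx]),
             profile_meta$ko_id[idx], NA_character_))
    hits$gene_label <- profile_meta$gene_label[idx]
    hits$cycle <- profile_meta$subset[idx]
  }
  rownames(hits) <- NULL
  hits
}

#' Two-phase annotation of one bin's ORFs
#'
#' Phase 1 searches all ORFs against every key subset jointly; hits compete by
#' bit score after triage at the run-scope stringency. ORFs annotated in
#' phase 1 are final and never revisited. Phase 2 (skipped in key-only runs)
#' searches only the remaining ORFs against the non-key remainder of the
#' metabolic database and annotates them the same way.
#'
#' @param proteins Named `AAStringSet` of the bin's ORF translations.
#' @param db A profile database from [load_profile_db()].
#' @param cfg A [triage_config()].
#' @param run_scope `"full"` or `"key_only"`.
#' @param partial_orfs orf_ids with a partial flag (see [triage_hits()]).
#' @param search_fun Search adapter with the signature of [hmm_search()];
#'   injectable for testing.
#' @return A list with `annotations` (best hit per annotated ORF) and
#'   `all_hits` (every prefiltered raw hit from both phases).
#' @export
annotate_two_phase <- function(proteins, db, cfg = triage_config(),
                               run_scope = c("full", "key_only"),
                               partial_orfs = character(0),
                               search_fun = hmm_search) {
  run_scope <- match.arg(run_scope)
  key_sets <- setdiff(names(db$hmm_files), "NonKey")
  raw1 <- do.call(rbind, lapply(key_sets, function(s)
    search_fun(proteins, db$hmm_files[[s]], db$profiles, cfg, phase = "key")))
  if (is.null(raw1)) raw1 <- empty_hits()
  tri1 <- triage_hits(prefilter(raw1, cfg), cfg, run_scope, partial_orfs)
  ann1 <- select_best(tri1, db$profiles)
  all_hits <- raw1
  ann2 <- NULL
  if (run_scope == "full" && "NonKey" %in% names(db$hmm_files)) {
    rest <- proteins[!names(proteins) %in% ann1$orf_id]
    raw2 <- search_fun(rest, db$hmm_files[["NonKey"]], db$profiles, cfg,
                       phase = "full")
    tri2 <- triage_hits(prefilter(raw2, cfg), cfg, run_scope, partial_orfs)
    ann2 <- select_best(tri2, db$profiles)
    all_hits <- rbind(all_hits, raw2)
  }
  ann <- rbind(ann1, ann2)
  ann <- ann[order(ann$orf_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotations = ann, all_hits = all_hits)
}

empty_hits <- function() {
  data.frame(orf_id = character(0), profile_id = character(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_len = integer(0), target_len = integer(0),
             phase = character(0), stringsAsFactors = FALSE)
}

#' Add user-supplied HMM profiles to a database
#'
#' User profiles (HMMER3 flat files) are either wrapped as an extra key
#' subset named `User` -- searched in phase 1 at key-gene stringency -- or
#' merged into the `NonKey` remainder. Model lengths are taken from the
#' profile headers; a file without parseable headers is fatal.
#'
#' @param db A database from [load_profile_db()].
#' @param paths Character vector of HMM flat files (empty = no-op).
#' @param as_key Wrap as a key subset (`TRUE`, default) or merge into NonKey.
#' @return The augmented database.
#' @export
load_user_profiles <- function(db, paths, as_key = TRUE) {
  if (length(paths) == 0) return(db)
  recs <- do.call(rbind, lapply(paths, parse_hmm_headers))
  if (anyDuplicated(c(db$profiles$profile_id, recs$profile_id)))
    stop("user profile name collides with the database")
  subset <- if (as_key) "User" else "NonKey"
  add <- data.frame(profile_id = recs$profile_id, ko_id = recs$profile_id,
                    gene_label = recs$profile_id,
                    target_len = recs$target_len, n_members = NA_integer_,
                    pooled = FALSE, subset = subset, is_key_gene = as_key,
                    stringsAsFactors = FALSE)
  db$profiles <- rbind(db$profiles[names(add)], add)
  merged <- tempfile(paste0("user_", subset), fileext = ".hmm")
  existing <- db$hmm_files[[subset]]
  file.create(merged)
  if (!is.null(existing)) file.append(merged, existing)
  for (p in paths) file.append(merged, p)
  db$hmm_files[[subset]] <- merged
  db
}
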