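# Shared fixtures, built lazily once per test session. The community preset
# and its database back several test files and the acceptance suite; caching
# keeps the run inside a sensible budget without changing any result.

fx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(fx_cache[[name]])) assign(name, force(expr), envir = fx_cache)
  get(name, envir = fx_cache)
}

fixture_community <- function() cached("community", {
  dir <- file.path(tempdir(), "cs_fx_community")
  fixture_preset(dir, seed = 42L, preset = "community")
})

fixture_db_dir <- function() cached("db_dir", {
  fx <- fixture_community()
  dbdir <- file.path(tempdir(), "cs_fx_db")
  run_build(fx$ko_dir, fx$cycles_path, dbdir)
  dbdir
})

fixture_db <- function() load_profile_db(fixture_db_dir())

# One full default-threshold annotation run of the fixture community.
fixture_run <- function() cached("run", {
  fx <- fixture_community()
  out <- file.path(tempdir(), "cs_fx_out")
  res <- run_annotate(fx$bins_dir, fixture_db_dir(), out,
                      coverage_path = fx$coverage_path)
  list(fx = fx, res = res, out = out)
})

# Small abstract families for clustering unit tests (no engines involved).
fixture_two_groups <- function() cached("two_groups", {
  f1 <- make_family(family_spec("KG1", n_members = 3, base_length = 200,
                                divergence = 0.05, indel_rate = 0,
                                seed = 11))$family
  f2 <- make_family(family_spec("KG2", n_members = 3, base_length = 200,
                                divergence = 0.05, indel_rate = 0,
                                seed = 22))$family
  ko_family("KMIX", c(f1$members, f2$members))
})

# Stub two-phase search machinery: a fake database plus a search function
# that serves canned hits, for exercising the phase logic without HMMER.
stub_db <- function() {
  profiles <- data.frame(
    profile_id = c("K00370_c0", "K99999_c0"),
    ko_id = c("K00370", "K99999"),
    gene_label = c("narG", "mysA"),
    target_len = c(300L, 300L),
    n_members = 3L, pooled = FALSE,
    subset = c("Nitrogen", "NonKey"),
    is_key_gene = c(TRUE, FALSE), stringsAsFactors = FALSE)
  list(profiles = profiles,
       hmm_files = list(Nitrogen = "STUB_KEY", NonKey = "STUB_NONKEY"))
}

stub_search <- function(hit_map) {
  function(proteins, hmm_path, profile_meta, cfg, phase) {
    h <- hit_map[[hmm_path]]
    if (is.null(h)) h <- cyclescan:::empty_hits()
    h <- h[h$orf_id %in% names(proteins), , drop = FALSE]
    if (nrow(h)) h$phase <- phase
    h
  }
}

stub_proteins <- function(ids, len = 300L) {
  Biostrings::AAStringSet(setNames(
    vapply(ids, function(i) paste(rep("M", len), collapse = ""),
           character(1)), ids))
}

make_hit <- function(orf, profile, evalue, bitscore, qlen = 300L,
                     tlen = 300L, phase = "key") {
  data.frame(orf_id = orf, profile_id = profile, evalue = evalue,
             bitscore = bitscore, query_len = as.integer(qlen),
             target_len = as.integer(tlen), phase = phase,
             stringsAsFactors = FALSE)
}
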