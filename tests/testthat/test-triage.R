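test_that("prefilter ceiling is inclusive and order-preserving", {
  hits <- rbind(make_hit("o1", "P1", 1e-7, 100),
                make_hit("o1", "P2", 1e-5, 100),
                make_hit("o2", "P3", 1e-6, 100))
  out <- prefilter(hits)
  expect_equal(out$evalue, c(1e-7, 1e-6))
  expect_equal(nrow(prefilter(hits[0, ])), 0L)
  ok <- rbind(make_hit("o1", "P1", 1e-8, 10), make_hit("o2", "P2", 1e-9, 10))
  expect_identical(prefilter(ok), ok)
})

test_that("size compatibility is |q - t| / t with an inclusive ceiling", {
  expect_true(size_compatible(100, 100, 0.20))
  expect_false(size_compatible(79, 100, 0.20))
  expect_true(size_compatible(80, 100, 0.20))
  expect_true(size_compatible(120, 100, 0.20))
  expect_false(size_compatible(121, 100, 0.20))
  expect_true(size_compatible(130, 100, 0.30))
})

test_that("triage applies the scope tier to large ORFs", {
  h <- make_hit("o1", "P1", 1e-60, 200, qlen = 300, tlen = 300)
  expect_equal(nrow(triage_hits(h, run_scope = "key_only")), 0L)
  out <- triage_hits(h, run_scope = "full")
  expect_equal(nrow(out), 1L)
  expect_false(out$small_protein)
  # at the key tier, 1e-100 passes (inclusive)
  h2 <- make_hit("o1", "P1", 1e-100, 500, qlen = 300, tlen = 300)
  expect_equal(nrow(triage_hits(h2, run_scope = "key_only")), 1L)
})

test_that("small proteins use the prefilter e-value and the 30% size bound", {
  # 150 aa, e-value far above the tiers but under the prefilter,
  # size difference 25%: survives only via the small-protein path
  h <- make_hit("o1", "P1", 1e-8, 40, qlen = 150, tlen = 200)
  out <- triage_hits(h, run_scope = "full")
  expect_equal(nrow(out), 1L)
  expect_true(out$small_protein)
  # but the global prefilter still applies
  h2 <- make_hit("o1", "P1", 1e-5, 40, qlen = 150, tlen = 150)
  expect_equal(nrow(triage_hits(prefilter(h2), run_scope = "full")), 0L)
  # and the 30% bound is a real ceiling
  h3 <- make_hit("o1", "P1", 1e-8, 40, qlen = 130, tlen = 200)
  expect_equal(nrow(triage_hits(h3, run_scope = "full")), 0L)
})

test_that("partial ORFs are exempt from the upper size bound only", {
  # query 30% longer than the model: dropped unless flagged partial
  h <- make_hit("o1", "P1", 1e-60, 200, qlen = 390, tlen = 300)
  expect_equal(nrow(triage_hits(h, run_scope = "full")), 0L)
  expect_equal(nrow(triage_hits(h, run_scope = "full",
                                partial_orfs = "o1")), 1L)
  # the lower bound still applies to partials
  h2 <- make_hit("o1", "P1", 1e-60, 200, qlen = 210, tlen = 300)
  expect_equal(nrow(triage_hits(h2, run_scope = "full",
                                partial_orfs = "o1")), 0L)
})

test_that("best-hit selection follows bitscore, then e-value, then profile id", {
  h <- rbind(make_hit("o1", "P1", 1e-80, 300), make_hit("o1", "P2", 1e-90, 250))
  expect_equal(select_best(h)$profile_id, "P1")
  expect_equal(select_best(h[1, , drop = FALSE])$profile_id, "P1")
  tie <- rbind(make_hit("o1", "P1", 1e-60, 200), make_hit("o1", "P2", 1e-80, 200))
  expect_equal(select_best(tie)$profile_id, "P2")
  tie2 <- rbind(make_hit("o1", "PB", 1e-80, 200), make_hit("o1", "PA", 1e-80, 200))
  expect_equal(select_best(tie2)$profile_id, "PA")
})

test_that("triage + selection agree with the brute-force oracle and are
           deterministic under reordering", {
  cfg <- triage_config()
  for (seed in 1:200) {
    hits <- random_hits(seed)
    scope <- if (seed %% 2 == 0) "full" else "key_only"
    got <- select_best(triage_hits(prefilter(hits, cfg), cfg, scope))
    want <- oracle_annotate(hits, cfg, scope)
    cols <- c("orf_id", "profile_id", "evalue", "bitscore")
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[cols], want[cols], ignore_attr = TRUE)
    }
    # shuffling the input changes nothing
    perm <- withr::with_seed(seed + 1000, sample(nrow(hits)))
    got2 <- select_best(triage_hits(prefilter(hits[perm, ], cfg), cfg, scope))
    expect_equal(got2[cols], got[cols], ignore_attr = TRUE)
  }
})

test_that("relaxing the tier from key to full only adds hits", {
  cfg <- triage_config()
  for (seed in 201:260) {
    hits <- prefilter(random_hits(seed), cfg)
    key_ids <- with(triage_hits(hits, cfg, "key_only"),
                    paste(orf_id, profile_id, evalue))
    full_ids <- with(triage_hits(hits, cfg, "full"),
                     paste(orf_id, profile_id, evalue))
    expect_true(all(key_ids %in% full_ids))
  }
})

test_that("two-phase annotation: key hits are final, non-key fills the rest", {
  db <- stub_db()
  hit_map <- list(
    STUB_KEY = make_hit("orf1", "K00370_c0", 1e-120, 400),
    STUB_NONKEY = rbind(make_hit("orf1", "K99999_c0", 1e-150, 500),
                        make_hit("orf2", "K99999_c0", 1e-60, 220)))
  prots <- stub_proteins(c("orf1", "orf2", "orf3"))
  res <- annotate_two_phase(prots, db, run_scope = "full",
                            search_fun = stub_search(hit_map))
  ann <- res$annotations
  expect_equal(nrow(ann), 2L)
  # orf1 keeps its phase-1 key annotation despite the stronger non-key hit
  expect_equal(ann$profile_id[ann$orf_id == "orf1"], "K00370_c0")
  expect_equal(ann$cycle[ann$orf_id == "orf1"], "Nitrogen")
  expect_equal(ann$phase[ann$orf_id == "orf2"], "full")
  expect_false("orf3" %in% ann$orf_id)
  expect_false(anyDuplicated(ann$orf_id) > 0)

  # key-only scope never annotates the non-key-only ORF
  res_key <- annotate_two_phase(prots, db, run_scope = "key_only",
                                search_fun = stub_search(hit_map))
  expect_equal(res_key$annotations$orf_id, "orf1")

  # phase precedence: dropping the non-key database changes no key annotation
  db_nokey <- db
  db_nokey$hmm_files$NonKey <- NULL
  res_drop <- annotate_two_phase(prots, db_nokey, run_scope = "full",
                                 search_fun = stub_search(hit_map))
  expect_equal(res_drop$annotations[res_drop$annotations$phase == "key", ],
               ann[ann$phase == "key", ], ignore_attr = TRUE)
})

test_that("phase precedence and uniqueness hold over randomized two-phase runs", {
  db <- stub_db()
  cfg <- triage_config()
  for (seed in 301:500) {
    h <- withr::with_seed(seed, {
      n1 <- sample.int(12L, 1L)
      n2 <- sample.int(12L, 1L)
      orfs1 <- sample(sprintf("orf%02d", 1:6), n1, replace = TRUE)
      orfs2 <- sample(sprintf("orf%02d", 1:6), n2, replace = TRUE)
      list(
        STUB_KEY = make_hit(orfs1, "K00370_c0",
                            10^-sample(c(4:8, 45:130), n1, TRUE),
                            sample(seq(50, 500, 25), n1, TRUE),
                            qlen = sample(c(150, 300), n1, TRUE)),
        STUB_NONKEY = make_hit(orfs2, "K99999_c0",
                               10^-sample(c(4:8, 45:130), n2, TRUE),
                               sample(seq(50, 500, 25), n2, TRUE),
                               qlen = sample(c(150, 300), n2, TRUE)))
    })
    prots <- stub_proteins(sprintf("orf%02d", 1:6))
    full <- annotate_two_phase(prots, db, cfg, "full",
                               search_fun = stub_search(h))$annotations
    expect_lte(nrow(full), 6L)
    expect_false(anyDuplicated(full$orf_id) > 0)
    db2 <- db
    db2$hmm_files$NonKey <- NULL
    keyonly_db <- annotate_two_phase(prots, db2, cfg, "full",
                                     search_fun = stub_search(h))$annotations
    expect_equal(keyonly_db, full[full$phase == "key", ],
                 ignore_attr = TRUE)
  }
})

test_that("user profiles join as an extra key subset or merge into NonKey", {
  skip_if(Sys.which("hmmbuild") == "" || Sys.which("mafft") == "")
  db <- fixture_db()
  fam <- make_family(family_spec("USERX", n_members = 4, base_length = 150,
                                 divergence = 0.05, seed = 9))$family
  cl <- cluster_family(fam)[[1]]
  user_hmm <- tempfile(fileext = ".hmm")
  build_profile(cl, 0L, user_hmm)

  db1 <- load_user_profiles(db, user_hmm, as_key = TRUE)
  expect_true("User" %in% names(db1$hmm_files))
  expect_true("USERX_c0" %in% db1$profiles$profile_id)
  expect_true(db1$profiles$is_key_gene[db1$profiles$profile_id == "USERX_c0"])
  expect_equal(nrow(db1$profiles), nrow(db$profiles) + 1L)

  db2 <- load_user_profiles(db, user_hmm, as_key = FALSE)
  expect_equal(db2$profiles$subset[db2$profiles$profile_id == "USERX_c0"],
               "NonKey")

  expect_identical(load_user_profiles(db, character(0)), db)

  garbage <- tempfile(fileext = ".hmm")
  writeLines("not a profile", garbage)
  expect_error(load_user_profiles(db, garbage), "parse")
})
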