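# Independent oracles, deliberately implemented without the package's own
# alignment or selection code paths.

# Plain Needleman-Wunsch with affine-free scoring (match 2, mismatch -1,
# gap -2): identity = matches / alignment columns, coverage = both-residue
# columns / shorter length. Used to verify the clustering contract.
nw_identity <- function(a, b, match = 2L, mismatch = -1L, gap = -2L) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  n <- length(A)
  m <- length(B)
  S <- matrix(0L, n + 1L, m + 1L)
  S[1, ] <- gap * 0:m
  S[, 1] <- gap * 0:n
  for (i in 1:n) {
    sub <- ifelse(A[i] == B, match, mismatch)
    row_prev <- S[i, ]
    row <- integer(m + 1L)
    row[1] <- gap * i
    for (j in 1:m)
      row[j + 1L] <- max(row_prev[j] + sub[j], row_prev[j + 1L] + gap,
                         row[j] + gap)
    S[i + 1L, ] <- row
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L; aligned <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1L, j + 1L] == S[i, j] + ifelse(A[i] == B[j], match, mismatch)) {
      matches <- matches + (A[i] == B[j])
      aligned <- aligned + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0 && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    cols <- cols + 1L
  }
  list(identity = matches / cols, coverage = aligned / min(n, m))
}

# Reference triage + best-hit selection, written as literal loops over the
# documented rules (no vectorized ordering tricks shared with the package).
oracle_annotate <- function(hits, cfg, run_scope, partial_orfs = character(0)) {
  tier <- if (run_scope == "key_only") cfg$e_key else cfg$e_full
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    small <- h$query_len < cfg$small_aa
    frac <- if (small) cfg$size_frac_small else cfg$size_frac
    e_ok <- if (small) h$evalue <= cfg$e_prefilter else h$evalue <= tier
    lo_ok <- h$query_len >= h$target_len * (1 - frac)
    hi_ok <- h$query_len <= h$target_len * (1 + frac) ||
      h$orf_id %in% partial_orfs
    keep[i] <- h$evalue <= cfg$e_prefilter && e_ok && lo_ok && hi_ok
  }
  surv <- hits[keep, , drop = FALSE]
  best <- list()
  for (orf in unique(surv$orf_id)) {
    cand <- surv[surv$orf_id == orf, , drop = FALSE]
    b <- cand[1, ]
    if (nrow(cand) > 1) {
      for (i in 2:nrow(cand)) {
        ci <- cand[i, ]
        better <- ci$bitscore > b$bitscore ||
          (ci$bitscore == b$bitscore && ci$evalue < b$evalue) ||
          (ci$bitscore == b$bitscore && ci$evalue == b$evalue &&
           ci$profile_id < b$profile_id)
        if (better) b <- ci
      }
    }
    best[[orf]] <- b
  }
  out <- do.call(rbind, best)
  if (is.null(out)) return(out)
  out <- out[order(out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random raw-hit instances with deliberate bitscore ties.
random_hits <- function(seed, max_hits = 50L) {
  withr::with_seed(seed, {
    n <- sample.int(max_hits, 1L)
    orf <- sample(sprintf("orf%02d", 1:8), n, replace = TRUE)
    prof <- sprintf("P%02d", sample.int(12L, n, replace = TRUE))
    qlen <- sample(60:400, n, replace = TRUE)
    data.frame(
      orf_id = orf, profile_id = prof,
      evalue = 10^-sample(c(3:8, 40:60, 90:130), n, replace = TRUE),
      bitscore = sample(seq(50, 300, by = 25), n, replace = TRUE),
      query_len = qlen,
      target_len = pmax(30L, qlen + sample(-120:120, n, replace = TRUE)),
      phase = "key", stringsAsFactors = FALSE)
  })
}
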