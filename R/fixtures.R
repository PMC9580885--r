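# Synthetic-data generator: motif-sharing protein families per KO, toy
# multi-bin communities with planted genes, and coverage tables, all
# deterministic from seeds so ground truth is exact.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic protein family
#'
#' @param ko_id Family identifier (KO number or gene label).
#' @param n_members Number of members to generate (default 8).
#' @param base_length Length of the family base sequence in residues
#'   (default 300).
#' @param motif Character vector of conserved blocks, or `NULL` to generate
#'   two blocks of ~12% of the base length each. Motif blocks sit at fixed
#'   relative positions (10% and 55% of the length) so profiles acquire
#'   high-information columns.
#' @param divergence Per-site substitution probability outside motifs
#'   (default 0.08; must be < 0.9).
#' @param indel_rate Expected small indels (1-3 residues) per member
#'   (default 0.15).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(ko_id, n_members = 8L, base_length = 300L,
                        motif = NULL, divergence = 0.08, indel_rate = 0.15,
                        seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.9, n_members >= 1,
            base_length >= 30)
  if (!is.null(motif) && sum(nchar(motif)) >= base_length)
    stop("total motif length must be below base_length")
  structure(list(ko_id = ko_id, n_members = as.integer(n_members),
                 base_length = as.integer(base_length), motif = motif,
                 divergence = divergence, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic KO protein family
#'
#' Members share the spec's conserved motif blocks and diverge from a common
#' base sequence by independent per-site substitutions (outside motifs) and
#' occasional short indels, so pairwise identity is controlled by
#' `divergence`. All members start with M. Deterministic per seed.
#'
#' @param spec A [family_spec()].
#' @return A list: `family` (a [ko_family()]) and `truth` (base sequence,
#'   motif positions, spec).
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$base_length
    motifs <- spec$motif
    if (is.null(motifs)) {
      mlen <- max(8L, as.integer(0.12 * L))
      motifs <- c(paste(sample(AA20, mlen, replace = TRUE), collapse = ""),
                  paste(sample(AA20, mlen, replace = TRUE), collapse = ""))
    }
    base <- c("M", sample(AA20, L - 1L, replace = TRUE))
    anchors <- as.integer(L * c(0.10, 0.55, 0.80))[seq_along(motifs)]
    mask <- rep(FALSE, L)
    for (j in seq_along(motifs)) {
      mchars <- strsplit(motifs[j], "")[[1]]
      pos <- anchors[j] + seq_along(mchars) - 1L
      pos <- pos[pos <= L]
      base[pos] <- mchars[seq_along(pos)]
      mask[pos] <- TRUE
    }
    mask[1] <- TRUE  # keep the start methionine
    members <- vapply(seq_len(spec$n_members), function(i) {
      s <- base
      mut <- which(!mask & runif(L) < spec$divergence)
      if (length(mut))
        s[mut] <- vapply(s[mut], function(a)
          sample(setdiff(AA20, a), 1L), character(1))
      n_indel <- stats::rbinom(1L, 3L, min(1, spec$indel_rate))
      for (k in seq_len(n_indel)) {
        free <- which(!mask[seq_along(s)])
        free <- free[free > 1 & free < length(s) - 3]
        if (length(free) == 0) break
        at <- sample(free, 1L)
        if (runif(1) < 0.5) {
          s <- append(s, sample(AA20, sample(1:3, 1L), replace = TRUE),
                      after = at)
        } else {
          del <- at:min(at + sample(0:2, 1L), length(s) - 1L)
          del <- del[!mask[del]]
          if (length(del)) s <- s[-del]
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(members) <- sprintf("%s_m%02d", spec$ko_id, seq_along(members))
    list(family = ko_family(spec$ko_id, members),
         truth = list(base = paste(base, collapse = ""), motif = motifs,
                      motif_mask = mask, spec = spec))
  })
}

#' Generate outgroup (decoy) proteins
#'
#' Random proteins verified by the alignment oracle to share < `max_identity`
#' identity with every member of the reference family; used as
#' false-positive controls.
#'
#' @param n Number of decoys (0 allowed).
#' @param length Decoy length in residues.
#' @param family Reference [ko_family()] (or `NULL` to skip the check).
#' @param seed Integer seed.
#' @param max_identity Identity ceiling versus every family member
#'   (default 0.25).
#' @return Named character vector of decoy proteins.
#' @export
make_outgroup <- function(n, length = 300L, family = NULL, seed = 1L,
                          max_identity = 0.25) {
  if (n == 0) return(setNames(character(0), character(0)))
  withr::with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (base::length(out) < n && tries < 50L * n) {
      tries <- tries + 1L
      cand <- paste(c("M", sample(AA20, length - 1L, replace = TRUE)),
                    collapse = "")
      ok <- TRUE
      if (!is.null(family)) {
        for (m in family$members) {
          if (pairwise_identity(cand, m)$identity >= max_identity) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) out <- c(out, cand)
    }
    if (base::length(out) < n)
      stop("could not generate ", n, " decoys under the identity ceiling")
    setNames(out, sprintf("decoy_%02d", seq_len(n)))
  })
}

#' Reverse-translate a protein to a coding sequence
#'
#' Uniform codon choice per amino acid under the standard bacterial code
#' (translation table 11), seeded; the result contains no internal stop
#' codons and ends with TAA.
#'
#' @param protein Amino-acid string (no stop character).
#' @param seed Integer seed.
#' @return Nucleotide string including the terminal stop codon.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  aas <- strsplit(toupper(protein), "")[[1]]
  stopifnot(all(aas %in% names(by_aa)), !"*" %in% aas)
  withr::with_seed(seed, {
    codons <- vapply(aas, function(a) {
      opts <- by_aa[[a]]
      opts[sample.int(base::length(opts), 1L)]
    }, character(1))
    paste0(paste(codons, collapse = ""), "TAA")
  })
}

#' Specification of a synthetic community
#'
#' @param bins List of bin specs, each `list(bin_id, genes, intergenic_len,
#'   depth)` where `genes` is a list of `list(family, copies, role, cycle,
#'   gene_label)` entries (`role` one of `"key"`, `"nonkey"`, `"decoy"`).
#' @param truncate_first Truncate the first planted gene of the first bin at
#'   the contig start to exercise partial-gene handling (default `TRUE`).
#' @param seed Integer seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(bins, truncate_first = TRUE, seed = 1L) {
  stopifnot(base::length(bins) >= 1,
            all(vapply(bins, function(b) b$depth >= 0, logical(1))))
  structure(list(bins = bins, truncate_first = truncate_first,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate a synthetic community with planted genes
#'
#' Builds one contig per bin: planted genes (reverse-translated family
#' members, used round-robin) separated by random intergenic sequence,
#' alternating strands. Optionally the first gene of the first bin is
#' truncated at the contig edge (its 5' 15% removed) so exactly one truth row
#' is flagged partial. Writes the bin FASTA files, the coverage TSV and the
#' truth table.
#'
#' @param spec A [community_spec()].
#' @param families Named list of protein sets (named character vectors or
#'   [ko_family()] objects) covering every family the spec plants.
#' @param out_dir Output directory; `bins/`, `coverage.tsv` and `truth.tsv`
#'   are created inside.
#' @return The truth data.frame (bin_id, contig_id, start, end, strand,
#'   family, role, cycle, gene_label, partial), invisibly written to
#'   `truth.tsv`.
#' @export
make_community <- function(spec, families, out_dir) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(file.path(out_dir, "bins"), recursive = TRUE,
             showWarnings = FALSE)
  families <- lapply(families, function(f)
    if (inherits(f, "ko_family")) f$members else f)
  truth <- list()
  depths <- numeric(0)
  withr::with_seed(spec$seed, {
    for (bi in seq_along(spec$bins)) {
      b <- spec$bins[[bi]]
      contig_id <- paste0(b$bin_id, "_ctg1")
      ig_len <- if (!is.null(b$intergenic_len)) b$intergenic_len else 150L
      # expand copies and shuffle planting order deterministically
      plant <- list()
      for (g in b$genes) {
        copies <- if (!is.null(g$copies)) g$copies else 1L
        for (k in seq_len(copies)) plant[[base::length(plant) + 1L]] <- g
      }
      plant <- plant[sample.int(base::length(plant))]
      used <- new.env()
      seq_parts <- character(0)
      pos <- 0L
      strand_flip <- TRUE
      for (gi in seq_along(plant)) {
        g <- plant[[gi]]
        mem <- families[[g$family]]
        if (is.null(mem)) stop("unknown family in community spec: ", g$family)
        cnt <- if (is.null(used[[g$family]])) 0L else used[[g$family]]
        used[[g$family]] <- cnt + 1L
        prot <- mem[[(cnt %% base::length(mem)) + 1L]]
        nt <- reverse_translate(prot, seed = sample.int(1e6, 1L))
        partial <- FALSE
        first_gene <- bi == 1L && gi == 1L && isTRUE(spec$truncate_first)
        if (first_gene) {
          drop_codons <- ceiling(0.15 * nchar(prot))
          nt <- substr(nt, 3L * drop_codons + 1L, nchar(nt))
          partial <- TRUE
        } else {
          ig <- paste(sample(c("A", "C", "G", "T"),
                             ig_len + sample.int(40L, 1L), replace = TRUE),
                      collapse = "")
          seq_parts <- c(seq_parts, ig)
          pos <- pos + nchar(ig)
        }
        strand_flip <- !strand_flip
        strand <- if (strand_flip) "-" else "+"
        # Shine-Dalgarno motif + short spacer upstream of every full gene so
        # the gene caller sees ordinary prokaryotic gene anatomy
        rbs <- if (partial) "" else
          paste0("AGGAGG", paste(sample(c("A", "C", "T"),
                                        sample(5:7, 1L), replace = TRUE),
                                 collapse = ""))
        cassette <- paste0(rbs, nt)
        glen <- nchar(nt)
        if (strand == "-") {
          cassette <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cassette)))
          start <- pos + 1L
          end <- pos + glen
        } else {
          start <- pos + nchar(rbs) + 1L
          end <- pos + nchar(cassette)
        }
        seq_parts <- c(seq_parts, cassette)
        pos <- pos + nchar(cassette)
        truth[[base::length(truth) + 1L]] <- data.frame(
          bin_id = b$bin_id, contig_id = contig_id, start = start, end = end,
          strand = strand, family = g$family,
          role = if (!is.null(g$role)) g$role else "key",
          cycle = if (!is.null(g$cycle)) g$cycle else NA_character_,
          gene_label = if (!is.null(g$gene_label)) g$gene_label else g$family,
          partial = partial, stringsAsFactors = FALSE)
      }
      tail_ig <- paste(sample(c("A", "C", "G", "T"), ig_len, replace = TRUE),
                       collapse = "")
      contig <- paste0(paste(seq_parts, collapse = ""), tail_ig)
      contigs <- Biostrings::DNAStringSet(setNames(contig, contig_id))
      Biostrings::writeXStringSet(
        contigs, file.path(out_dir, "bins", paste0(b$bin_id, ".fna")))
      depths[b$bin_id] <- b$depth
    }
  })
  truth <- do.call(rbind, truth)
  write_coverage(depths, file.path(out_dir, "coverage.tsv"))
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth
}

#' Write KO families as a database-builder input directory
#'
#' @param families Named list of [ko_family()] objects or named character
#'   vectors.
#' @param dir Output directory; one `<id>.faa` per family.
#' @return `dir`, invisibly.
#' @export
write_ko_dir <- function(families, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(families)) {
    f <- families[[id]]
    seqs <- if (inherits(f, "ko_family")) f$members else f
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                                file.path(dir, paste0(id, ".faa")))
  }
  invisible(dir)
}

#' Write a cycle configuration YAML
#'
#' @param cycles Named list: cycle -> list of `list(ko, gene_label)`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_cycle_config <- function(cycles, path) {
  yaml::write_yaml(cycles, path)
  invisible(path)
}

#' Generate a complete fixture set
#'
#' Presets define the package's reference test conditions. `"small"` writes
#' six KO families and a cycle config for database-builder exercises.
#' `"community"` additionally writes a three-bin community with 19 planted
#' key genes (Nitrogen, Methane, Sulfur and a KO-less hydrogenase group),
#' non-key genes, decoy proteins with < 25% identity to every family, one
#' edge-truncated partial gene, and a coverage table (depths 10/30/60).
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed; per-family seeds are derived from it.
#' @param preset `"small"` or `"community"`.
#' @return A list with `families`, `cycles`, and for the community preset
#'   `truth`, `decoys` and the relevant paths.
#' @export
fixture_preset <- function(out_dir, seed = 1L,
                           preset = c("community", "small")) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  key_specs <- list(
    list(ko = "K00370", gene = "narG", cycle = "Nitrogen", len = 330L),
    list(ko = "K00368", gene = "nirK", cycle = "Nitrogen", len = 270L),
    list(ko = "K10944", gene = "pmoA", cycle = "Methane", len = 250L),
    list(ko = "K10945", gene = "pmoB", cycle = "Methane", len = 300L),
    list(ko = "K10946", gene = "pmoC", cycle = "Methane", len = 260L),
    list(ko = "K11180", gene = "dsrA", cycle = "Sulfur", len = 320L),
    list(ko = "FeFe-A", gene = "FeFe-A", cycle = "Hydrogenases", len = 290L))
  nonkey_specs <- list(
    list(ko = "K00001", gene = "adh", len = 310L),
    list(ko = "K00002", gene = "adhP", len = 280L),
    list(ko = "K03388", gene = "hdrA", len = 340L))
  all_specs <- c(key_specs, nonkey_specs)
  if (preset == "small") all_specs <- all_specs[1:6]
  fams <- list()
  for (i in seq_along(all_specs)) {
    s <- all_specs[[i]]
    fams[[s$ko]] <- make_family(family_spec(
      s$ko, n_members = 8L, base_length = s$len,
      divergence = 0.08, indel_rate = 0.15,
      seed = seed * 1000L + i))$family
  }
  ko_dir <- file.path(out_dir, "ko")
  write_ko_dir(fams, ko_dir)
  cycles <- list()
  for (s in key_specs) {
    if (preset == "small" && !s$ko %in% names(fams)) next
    cycles[[s$cycle]] <- c(cycles[[s$cycle]],
                           list(list(ko = s$ko, gene_label = s$gene)))
  }
  cycles_path <- file.path(out_dir, "cycles.yaml")
  write_cycle_config(cycles, cycles_path)
  res <- list(families = fams, cycles = cycles, ko_dir = ko_dir,
              cycles_path = cycles_path)
  if (preset == "small") return(res)

  decoys <- make_outgroup(4L, length = 280L, family = fams[["K10944"]],
                          seed = seed + 77L)
  plant <- function(fam, copies, role, cycle = NA, gene = fam)
    list(family = fam, copies = copies, role = role, cycle = cycle,
         gene_label = gene)
  bins <- list(
    list(bin_id = "binA", depth = 10, intergenic_len = 150L, genes = list(
      plant("K00370", 2L, "key", "Nitrogen", "narG"),
      plant("K00368", 1L, "key", "Nitrogen", "nirK"),
      plant("K10944", 1L, "key", "Methane", "pmoA"),
      plant("K10945", 1L, "key", "Methane", "pmoB"),
      plant("K10946", 1L, "key", "Methane", "pmoC"),
      plant("K11180", 1L, "key", "Sulfur", "dsrA"),
      plant("decoys", 1L, "decoy"))),
    list(bin_id = "binB", depth = 30, intergenic_len = 150L, genes = list(
      plant("K10944", 2L, "key", "Methane", "pmoA"),
      plant("K10945", 1L, "key", "Methane", "pmoB"),
      plant("K10946", 1L, "key", "Methane", "pmoC"),
      plant("FeFe-A", 2L, "key", "Hydrogenases", "FeFe-A"),
      plant("K00001", 1L, "nonkey"),
      plant("decoys", 2L, "decoy"))),
    list(bin_id = "binC", depth = 60, intergenic_len = 150L, genes = list(
      plant("K00370", 1L, "key", "Nitrogen", "narG"),
      plant("K00368", 2L, "key", "Nitrogen", "nirK"),
      plant("K11180", 2L, "key", "Sulfur", "dsrA"),
      plant("FeFe-A", 1L, "key", "Hydrogenases", "FeFe-A"),
      plant("K03388", 1L, "nonkey"),
      plant("decoys", 1L, "decoy"))))
  cspec <- community_spec(bins, truncate_first = TRUE, seed = seed + 13L)
  truth <- make_community(cspec, c(fams, list(decoys = decoys)), out_dir)
  res$truth <- truth
  res$decoys <- decoys
  res$bins_dir <- file.path(out_dir, "bins")
  res$coverage_path <- file.path(out_dir, "coverage.tsv")
  res
}

#' Score pipeline output against a fixture truth table
#'
#' Matches annotations to planted genes by coordinate overlap (an annotated
#' ORF must cover at least half of the planted gene on the same contig).
#' A planted key gene counts as recovered when a matching annotation carries
#' its cycle; a decoy annotation is any annotation overlapping a planted
#' decoy.
#'
#' @param truth Truth table from [make_community()].
#' @param annotations Annotation data.frame (with bin_id).
#' @param orfs Combined ORF table for all bins.
#' @return List: `n_key`, `n_recovered`, `recall`, `decoy_annotations`.
#' @export
score_recovery <- function(truth, annotations, orfs) {
  ann <- merge(annotations, orfs[c("orf_id", "contig_id", "start", "end")],
               by = "orf_id")
  overlaps <- function(trow) {
    sel <- ann$bin_id == trow$bin_id & ann$contig_id == trow$contig_id
    a <- ann[sel, , drop = FALSE]
    if (nrow(a) == 0) return(a)
    ov <- pmin(a$end, trow$end) - pmax(a$start, trow$start) + 1
    a[ov >= 0.5 * (trow$end - trow$start + 1), , drop = FALSE]
  }
  key <- truth[truth$role == "key", , drop = FALSE]
  recovered <- vapply(seq_len(nrow(key)), function(i) {
    hits <- overlaps(key[i, ])
    any(hits$cycle == key$cycle[i], na.rm = TRUE)
  }, logical(1))
  dec <- truth[truth$role == "decoy", , drop = FALSE]
  decoy_n <- sum(vapply(seq_len(nrow(dec)), function(i)
    nrow(overlaps(dec[i, ])), integer(1)))
  list(n_key = nrow(key), n_recovered = sum(recovered),
       recall = if (nrow(key)) sum(recovered) / nrow(key) else NA_real_,
       decoy_annotations = decoy_n)
}
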