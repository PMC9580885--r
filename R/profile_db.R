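#' Construct a KO protein family
#'
#' Wraps a set of protein sequences under one KEGG orthology (or gene-label)
#' identifier. The family mean length is recomputed from the members whenever
#' the membership changes, so downstream filters always see a consistent value.
#'
#' @param ko_id KO identifier (`K#####`) or, for KO-less families such as
#'   hydrogenase groups, a short gene label.
#' @param seqs Named character vector or `AAStringSet` of protein sequences.
#' @return An object of class `ko_family` with elements `ko_id`, `members`
#'   (named character vector) and `mean_length`.
#' @export
#' @examples
#' fam <- ko_family("K00001", c(s1 = "MKVLAT", s2 = "MKVLST"))
#' fam$mean_length
ko_family <- function(ko_id, seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) == 0) stop("family '", ko_id, "' has no members")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all member sequences must be named")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZUO]", seqs)
  if (any(bad))
    stop("non-amino-acid characters in members: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stop("zero-length member sequence")
  structure(list(ko_id = ko_id, members = seqs,
                 mean_length = mean(nchar(seqs))),
            class = "ko_family")
}

#' @export
print.ko_family <- function(x, ...) {
  cat(sprintf("<ko_family %s: %d members, mean length %.1f aa>\n",
              x$ko_id, length(x$members), x$mean_length))
  invisible(x)
}

#' Length-filter a KO family around its mean length
#'
#' Discards members shorter than `len_lo_frac` or longer than `len_hi_frac`
#' times the family mean length (both bounds inclusive: a member at exactly
#' 60% or 150% of the mean is retained). If fewer than `min_unique_seqs`
#' members would survive, the unfiltered family is returned unchanged, so the
#' filter never drops a family below the retention threshold by itself.
#'
#' @param family A [ko_family()].
#' @param cfg A [builder_config()].
#' @return A `ko_family` with the surviving members and recomputed mean.
#' @export
length_filter <- function(family, cfg = builder_config()) {
  stopifnot(inherits(family, "ko_family"))
  lens <- nchar(family$members)
  lo <- cfg$len_lo_frac * family$mean_length
  hi <- cfg$len_hi_frac * family$mean_length
  keep <- lens >= lo & lens <= hi
  if (sum(keep) < cfg$min_unique_seqs) return(family)
  ko_family(family$ko_id, family$members[keep])
}

#' De-replicate a KO family
#'
#' Collapses exact duplicate residue strings to their first occurrence.
#' Families with three or fewer entries pass through unchanged (only sets with
#' more than three entries are clustered).
#'
#' @inheritParams length_filter
#' @return A `ko_family` of unique members, first-occurrence order preserved.
#' @export
dereplicate <- function(family) {
  stopifnot(inherits(family, "ko_family"))
  if (length(family$members) <= 3) return(family)
  ko_family(family$ko_id, family$members[!duplicated(unname(family$members))])
}

#' Decide whether a KO family is retained
#'
#' A KO is discarded when fewer than `min_unique_seqs` unique residue strings
#' remain after de-replication: that is the minimum needed to build a
#' meaningful profile.
#'
#' @inheritParams length_filter
#' @return `TRUE` to keep the KO, `FALSE` to discard it.
#' @export
ko_retention <- function(family, cfg = builder_config()) {
  stopifnot(inherits(family, "ko_family"))
  length(unique(unname(family$members))) >= cfg$min_unique_seqs
}

#' Greedy identity/coverage clustering of a KO family
#'
#' Linear-scan clustering: members are visited longest first (ties broken by
#' name) and join the first existing cluster whose representative they match
#' at `cluster_min_id` identity over `cluster_min_cov` coverage of the shorter
#' sequence (see [pairwise_identity()]); otherwise they found a new cluster
#' with themselves as representative. Every member therefore satisfies the
#' identity/coverage contract with respect to its representative.
#'
#' @inheritParams length_filter
#' @return A list of clusters, each a list with `ko_id`, `members` (named
#'   character vector), `representative` (name) and `pooled = FALSE`.
#' @export
cluster_family <- function(family, cfg = builder_config()) {
  stopifnot(inherits(family, "ko_family"))
  ord <- order(-nchar(family$members), names(family$members))
  seqs <- family$members[ord]
  clusters <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_seq <- clusters[[k]]$members[[clusters[[k]]$representative]]
      pw <- pairwise_identity(seqs[[i]], rep_seq)
      if (pw$identity >= cfg$cluster_min_id &&
          pw$coverage >= cfg$cluster_min_cov) {
        clusters[[k]]$members <- c(clusters[[k]]$members, seqs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(ko_id = family$ko_id, members = seqs[i],
             representative = names(seqs)[i], pooled = FALSE)
    }
  }
  clusters
}

#' Pool undersized clusters of one KO
#'
#' Clusters with fewer than `min_cluster_size` members are removed and their
#' members combined into a single pooled cluster (flagged `pooled = TRUE`);
#' larger clusters are untouched and total membership is conserved. Surviving
#' standalone clusters are ordered by descending size (ties by representative
#' name) and the pooled cluster, if any, comes last.
#'
#' @param clusters Cluster list from [cluster_family()] (one KO).
#' @param cfg A [builder_config()].
#' @return A cluster list in canonical order.
#' @export
merge_small_clusters <- function(clusters, cfg = builder_config()) {
  if (length(clusters) == 0) return(clusters)
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  big <- clusters[sizes >= cfg$min_cluster_size]
  small <- clusters[sizes < cfg$min_cluster_size]
  if (length(big)) {
    ord <- order(-vapply(big, function(cl) length(cl$members), integer(1)),
                 vapply(big, function(cl) cl$representative, character(1)))
    big <- big[ord]
  }
  if (length(small)) {
    members <- do.call(c, lapply(small, function(cl) cl$members))
    rep_name <- names(members)[order(-nchar(members), names(members))][1]
    big[[length(big) + 1L]] <- list(ko_id = clusters[[1]]$ko_id,
                                    members = members,
                                    representative = rep_name, pooled = TRUE)
  }
  big
}

#' Build one profile HMM from a cluster
#'
#' Aligns the cluster members with MAFFT (`--quiet --anysymbol --auto`) and
#' builds a profile with `hmmbuild` (default settings). The returned record
#' carries the model length (`target_len`) that `hmmbuild` reports, which the
#' size filter later compares against query lengths.
#'
#' @param cluster One cluster from [merge_small_clusters()], with at least two
#'   members.
#' @param cluster_index Ordinal of the cluster within its KO (0-based).
#' @param hmm_path File the profile is appended to (HMMER3 flat format).
#' @param gene_label Short gene symbol; defaults to the KO id.
#' @return A one-row data.frame (profile_id, ko_id, gene_label, target_len,
#'   n_members, pooled).
#' @export
build_profile <- function(cluster, cluster_index, hmm_path,
                          gene_label = cluster$ko_id) {
  if (length(cluster$members) < 2)
    stop("profile build for ", cluster$ko_id, " cluster ", cluster_index,
         ": needs >= 2 members")
  profile_id <- sprintf("%s_c%d", cluster$ko_id, as.integer(cluster_index))
  td <- tempfile("hmmbuild")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  faa <- file.path(td, "cluster.faa")
  aln <- file.path(td, "cluster.aln")
  hmm <- file.path(td, "cluster.hmm")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(cluster$members), faa)
  status <- system2(find_tool("mafft"),
                    c("--quiet", "--anysymbol", "--auto", shQuote(faa)),
                    stdout = aln, stderr = FALSE)
  if (status != 0 || !file.size(aln) > 0)
    stop("mafft failed for ", cluster$ko_id, " cluster ", cluster_index)
  out <- system2(find_tool("hmmbuild"),
                 c("-n", profile_id, "--amino", shQuote(hmm), shQuote(aln)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("hmmbuild failed for ", cluster$ko_id, " cluster ", cluster_index,
         ": ", paste(tail(out, 3), collapse = " "))
  target_len <- parse_hmm_leng(hmm)
  file.append(hmm_path, hmm)
  data.frame(profile_id = profile_id, ko_id = cluster$ko_id,
             gene_label = gene_label, target_len = target_len,
             n_members = length(cluster$members),
             pooled = isTRUE(cluster$pooled), stringsAsFactors = FALSE)
}

# Model length(s) from the LENG lines of an HMMER3 flat file.
parse_hmm_leng <- function(hmm_path) {
  lines <- grep("^LENG ", readLines(hmm_path), value = TRUE)
  if (length(lines) == 0) stop("no LENG header in ", hmm_path)
  as.integer(sub("^LENG +", "", lines))
}

# Profile names + lengths from an HMMER3 flat file (possibly concatenated).
parse_hmm_headers <- function(hmm_path) {
  lines <- readLines(hmm_path)
  nm <- sub("^NAME +", "", grep("^NAME ", lines, value = TRUE))
  ln <- as.integer(sub("^LENG +", "", grep("^LENG ", lines, value = TRUE)))
  if (length(nm) == 0 || length(nm) != length(ln))
    stop("cannot parse profile headers in ", hmm_path)
  data.frame(profile_id = nm, target_len = ln, stringsAsFactors = FALSE)
}

#' Assign profiles to nutrient-cycle subsets
#'
#' Each profile joins the first declared cycle (declaration order in the
#' config) that claims its KO or gene label; unclaimed profiles go to the
#' `NonKey` subset. A KO claimed by two cycles is a configuration error.
#' Config entries naming a KO absent from the profile set are reported under
#' `missing` but do not stop the run.
#'
#' @param profiles data.frame with columns profile_id, ko_id, gene_label,
#'   target_len (one row per profile).
#' @param cycle_config Named list in declaration order: cycle name ->
#'   data.frame/list of entries with `ko` and optional `gene_label`. See
#'   [read_cycle_config()].
#' @return A list with `profiles` (input plus `subset`, `is_key_gene`,
#'   `gene_label` columns), `manifest` (subset, n_kos, n_profiles) and
#'   `missing` (config KOs with no profile).
#' @export
assemble_subsets <- function(profiles, cycle_config) {
  stopifnot(is.data.frame(profiles),
            all(c("profile_id", "ko_id", "target_len") %in% names(profiles)))
  if (anyDuplicated(profiles$profile_id))
    stop("duplicate profile_id in profile set")
  cyc_names <- names(cycle_config)
  bad <- setdiff(cyc_names, c(key_subset_names(), "User"))
  if (length(bad))
    stop("unknown cycle name(s) in config: ", paste(bad, collapse = ", "))
  entries <- data.frame(cycle = character(0), ko = character(0),
                        gene_label = character(0), stringsAsFactors = FALSE)
  for (cy in cyc_names) {
    es <- cycle_config[[cy]]
    for (e in es) {
      entries <- rbind(entries, data.frame(
        cycle = cy, ko = e$ko,
        gene_label = if (!is.null(e$gene_label)) e$gene_label else e$ko,
        stringsAsFactors = FALSE))
    }
  }
  dup <- unique(entries$ko[duplicated(entries$ko)])
  if (length(dup)) {
    coll <- vapply(dup, function(k)
      paste0(k, " (", paste(entries$cycle[entries$ko == k], collapse = ", "),
             ")"), character(1))
    stop("KO claimed by more than one cycle: ", paste(coll, collapse = "; "))
  }
  idx <- match(profiles$ko_id, entries$ko)
  profiles$subset <- ifelse(is.na(idx), "NonKey", entries$cycle[idx])
  profiles$is_key_gene <- !is.na(idx)
  if (!"gene_label" %in% names(profiles)) profiles$gene_label <- profiles$ko_id
  profiles$gene_label <- ifelse(is.na(idx), profiles$gene_label,
                                entries$gene_label[idx])
  missing <- setdiff(entries$ko, profiles$ko_id)
  subsets <- unique(c(intersect(c(cyc_names, "NonKey"),
                                unique(profiles$subset))))
  manifest <- do.call(rbind, lapply(subsets, function(s) {
    p <- profiles[profiles$subset == s, , drop = FALSE]
    data.frame(subset = s, n_kos = length(unique(p$ko_id)),
               n_profiles = nrow(p), stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, manifest = manifest, missing = missing)
}

#' Read a directory of KO-keyed protein FASTA files
#'
#' One multi-FASTA per KO, named `<KO>.faa` (or `.fa`/`.fasta`); the filename
#' stem becomes the family identifier.
#'
#' @param ko_dir Directory path.
#' @return Named list of [ko_family()] objects.
#' @export
read_ko_dir <- function(ko_dir) {
  files <- list.files(ko_dir, pattern = "\\.(faa|fa|fasta)$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no FASTA files in ", ko_dir)
  fams <- lapply(files, function(f) {
    seqs <- Biostrings::readAAStringSet(f)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ko_family(tools::file_path_sans_ext(basename(f)), seqs)
  })
  names(fams) <- vapply(fams, function(f) f$ko_id, character(1))
  fams[order(names(fams))]
}

#' Read a cycle configuration file
#'
#' YAML mapping cycle names (in declaration order, which sets assignment
#' precedence) to entry lists with fields `ko` and optional `gene_label`:
#' ```yaml
#' Nitrogen:
#'   - {ko: K00370, gene_label: narG}
#' Sulfur:
#'   - {ko: K11180, gene_label: dsrA}
#' ```
#' A TSV with columns cycle, ko, gene_label is also accepted (declaration
#' order = row order of first appearance).
#'
#' @param path Config file path.
#' @return Named list usable by [assemble_subsets()].
#' @export
read_cycle_config <- function(path) {
  if (grepl("\\.(ya?ml)$", path)) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    return(cfg)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("cycle", "ko") %in% names(tab)))
  if (!"gene_label" %in% names(tab)) tab$gene_label <- tab$ko
  cfg <- list()
  for (i in seq_len(nrow(tab))) {
    cy <- tab$cycle[i]
    cfg[[cy]] <- c(cfg[[cy]], list(list(ko = tab$ko[i],
                                        gene_label = tab$gene_label[i])))
  }
  cfg
}
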