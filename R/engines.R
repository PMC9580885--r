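# Adapters around the external engines (MAFFT, HMMER, Prodigal). Every call
# site goes through find_tool() so a missing binary fails with a clear message
# and tests can probe availability.

#' Locate an external tool on PATH
#'
#' @param name Binary name (e.g. `"hmmsearch"`).
#' @return Absolute path to the binary.
#' @export
find_tool <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path))
    stop("external tool '", name, "' not found on PATH; ",
         "install HMMER/Prodigal/MAFFT or adjust PATH")
  unname(path)
}

#' Search proteins against a profile subset with hmmsearch
#'
#' Runs `hmmsearch --tblout` with the prefilter e-value as the reporting
#' ceiling and parses the per-target table into raw hits. Queries are the
#' profiles, targets the ORF proteins; the full-sequence e-value and bit score
#' are reported (the engine's default reporting unit).
#'
#' @param proteins Named `AAStringSet` (or character vector) of ORF proteins.
#' @param hmm_path HMMER3 flat file of one subset.
#' @param profile_meta data.frame with profile_id and target_len for every
#'   profile in `hmm_path` (from the database manifest).
#' @param cfg A [triage_config()]; `e_prefilter` is the reporting ceiling.
#' @param phase `"key"` or `"full"`, recorded on each hit.
#' @return data.frame of raw hits: orf_id, profile_id, evalue, bitscore,
#'   query_len, target_len, phase.
#' @export
hmm_search <- function(proteins, hmm_path, profile_meta,
                       cfg = triage_config(), phase = "key") {
  if (methods::is(proteins, "XStringSet")) {
    widths <- setNames(Biostrings::width(proteins), names(proteins))
  } else {
    proteins <- Biostrings::AAStringSet(proteins)
    widths <- setNames(Biostrings::width(proteins), names(proteins))
  }
  empty <- data.frame(orf_id = character(0), profile_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      query_len = integer(0), target_len = integer(0),
                      phase = character(0), stringsAsFactors = FALSE)
  if (length(proteins) == 0) return(empty)
  td <- tempfile("hmmsearch")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  faa <- file.path(td, "orfs.faa")
  tbl <- file.path(td, "hits.tbl")
  Biostrings::writeXStringSet(proteins, faa)
  out <- system2(find_tool("hmmsearch"),
                 c("--noali", "--cpu", "1", "-o", shQuote(file.path(td, "main.out")),
                   "-E", format(cfg$e_prefilter, scientific = TRUE),
                   "--tblout", shQuote(tbl), shQuote(hmm_path), shQuote(faa)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("hmmsearch failed on ", hmm_path, ": ",
         paste(tail(out, 3), collapse = " "))
  hits <- parse_tblout(tbl)
  if (nrow(hits) == 0) return(empty)
  hits$query_len <- as.integer(widths[hits$orf_id])
  tl <- setNames(profile_meta$target_len, profile_meta$profile_id)
  hits$target_len <- as.integer(tl[hits$profile_id])
  if (anyNA(hits$target_len))
    stop("hits against profiles absent from the manifest: ",
         paste(unique(hits$profile_id[is.na(hits$target_len)]), collapse = ", "))
  hits$phase <- phase
  hits[order(hits$orf_id, hits$profile_id), , drop = FALSE]
}

# Parse an hmmsearch --tblout file: whitespace-separated, 18 fixed fields
# then free-text description.
parse_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(orf_id = character(0), profile_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    orf_id = vapply(fields, `[[`, character(1), 1L),
    profile_id = vapply(fields, `[[`, character(1), 3L),
    evalue = as.numeric(vapply(fields, `[[`, character(1), 5L)),
    bitscore = as.numeric(vapply(fields, `[[`, character(1), 6L)),
    stringsAsFactors = FALSE)
}

#' Call genes on a bin with Prodigal
#'
#' Runs the gene caller in the bin's mode (`single` for trustworthy MAGs,
#' `meta` otherwise) with partial-gene prediction at contig edges enabled
#' (the default open-ends behavior), and returns the ORF table plus
#' translations. ORF identifiers are `bin|contig_ordinal` and are stable for
#' a given input.
#'
#' @param bin A bin record from [scan_bins()].
#' @param out_dir Optional directory to keep the per-bin `.faa`, `.ffn` and
#'   GFF files; a temporary directory is used when `NULL`.
#' @return A list with `orfs` (data.frame: orf_id, bin_id, contig_id, start,
#'   end, strand, partial5, partial3, aa_len) and `proteins` (named
#'   `AAStringSet`, stop characters stripped).
#' @export
call_genes <- function(bin, out_dir = NULL) {
  td <- if (is.null(out_dir)) {
    d <- tempfile("prodigal"); dir.create(d); d
  } else {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE); out_dir
  }
  if (is.null(out_dir)) on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fna <- file.path(td, paste0(bin$bin_id, ".fna"))
  faa <- file.path(td, paste0(bin$bin_id, ".faa"))
  ffn <- file.path(td, paste0(bin$bin_id, ".ffn"))
  gff <- file.path(td, paste0(bin$bin_id, ".prodigal.gff"))
  Biostrings::writeXStringSet(bin$contigs, fna)
  out <- system2(find_tool("prodigal"),
                 c("-i", shQuote(fna), "-a", shQuote(faa), "-d", shQuote(ffn),
                   "-o", shQuote(gff), "-f", "gff", "-p", bin$mode, "-q"),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("prodigal failed on bin ", bin$bin_id, ": ",
         paste(tail(out, 2), collapse = " "))
  prots <- if (file.exists(faa) && file.size(faa) > 0)
    Biostrings::readAAStringSet(faa) else Biostrings::AAStringSet()
  if (length(prots) == 0) {
    return(list(orfs = data.frame(orf_id = character(0), bin_id = character(0),
                                  contig_id = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  partial5 = logical(0), partial3 = logical(0),
                                  aa_len = integer(0), stringsAsFactors = FALSE),
                proteins = prots))
  }
  hdr <- names(prots)
  # ">contig_3 # 2207 # 3709 # 1 # ID=1_3;partial=00;..."
  parts <- strsplit(hdr, " # ", fixed = TRUE)
  pname <- vapply(parts, `[[`, character(1), 1L)
  contig <- sub("_[0-9]+$", "", pname)
  ordin <- as.integer(sub("^.*_", "", pname))
  start <- as.integer(vapply(parts, `[[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[[`, character(1), 3L))
  strand <- ifelse(vapply(parts, `[[`, character(1), 4L) == "1", "+", "-")
  attrs <- vapply(parts, `[[`, character(1), 5L)
  partial <- sub("^.*partial=([01]{2}).*$", "\\1", attrs)
  # prodigal: first digit = left contig edge, second = right edge
  left <- substr(partial, 1, 1) == "1"
  right <- substr(partial, 2, 2) == "1"
  partial5 <- ifelse(strand == "+", left, right)
  partial3 <- ifelse(strand == "+", right, left)
  seqs <- sub("\\*$", "", as.character(prots))
  orf_id <- sprintf("%s|%s_%d", bin$bin_id, contig, ordin)
  # drop residue-free calls (all-X translations from N-runs)
  real <- grepl("[^X]", seqs)
  if (!all(real)) {
    keep <- which(real)
    seqs <- seqs[keep]; orf_id <- orf_id[keep]; contig <- contig[keep]
    start <- start[keep]; end <- end[keep]; strand <- strand[keep]
    partial5 <- partial5[keep]; partial3 <- partial3[keep]
  }
  orfs <- data.frame(orf_id = orf_id,
                     bin_id = rep(bin$bin_id, length(orf_id)),
                     contig_id = contig,
                     start = start, end = end, strand = strand,
                     partial5 = partial5, partial3 = partial3,
                     aa_len = nchar(seqs), stringsAsFactors = FALSE)
  proteins <- Biostrings::AAStringSet(setNames(seqs, orf_id))
  if (!is.null(out_dir))
    Biostrings::writeXStringSet(proteins, faa)
  list(orfs = orfs, proteins = proteins)
}

#' Ribosomal RNA detection hook
#'
#' Runs a user-supplied classifier command on the bin's contigs. The command
#' receives the contig FASTA path as its last argument and must print FASTA
#' records of detected rRNA genes on stdout. Without an adapter the step is
#' skipped with a warning; taxonomy assignment is out of scope.
#'
#' @param bin A bin record from [scan_bins()].
#' @param adapter_cmd Character vector: command and leading arguments, or
#'   `NULL`.
#' @return A `DNAStringSet` of detected features (possibly empty).
#' @export
detect_rrna <- function(bin, adapter_cmd = NULL) {
  if (is.null(adapter_cmd)) {
    warning("no rRNA adapter configured for bin ", bin$bin_id,
            "; step skipped")
    return(Biostrings::DNAStringSet())
  }
  td <- tempfile("rrna")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fna <- file.path(td, "contigs.fna")
  out <- file.path(td, "rrna.fna")
  Biostrings::writeXStringSet(bin$contigs, fna)
  status <- suppressWarnings(
    system2(adapter_cmd[1], c(adapter_cmd[-1], shQuote(fna)), stdout = out,
            stderr = FALSE))
  if (status != 0) {
    warning("rRNA adapter failed on bin ", bin$bin_id, "; step skipped")
    return(Biostrings::DNAStringSet())
  }
  tryCatch(Biostrings::readDNAStringSet(out), error = function(e) {
    warning("rRNA adapter output for bin ", bin$bin_id,
            " could not be parsed: ", conditionMessage(e))
    Biostrings::DNAStringSet()
  })
}
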