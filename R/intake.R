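#' Decide the gene-calling mode from bin size
#'
#' A bin is treated as a single trustworthy genome only when its total length
#' lies inside the configured band (boundaries inclusive); smaller bins are
#' too short for single-mode gene calling and larger ones cannot be one
#' prokaryotic genome, so both are processed in meta mode.
#'
#' @param total_len Total bin length in bp (vectorized).
#' @param cfg An [intake_config()].
#' @return `"single"` or `"meta"` per element.
#' @export
#' @examples
#' select_mode(c(4641652, 16e6, 4e5))
select_mode <- function(total_len, cfg = intake_config()) {
  stopifnot(all(total_len > 0))
  ifelse(total_len >= cfg$min_single_bp & total_len <= cfg$max_single_bp,
         "single", "meta")
}

#' Should slow auxiliary analyses run for this bin?
#'
#' The upper size bound doubles as a runtime guard: optional analyses (rRNA
#' classification and the legacy tRNA/ncRNA/CRISPR hooks) are skipped for bins
#' larger than `max_single_bp`, typically the unbinned metagenome fraction.
#'
#' @inheritParams select_mode
#' @return Logical, `TRUE` when auxiliary analyses are allowed.
#' @export
auxiliary_enabled <- function(total_len, cfg = intake_config()) {
  total_len <= cfg$max_single_bp
}

#' Discover input bins in a directory
#'
#' Every `.fa`/`.fna`/`.fasta` file becomes one bin; the filename stem is the
#' bin id and an unbinned-fraction file is just another bin. Bins with
#' duplicated contig headers (or unreadable FASTA) are rejected with a warning
#' while the remaining bins are processed; a directory without FASTA files is
#' fatal.
#'
#' @param path Input directory.
#' @param cfg An [intake_config()] used to set each bin's mode.
#' @return List of bin records: `bin_id`, `contigs` (`DNAStringSet`),
#'   `total_len`, `mode`, `coverage` (NA until [load_coverage()]).
#' @export
scan_bins <- function(path, cfg = intake_config()) {
  if (!dir.exists(path)) stop("input directory not found: ", path)
  files <- list.files(path, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  if (length(files) == 0) stop("no FASTA files in ", path)
  bins <- list()
  for (f in sort(files)) {
    bin_id <- tools::file_path_sans_ext(basename(f))
    contigs <- tryCatch(Biostrings::readDNAStringSet(f), error = function(e) {
      warning("bin ", bin_id, " unreadable, skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(contigs)) next
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    if (anyDuplicated(names(contigs))) {
      warning("bin ", bin_id, " has duplicated contig headers, skipped")
      next
    }
    total_len <- sum(Biostrings::width(contigs))
    bins[[bin_id]] <- list(bin_id = bin_id, contigs = contigs,
                           total_len = total_len,
                           mode = select_mode(total_len, cfg),
                           coverage = NA_real_)
  }
  if (length(bins) == 0) stop("no usable bins in ", path)
  bins
}

#' Load a per-bin coverage table
#'
#' TSV with two columns, `bin_id` and mean depth, with an optional header
#' line. Bins without a row keep coverage `NA` (they are excluded from
#' abundance denominators, with a warning); rows naming unknown bins are
#' warned about and ignored; a non-numeric or negative depth is an error
#' naming the offending line.
#'
#' @param path Coverage TSV path.
#' @param bin_ids Character vector of known bin ids.
#' @return Named numeric vector over `bin_ids` (NA where absent).
#' @export
load_coverage <- function(path, bin_ids) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("coverage table ", path, " is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first_depth <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_depth)) start <- 2L  # header line
  cov <- setNames(rep(NA_real_, length(bin_ids)), bin_ids)
  for (i in seq.int(start, length.out = max(0L, length(lines) - start + 1L))) {
    fl <- fields[[i]]
    if (length(fl) < 2)
      stop("coverage table line ", i, ": expected bin_id<TAB>depth")
    depth <- suppressWarnings(as.numeric(fl[2]))
    if (is.na(depth) || depth < 0)
      stop("coverage table line ", i, ": invalid depth '", fl[2], "'")
    if (!fl[1] %in% bin_ids) {
      warning("coverage row for unknown bin '", fl[1], "' ignored")
      next
    }
    cov[fl[1]] <- depth
  }
  uncovered <- bin_ids[is.na(cov)]
  if (length(uncovered))
    warning("no coverage for bin(s): ", paste(uncovered, collapse = ", "),
            "; excluded from abundance denominators")
  cov
}

#' Write a per-bin coverage table
#'
#' Inverse of [load_coverage()]; the two round-trip unchanged.
#'
#' @param coverage Named numeric vector (NA entries are omitted).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  keep <- !is.na(coverage)
  writeLines(sprintf("%s\t%s", names(coverage)[keep],
                     format(coverage[keep], trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}
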