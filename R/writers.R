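# Per-bin annotated output writers: GFF3 (via rtracklayer), a compact
# GenBank-style flat file, and the all-hits/best-hits TSVs.

#' Write a bin's ORFs and annotations as GFF3
#'
#' CDS features with `product` (gene label) and `ko` qualifiers where an ORF
#' was annotated; unannotated ORFs are written with product
#' `hypothetical protein`.
#'
#' @param orfs ORF table from [call_genes()].
#' @param annotations Annotation data.frame (may be empty).
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(orfs, annotations, path) {
  if (nrow(orfs) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  idx <- match(orfs$orf_id, annotations$orf_id)
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig_id,
    ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
    strand = orfs$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "cyclescan"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- orfs$orf_id
  S4Vectors::mcols(gr)$product <- ifelse(is.na(idx), "hypothetical protein",
                                         annotations$gene_label[idx])
  ko <- ifelse(is.na(idx), NA_character_, annotations$ko_id[idx])
  S4Vectors::mcols(gr)$ko <- ko
  S4Vectors::mcols(gr)$partial <-
    ifelse(orfs$partial5 | orfs$partial3, "true", NA_character_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a bin as a GenBank-style flat file
#'
#' A minimal flat file (LOCUS / FEATURES / ORIGIN) with one record per contig
#' and one CDS feature per ORF, carrying `product` and `db_xref` (KO)
#' qualifiers. Intended for human inspection and downstream viewers that
#' accept plain GenBank.
#'
#' @param bin Bin record from [scan_bins()].
#' @param orfs ORF table from [call_genes()].
#' @param annotations Annotation data.frame.
#' @param path Output `.gbk` path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(bin, orfs, annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  idx <- match(orfs$orf_id, annotations$orf_id)
  product <- ifelse(is.na(idx), "hypothetical protein",
                    annotations$gene_label[idx])
  ko <- ifelse(is.na(idx), NA_character_, annotations$ko_id[idx])
  for (ci in seq_along(bin$contigs)) {
    cid <- names(bin$contigs)[ci]
    seq <- tolower(as.character(bin$contigs[[ci]]))
    len <- nchar(seq)
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     linear   %s",
                       cid, len, format(Sys.Date(), "%d-%b-%Y")), con)
    writeLines(sprintf("DEFINITION  %s bin %s.", cid, bin$bin_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    rows <- which(orfs$contig_id == cid)
    for (i in rows) {
      loc <- sprintf("%d..%d", orfs$start[i], orfs$end[i])
      if (orfs$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         orfs$orf_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"", product[i]),
                 con)
      if (!is.na(ko[i]))
        writeLines(sprintf("                     /db_xref=\"KO:%s\"", ko[i]),
                   con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, len, by = 60)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59, len))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write the all-hits and best-hits TSVs
#'
#' Two files per run: every raw hit that passed the reporting prefilter, and
#' the per-ORF best hits with their annotation columns.
#'
#' @param all_hits Raw-hit data.frame from [annotate_two_phase()].
#' @param annotations Best-hit annotation data.frame.
#' @param all_path,best_path Output TSV paths.
#' @return Invisibly, `c(all_path, best_path)`.
#' @export
write_hit_tables <- function(all_hits, annotations, all_path, best_path) {
  utils::write.table(all_hits, all_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(annotations, best_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(all_path, best_path))
}
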