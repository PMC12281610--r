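#' Read a FASTA file
#'
#' Sequences are uppercased on the way in so that downstream Hamming
#' comparisons see a canonical alphabet. Gzipped input is handled
#' transparently by extension. Duplicate sequence ids are kept but flagged
#' with a warning.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet] named by the full header lines; the
#'   id of a record is the first whitespace-delimited token of its name.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(x) == 0L)) {
    stop("malformed FASTA in ", path, ": empty sequence at record ",
         which(Biostrings::width(x) == 0L)[1L])
  }
  ids <- record_ids(names(x))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA in ", path, ": empty header at record ",
         which(!nzchar(ids))[1L])
  }
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  up <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(up) <- names(x)
  up
}

#' Write sequences as FASTA
#'
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param line_width Sequence line wrap width.
#' @export
write_fasta <- function(x, path, line_width = 80L) {
  x <- as_dna(x)
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A [Biostrings::QualityScaledDNAStringSet] with
#'   [Biostrings::PhredQuality] scores.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt")  # also reads plain text transparently
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path,
         ": number of lines is not a multiple of 4")
  }
  hdr <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  seqs <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  plus <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  qual <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  if (any(!startsWith(hdr, "@")) || any(!startsWith(plus, "+"))) {
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))[1L]
    stop("malformed FASTQ in ", path, ": record ", bad,
         " lacks its @/+ marker lines")
  }
  ids <- sub("^@", "", hdr)
  bad <- nchar(seqs) != nchar(qual) | nchar(seqs) == 0L
  if (any(bad)) {
    stop("malformed FASTQ in ", path,
         ": sequence/quality length mismatch for record ",
         record_ids(ids)[which(bad)[1L]])
  }
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- ids
  Biostrings::QualityScaledDNAStringSet(out,
                                        Biostrings::PhredQuality(qual))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path (a `.gz` extension triggers compression).
#' @export
write_fastq <- function(x, path) {
  stopifnot(is(x, "QualityScaledDNAStringSet"))
  Biostrings::writeXStringSet(
    as(x, "DNAStringSet"), path, format = "fastq",
    qualities = Biostrings::BStringSet(Biostrings::quality(x)),
    compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Decode Phred scores from a quality-scaled read set
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet] or
#'   [Biostrings::PhredQuality].
#' @return An [IRanges::IntegerList] of per-base scores.
#' @export
phred_scores <- function(x) {
  if (is(x, "QualityScaledDNAStringSet")) x <- Biostrings::quality(x)
  methods::as(x, "IntegerList")
}

#' Read gene features from a GFF3 file
#'
#' Only rows whose type is in `types` are returned. The feature id is taken
#' from the `ID` attribute, falling back to `locus_tag`; a feature with
#' neither is an error, as is a kept feature without strand (promoter
#' extraction needs orientation).
#'
#' @param path Path to a GFF3 file.
#' @param types Character vector of feature types to keep.
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id` and
#'   `type`, named by `feature_id`.
#' @export
read_gff3 <- function(path, types = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  keep <- which(as.character(gr$type) %in% types)
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    rep(NA_character_, length(gr))
  lt <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else
    rep(NA_character_, length(gr))
  fid <- ifelse(is.na(id) | !nzchar(id), lt, id)
  if (anyNA(fid) || any(!nzchar(fid))) {
    bad <- which(is.na(fid) | !nzchar(fid))[1L]
    stop("GFF3 feature ", keep[bad], " in ", path,
         " has neither ID nor locus_tag attribute")
  }
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    bad <- which(as.character(GenomicRanges::strand(gr)) == "*")[1L]
    stop("GFF3 feature ", keep[bad], " in ", path,
         " (", fid[bad], ") has no strand; strand is required")
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    feature_id = fid,
    type = as.character(gr$type))
  names(out) <- fid
  out
}

#' Write gene features as GFF3
#'
#' @param features A [GenomicRanges::GRanges] with a `feature_id` column.
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(is(features, "GRanges"))
  gr <- features
  gr$ID <- gr$feature_id
  if (is.null(gr$type)) gr$type <- "gene"
  gr$source <- "recordseq"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write spacer alignments as a minimal SAM file
#'
#' Emits an `@HD`/`@SQ` header with contig lengths, one line per alignment
#' (`FLAG` 16 for minus-strand placements with the stored sequence
#' reverse-complemented back to reference orientation, `NM:i` carrying the
#' mismatch count) and unmapped records with `FLAG` 4.
#'
#' @param alignments A data frame as produced by [map_spacers()].
#' @param references Named [Biostrings::DNAStringSet] of reference contigs.
#' @param path Output path.
#' @export
write_sam <- function(alignments, references, path) {
  references <- as_dna(references)
  refnames <- record_ids(names(references))
  reflen <- setNames(Biostrings::width(references), refnames)
  mapped <- !is.na(alignments$ref_id)
  if (any(!(alignments$ref_id[mapped] %in% refnames))) {
    stop("alignment references unknown contig: ",
         setdiff(alignments$ref_id[mapped], refnames)[1L])
  }
  spalen <- nchar(alignments$seq)
  ends <- alignments$start + spalen - 1L
  over <- mapped & ends > reflen[alignments$ref_id]
  if (any(over, na.rm = TRUE)) {
    stop("alignment of ", alignments$spacer_id[which(over)[1L]],
         " extends beyond the end of contig ",
         alignments$ref_id[which(over)[1L]])
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refnames, reflen[refnames]))
  seqout <- alignments$seq
  minus <- mapped & alignments$strand == "-"
  if (any(minus)) {
    seqout[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqout[minus])))
  }
  lines <- ifelse(
    mapped,
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            alignments$spacer_id, ifelse(alignments$strand == "-", 16L, 0L),
            alignments$ref_id, alignments$start, spalen, seqout,
            alignments$n_mismatch),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
            alignments$spacer_id, alignments$seq))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write / read a gene-by-sample count table (TSV)
#'
#' Genes as rows, samples as columns, header row, integer cells; first
#' column `gene_id`.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path File path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("count table lacks a gene_id column: ",
                                      path)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Read a differential expression table
#'
#' Expects tab-separated columns `gene_id`, `log2fc` and `fdr`.
#'
#' @param path File path.
#' @return A data frame with those three columns.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("differential expression table ", path,
         " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  df[need]
}

# first whitespace-delimited token of a FASTA/FASTQ header
record_ids <- function(x) sub("\\s.*$", "", x)

as_dna <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    names(out) <- names(x)
    return(out)
  }
  methods::as(x, "DNAStringSet")
}
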