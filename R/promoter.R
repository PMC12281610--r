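#' Select strongly induced genes from a differential expression table
#'
#' Keeps genes with `log2fc` strictly greater than `logfc_min` and `fdr`
#' strictly below `fdr_max`, sorted by descending fold change. The default
#' threshold reproduces the transcriptome-mining rule used to nominate
#' inducible promoters (log2 fold change above 8 under significance).
#'
#' @param de_table Data frame with columns `gene_id`, `log2fc`, `fdr`
#'   (see [read_de_table()]).
#' @param logfc_min Strict lower bound on log2 fold change.
#' @param fdr_max Strict upper bound on FDR.
#' @return Character vector of gene ids.
#' @export
select_candidates <- function(de_table, logfc_min = 8, fdr_max = 0.05) {
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(de_table))
  if (length(miss)) {
    stop("differential expression table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  keep <- de_table$log2fc > logfc_min & de_table$fdr < fdr_max
  sel <- de_table[keep, , drop = FALSE]
  sel$gene_id[order(-sel$log2fc)]
}

#' Extract a candidate promoter region upstream of a gene
#'
#' In `upstream200` mode the region is the `window` bases upstream of the
#' annotated gene start (the start-codon proxy), strand-aware: for a minus
#' strand gene the window lies downstream in reference coordinates and the
#' sequence is reverse-complemented so its 3' end abuts the start codon.
#' The window is truncated at the contig end and, when `truncate = TRUE`,
#' at the boundary of the nearest annotated feature intruding into it. In
#' `intergenic` mode the entire gap between the gene's start-codon-side
#' boundary and the nearest feature upstream of it (on either strand) is
#' returned, so a divergently transcribed pair sharing one intergenic
#' region yields that same region from both genes, in opposite
#' orientations.
#'
#' @param gene_id Gene to extract for; must be in the annotation.
#' @param annotation [GenomicRanges::GRanges] with `feature_id` (see
#'   [read_gff3()]).
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param window Upstream window width (bp) for `upstream200` mode.
#' @param mode `"upstream200"` or `"intergenic"`.
#' @param truncate Truncate the window at intruding upstream features.
#' @return A one-row data frame: `gene_id`, `seq`, `source`, `contig`,
#'   `start`, `end` (1-based inclusive reference coordinates), `strand`,
#'   `truncated` — or `NULL` (with a warning) when the upstream gap is
#'   empty.
#' @export
extract_promoter <- function(gene_id, annotation, genome, window = 200L,
                             mode = c("upstream200", "intergenic"),
                             truncate = TRUE) {
  mode <- match.arg(mode)
  genome <- as_dna(genome)
  names(genome) <- record_ids(names(genome))
  gi <- match(gene_id, annotation$feature_id)
  if (is.na(gi)) stop("gene ", gene_id, " not found in the annotation")
  gene <- annotation[gi]
  contig <- as.character(GenomicRanges::seqnames(gene))
  if (!contig %in% names(genome)) {
    stop("contig ", contig, " not present in the genome sequences")
  }
  clen <- Biostrings::width(genome[contig])
  strand <- as.character(GenomicRanges::strand(gene))
  gstart <- GenomicRanges::start(gene)
  gend <- GenomicRanges::end(gene)
  others <- annotation[-gi]
  others <- others[as.character(GenomicRanges::seqnames(others)) == contig]

  if (strand == "+") {
    # nearest upstream covered base below the gene start
    ostart <- GenomicRanges::start(others)
    oend <- GenomicRanges::end(others)
    ub <- suppressWarnings(max(pmin(oend[ostart <= gstart - 1L],
                                    gstart - 1L)))
    if (!is.finite(ub)) ub <- 0L
    if (mode == "upstream200") {
      lo <- max(1L, gstart - window)
      truncated <- FALSE
      if (truncate && ub >= lo) {
        lo <- ub + 1L
        truncated <- TRUE
      }
      hi <- gstart - 1L
    } else {
      lo <- ub + 1L
      hi <- gstart - 1L
      truncated <- ub > 0L
    }
  } else {
    ostart <- GenomicRanges::start(others)
    oend <- GenomicRanges::end(others)
    ub <- suppressWarnings(min(pmax(ostart[oend >= gend + 1L],
                                    gend + 1L)))
    if (!is.finite(ub)) ub <- clen + 1L
    if (mode == "upstream200") {
      hi <- min(clen, gend + window)
      truncated <- FALSE
      if (truncate && ub <= hi) {
        hi <- ub - 1L
        truncated <- TRUE
      }
      lo <- gend + 1L
    } else {
      hi <- ub - 1L
      lo <- gend + 1L
      truncated <- ub <= clen
    }
  }
  if (hi < lo) {
    warning("gene ", gene_id, ": upstream gap is empty; no candidate")
    return(NULL)
  }
  seq <- as.character(Biostrings::subseq(genome[[contig]], lo, hi))
  if (strand == "-") {
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  data.frame(gene_id = gene_id, seq = seq,
             source = if (mode == "upstream200") "upstream200" else
               "intergenic",
             contig = contig, start = lo, end = hi, strand = strand,
             truncated = truncated, stringsAsFactors = FALSE)
}

#' @rdname extract_promoter
#' @param gene_ids Character vector of genes.
#' @return For `extract_promoters`, a data frame with one row per gene
#'   that yielded a candidate.
#' @export
extract_promoters <- function(gene_ids, annotation, genome, window = 200L,
                              mode = c("upstream200", "intergenic"),
                              truncate = TRUE) {
  mode <- match.arg(mode)
  rows <- lapply(gene_ids, extract_promoter, annotation = annotation,
                 genome = genome, window = window, mode = mode,
                 truncate = truncate)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), seq = character(),
                      source = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), truncated = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
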