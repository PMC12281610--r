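#' Count spacer alignments per gene
#'
#' A deduplicated alignment is assigned to a gene when its interval
#' overlaps the gene interval by at least 1 bp, ignoring strand (spacers
#' report transcripts from either strand). Alignments overlapping two or
#' more genes are discarded as ambiguous; alignments overlapping none are
#' reported as intergenic. Assigned + ambiguous + intergenic always equals
#' the number of mapped alignments.
#'
#' @param alignments Data frame from [map_spacers()] /
#'   [remove_duplicates()]; unmapped rows are ignored.
#' @param annotation A [GenomicRanges::GRanges] of gene features with a
#'   `feature_id` column (see [read_gff3()]).
#' @return A list with `counts` (named integer vector over all annotation
#'   genes) and `summary` (`assigned`, `ambiguous`, `intergenic`).
#' @export
count_per_gene <- function(alignments, annotation) {
  stopifnot(is(annotation, "GRanges"))
  aln <- alignments[!is.na(alignments$ref_id), , drop = FALSE]
  contigs <- GenomeInfoDb::seqlevels(annotation)
  bad <- setdiff(unique(aln$ref_id), contigs)
  if (length(bad)) {
    stop("alignment contig(s) absent from the annotation: ",
         paste(bad, collapse = ", "))
  }
  counts <- setNames(integer(length(annotation)), annotation$feature_id)
  if (!nrow(aln)) {
    return(list(counts = counts,
                summary = c(assigned = 0L, ambiguous = 0L,
                            intergenic = 0L)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(aln$ref_id, levels = contigs),
    ranges = IRanges::IRanges(start = aln$start,
                              width = nchar(aln$seq)))
  ov <- GenomicRanges::findOverlaps(gr, annotation, minoverlap = 1L,
                                    ignore.strand = TRUE)
  nhit <- tabulate(S4Vectors::queryHits(ov), nbins = nrow(aln))
  uniq <- which(nhit == 1L)
  sel <- S4Vectors::queryHits(ov) %in% uniq
  tab <- tabulate(S4Vectors::subjectHits(ov)[sel],
                  nbins = length(annotation))
  counts[] <- tab
  list(counts = counts,
       summary = c(assigned = length(uniq),
                   ambiguous = sum(nhit >= 2L),
                   intergenic = sum(nhit == 0L)))
}

#' Discard genes with few counts
#'
#' Retains genes whose total count across all samples is at least
#' `min_total` (the default mirrors discarding genes with less than 10
#' counts across conditions).
#'
#' @param counts Genes x samples integer matrix.
#' @param min_total Minimum row sum to keep a gene.
#' @return The filtered matrix.
#' @export
filter_low_counts <- function(counts, min_total = 10L) {
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / colsum[s] * 1e6`; every column of the
#' result sums to one million.
#'
#' @param counts Genes x samples matrix.
#' @return A numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop("zero total count in sample(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  }
  sweep(counts, 2L, cs, "/") * 1e6
}

#' Variance-stabilising transform of counts
#'
#' A deterministic log-CPM transform, `log2(cpm + 0.5)`, used before
#' ordination and clustering. Monotone in the counts and free of fitted
#' parameters; see the methods vignette for why this stand-in is preferred
#' over a fitted transformation.
#'
#' @param counts Genes x samples matrix.
#' @return A numeric matrix of the same shape.
#' @export
vst_counts <- function(counts) {
  log2(cpm(counts) + 0.5)
}

#' Principal component analysis of samples
#'
#' Genes are centred, sample scores come from the singular value
#' decomposition, and components are ordered by explained variance. Signs
#' are fixed so that the largest-magnitude gene loading of every component
#' is positive, making results deterministic.
#'
#' @param x Genes x samples numeric matrix (typically [vst_counts()]).
#' @return A list with `scores` (samples x components), `var_explained`
#'   and `loadings`.
#' @export
pca_samples <- function(x) {
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2L, function(v) {
    sign(v[which.max(abs(v))])
  })
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, "*")
  loadings <- sweep(p$rotation, 2L, flip, "*")
  list(scores = scores,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       loadings = loadings)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage clustering on Euclidean distances between sample
#' columns.
#'
#' @param x Genes x samples numeric matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
hclust_samples <- function(x) {
  if (ncol(x) < 2L) stop("clustering needs at least 2 samples")
  hclust(dist(t(x)), method = "average")
}

#' Relative spacer count of the sensor gene
#'
#' CPM-transformed plasmid counts of the sensor gene divided by the total
#' number of spacers extracted in each sample (pre-mapping; by default the
#' unique spacers retained by [dedup_sample()]).
#'
#' @param plasmid_counts Plasmid genes x samples count matrix.
#' @param total_spacers Named vector of per-sample total extracted
#'   spacers; names must cover the count matrix columns.
#' @param gene Sensor gene id.
#' @return Named per-sample numeric vector.
#' @export
relative_spacer_count <- function(plasmid_counts, total_spacers,
                                  gene = "FbFP") {
  if (!gene %in% rownames(plasmid_counts)) {
    stop("gene ", gene, " not found in the plasmid count table")
  }
  miss <- setdiff(colnames(plasmid_counts), names(total_spacers))
  if (length(miss)) {
    stop("total_spacers lacks sample(s): ", paste(miss, collapse = ", "))
  }
  cpm(plasmid_counts)[gene, ] / total_spacers[colnames(plasmid_counts)]
}

#' Benjamini-Hochberg adjustment
#'
#' Classic step-up false discovery rate control:
#' `padj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
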