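#' Place spacers on reference contigs
#'
#' Finds every placement of each spacer and of its reverse complement with
#' at most `max_mismatch` mismatches (seeded pigeonhole search with full
#' Hamming verification; ambiguous bases never match). The reported
#' placement has the fewest mismatches; when several placements tie at the
#' minimum the spacer is flagged `multi` and the lexicographically smallest
#' `(ref_id, start, strand)` is reported. Minus-strand placements are
#' reported at the forward coordinates of the matched substring. Spacers
#' with no placement are `unmapped` (with a reason; a spacer of only
#' ambiguous bases can never match).
#'
#' @param spacers Character vector of spacer sequences; names become
#'   spacer ids (defaults to `spacer<i>`).
#' @param references Named [Biostrings::DNAStringSet] of contigs.
#' @param max_mismatch Mismatch budget (default 1).
#' @return A data frame with columns `spacer_id`, `seq`, `ref_id`, `start`
#'   (1-based), `strand`, `n_mismatch`, `n_best` (placements tying the
#'   minimum), `mapq_proxy` (`unique`/`multi`/`unmapped`) and `reason` for
#'   unmapped spacers.
#' @export
map_spacers <- function(spacers, references, max_mismatch = 1L) {
  if (is.data.frame(spacers)) {
    spacers <- setNames(spacers$spacer, rownames(spacers))
  }
  if (is(spacers, "XStringSet")) spacers <- as.character(spacers)
  spacers <- toupper(spacers)
  ids <- names(spacers)
  if (is.null(ids)) ids <- sprintf("spacer%d", seq_along(spacers))
  references <- as_dna(references)
  refnames <- record_ids(names(references))
  hits <- map_all_hits_cpp(spacers, as.character(references),
                           as.integer(max_mismatch))
  out <- data.frame(spacer_id = ids, seq = unname(spacers),
                    ref_id = NA_character_, start = NA_integer_,
                    strand = NA_character_, n_mismatch = NA_integer_,
                    n_best = 0L, mapq_proxy = "unmapped",
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$refname <- refnames[hits$ref]
    o <- order(hits$query, hits$mm, hits$refname, hits$start, hits$strand,
               method = "radix")
    hits <- hits[o, , drop = FALSE]
    first <- which(!duplicated(hits$query))
    q <- hits$query[first]
    minmm <- hits$mm[first]
    at_min <- hits$mm == minmm[match(hits$query, q)]
    nbest <- tabulate(hits$query[at_min], nbins = length(spacers))
    out$ref_id[q] <- hits$refname[first]
    out$start[q] <- hits$start[first]
    out$strand[q] <- hits$strand[first]
    out$n_mismatch[q] <- minmm
    out$n_best[q] <- nbest[q]
    out$mapq_proxy[q] <- ifelse(nbest[q] > 1L, "multi", "unique")
  }
  un <- out$mapq_proxy == "unmapped"
  out$reason[un] <- ifelse(grepl("^[^ACGT]*$", out$seq[un]),
                           "only_ambiguous_bases", "no_placement")
  out
}

#' @rdname map_spacers
#' @param spacer A single spacer sequence.
#' @export
map_spacer <- function(spacer, references, max_mismatch = 1L) {
  map_spacers(setNames(as.character(spacer)[1L],
                       names(spacer)[1L] %||% "spacer1"),
              references, max_mismatch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove duplicate spacer placements
#'
#' Keeps one alignment per `(ref_id, start, strand, seq)` combination:
#' identical molecules landing at one locus are amplification artifacts,
#' while distinct sequences at one position are independent acquisitions
#' and are all retained. Unmapped records pass through untouched.
#'
#' @param alignments A data frame from [map_spacers()].
#' @return The deduplicated data frame; the number of removed rows is
#'   attached as attribute `n_removed`.
#' @export
remove_duplicates <- function(alignments) {
  mapped <- !is.na(alignments$ref_id)
  key <- paste(alignments$ref_id, alignments$start, alignments$strand,
               alignments$seq, sep = "\r")
  dup <- mapped & duplicated(key)
  out <- alignments[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(dup)
  out
}
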