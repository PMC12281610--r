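#' Quality trimming parameters
#'
#' Single-end trimming rules equivalent to the flag string
#' `LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15 MINLEN:75`, applied in that
#' order. The sliding-window step scans full windows 5' to 3' and cuts the
#' read just before the first window whose mean quality falls (strictly)
#' below `window_q`; remaining 3' bases individually below `window_q` are
#' then clipped, matching the reference tool's documented behaviour.
#'
#' @param leading_q Minimum quality for 5' bases.
#' @param trailing_q Minimum quality for 3' bases.
#' @param window_size Sliding window width in bases.
#' @param window_q Required mean window quality.
#' @param min_len Minimum read length after trimming; shorter reads are
#'   dropped.
#' @return A validated list of class `trim_params`.
#' @export
trim_params <- function(leading_q = 3, trailing_q = 3, window_size = 4,
                        window_q = 15, min_len = 75) {
  stopifnot(leading_q >= 0, trailing_q >= 0, window_size >= 1,
            window_q >= 0, min_len >= 0)
  structure(list(leading_q = as.integer(leading_q),
                 trailing_q = as.integer(trailing_q),
                 window_size = as.integer(window_size),
                 window_q = window_q, min_len = as.integer(min_len)),
            class = "trim_params")
}

#' Quality-trim reads
#'
#' Applies the [trim_params()] rule set to every read; reads falling below
#' `min_len` are dropped. Trimming never reorders or renames reads and is
#' idempotent. Input without qualities bypasses trimming with a warning
#' (this permits re-running from FASTA archives).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (or a plain
#'   [Biostrings::DNAStringSet], returned unchanged with a warning).
#' @param params A [trim_params()].
#' @return The trimmed read set; the number of dropped reads is attached as
#'   attribute `n_dropped`.
#' @export
trim_reads <- function(reads, params = trim_params()) {
  stopifnot(inherits(params, "trim_params"))
  if (!is(reads, "QualityScaledDNAStringSet")) {
    warning("reads carry no qualities; trimming skipped")
    return(reads)
  }
  quals <- as.character(Biostrings::quality(reads))
  b <- trim_bounds_cpp(quals, params$leading_q, params$trailing_q,
                       params$window_size, params$window_q, params$min_len)
  keep <- b[, 1L] > 0L
  seqs <- substring(as.character(reads)[keep], b[keep, 1L], b[keep, 2L])
  qout <- substring(quals[keep], b[keep, 1L], b[keep, 2L])
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, names(reads)[keep])),
    Biostrings::PhredQuality(qout))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Drop qualities from reads
#'
#' FASTQ to FASTA conversion: ids, order and sequences are preserved
#' verbatim (including any N bases).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] or
#'   [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet].
#' @export
fastq_to_fasta <- function(reads) {
  out <- methods::as(reads, "DNAStringSet")
  names(out) <- names(reads)
  out
}
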