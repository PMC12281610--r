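#' Direct repeat specification
#'
#' The flanking grammar of a recording array: spacers are delimited by DR1
#' upstream and DR2 downstream, each matched under its own Hamming budget
#' (the budgets are inclusive: a flank with exactly `max_mm` mismatches is
#' accepted).
#'
#' @param dr1,dr2 Direct repeat sequences (A/C/G/T).
#' @param max_mm_dr1,max_mm_dr2 Mismatch budgets for the two repeats.
#' @return A validated list of class `dr_spec`.
#' @export
dr_spec <- function(dr1 = "GAATTGAAAC", dr2 = "GTCGTACTTT",
                    max_mm_dr1 = 2L, max_mm_dr2 = 3L) {
  dr1 <- toupper(dr1); dr2 <- toupper(dr2)
  stopifnot(nchar(dr1) > 0, nchar(dr2) > 0,
            grepl("^[ACGT]+$", dr1), grepl("^[ACGT]+$", dr2),
            max_mm_dr1 >= 0, max_mm_dr2 >= 0)
  structure(list(dr1 = dr1, dr2 = dr2,
                 max_mm_dr1 = as.integer(max_mm_dr1),
                 max_mm_dr2 = as.integer(max_mm_dr2)),
            class = "dr_spec")
}

#' Spacer extraction parameters
#'
#' `restricted` mode only accepts spacers whose length lies in
#' `[spacer_len_min, spacer_len_max]`; `unrestricted` mode accepts any
#' length of at least 1 while keeping the same flank mismatch budgets.
#' `dedup_hamming` is the uniqueness radius of [dedup_sample()]: retained
#' spacers differ pairwise by more than this many mismatches (or in
#' length).
#'
#' @param mode `"restricted"` or `"unrestricted"`.
#' @param spacer_len_min,spacer_len_max Spacer length bounds (bp).
#' @param dedup_hamming Uniqueness collapse radius.
#' @return A validated list of class `extraction_params`.
#' @export
extraction_params <- function(mode = c("restricted", "unrestricted"),
                              spacer_len_min = 20L, spacer_len_max = 66L,
                              dedup_hamming = 1L) {
  mode <- match.arg(mode)
  stopifnot(spacer_len_min >= 1, spacer_len_min <= spacer_len_max,
            dedup_hamming >= 0)
  structure(list(mode = mode, spacer_len_min = as.integer(spacer_len_min),
                 spacer_len_max = as.integer(spacer_len_max),
                 dedup_hamming = as.integer(dedup_hamming)),
            class = "extraction_params")
}

#' Hamming distance with the package N-policy
#'
#' Counts differing positions between two equal-length sequences. Any base
#' outside A/C/G/T (N in particular) differs from everything, including
#' itself.
#'
#' @param a,b Sequences of equal length.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  d <- hamming_cpp(a, b)
  if (d < 0) stop("hamming() requires equal-length sequences (",
                  nchar(a), " vs ", nchar(b), ")")
  d
}

#' Find direct-repeat-flanked cassettes in reads
#'
#' Scans each read left to right on the given strand. A DR1 site is any
#' offset matching `dr1` within its budget; for each DR1 site the DR2
#' candidates are downstream offsets matching `dr2` within budget (with
#' the spacer length constrained in restricted mode), and the winner
#' minimises total flank mismatches, ties resolved towards the shorter
#' spacer. After a cassette is emitted the scan resumes past its DR2, so
#' cassettes never overlap; a DR1 site without any DR2 is skipped.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of
#'   uppercase reads; names become read ids.
#' @param dr A [dr_spec()].
#' @param params An [extraction_params()].
#' @return A data frame with one row per cassette: `read_id`, `spacer_seq`,
#'   `dr1_start`, `dr2_start` (1-based read offsets), `mm_dr1`, `mm_dr2`,
#'   `cassette_index` (ordinal within the read).
#' @export
find_cassettes <- function(reads, dr = dr_spec(),
                           params = extraction_params()) {
  stopifnot(inherits(dr, "dr_spec"), inherits(params, "extraction_params"))
  if (is(reads, "XStringSet")) {
    ids <- names(reads)
    reads <- as.character(reads)
  } else {
    ids <- names(reads)
    reads <- toupper(reads)
  }
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  hits <- scan_cassettes_cpp(reads, dr$dr1, dr$dr2, dr$max_mm_dr1,
                             dr$max_mm_dr2,
                             params$mode == "restricted",
                             params$spacer_len_min, params$spacer_len_max)
  l1 <- nchar(dr$dr1)
  data.frame(
    read_id = ids[hits$read],
    spacer_seq = substr(reads[hits$read], hits$dr1_start + l1,
                        hits$dr2_start - 1L),
    dr1_start = hits$dr1_start, dr2_start = hits$dr2_start,
    mm_dr1 = hits$mm_dr1, mm_dr2 = hits$mm_dr2,
    cassette_index = hits$cassette_index,
    stringsAsFactors = FALSE)
}

#' Collapse near-identical spacers within a sample
#'
#' Implements the per-sample uniqueness rule: distinct spacer sequences are
#' processed in descending multiplicity (ties lexicographic); a sequence
#' joins the first retained cluster whose representative has equal length
#' and Hamming distance at most `dedup_hamming`, otherwise it founds a new
#' cluster. Retained representatives therefore differ pairwise by more
#' than `dedup_hamming` mismatches or in length.
#'
#' @param spacers Character vector of spacer sequences (with repeats), or
#'   the data frame returned by [find_cassettes()].
#' @param params An [extraction_params()]; only `dedup_hamming` is used.
#' @return A list with `spacers` (data frame of `spacer`, `multiplicity`,
#'   `n_members`) in retention order and `clusters` (data frame mapping
#'   every distinct input sequence to its representative).
#' @export
dedup_sample <- function(spacers, params = extraction_params()) {
  if (is.data.frame(spacers)) spacers <- spacers$spacer_seq
  if (!length(spacers)) {
    return(list(
      spacers = data.frame(spacer = character(), multiplicity = integer(),
                           n_members = integer(),
                           stringsAsFactors = FALSE),
      clusters = data.frame(member = character(),
                            representative = character(),
                            stringsAsFactors = FALSE)))
  }
  tab <- table(spacers)
  seqs <- names(tab)
  mult <- as.integer(tab)
  o <- order(-mult, seqs, method = "radix")
  seqs <- seqs[o]
  mult <- mult[o]
  rep_idx <- dedup_greedy_cpp(seqs, params$dedup_hamming)
  cl_mult <- tapply(mult, rep_idx, sum)
  cl_size <- tapply(rep(1L, length(mult)), rep_idx, sum)
  keep <- sort(unique(rep_idx))
  list(
    spacers = data.frame(spacer = seqs[keep],
                         multiplicity = as.integer(cl_mult[as.character(keep)]),
                         n_members = as.integer(cl_size[as.character(keep)]),
                         stringsAsFactors = FALSE),
    clusters = data.frame(member = seqs,
                          representative = seqs[rep_idx],
                          stringsAsFactors = FALSE))
}

#' Length and GC summaries of a spacer set
#'
#' @param spacers Character vector of spacer sequences (or the data frame
#'   from [find_cassettes()]).
#' @param length_breaks,gc_breaks Histogram breaks; defaults are unit bins
#'   over the observed length range and 5% GC bins.
#' @return A list with `length_hist` and `gc_hist` (objects from
#'   [graphics::hist()], not plotted), plus mean and median of both
#'   quantities.
#' @export
spacer_summaries <- function(spacers, length_breaks = NULL,
                             gc_breaks = seq(0, 1, 0.05)) {
  if (is.data.frame(spacers)) spacers <- spacers$spacer_seq
  len <- nchar(spacers)
  gc <- nchar(gsub("[^GC]", "", spacers)) / len
  if (is.null(length_breaks)) {
    length_breaks <- seq(min(len) - 0.5, max(len) + 0.5, by = 1)
  }
  list(length_hist = graphics::hist(len, breaks = length_breaks,
                                    plot = FALSE),
       gc_hist = graphics::hist(gc, breaks = gc_breaks, plot = FALSE),
       length_mean = mean(len), length_median = median(len),
       gc_mean = mean(gc), gc_median = median(gc))
}
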