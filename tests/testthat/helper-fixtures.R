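# Small in-code fixture builders shared across test files.

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, "")
}

# a read with one planted cassette between pads that cannot resemble the
# repeats (poly-C), so flank matching is fully controlled by the caller
planted_read <- function(spacer, dr1 = "GAATTGAAAC", dr2 = "GTCGTACTTT",
                         left = 10L, right = 10L) {
  paste0(strrep("C", left), dr1, spacer, dr2, strrep("C", right))
}

# substitute specific positions of a sequence with a different base
mutate_at <- function(seq, pos) {
  for (p in pos) {
    old <- substr(seq, p, p)
    new <- setdiff(c("A", "C", "G", "T"), old)[1L]
    substr(seq, p, p) <- new
  }
  seq
}

# random reads with qualities for trimming batteries
random_fastq <- function(n, len_range = c(75L, 150L),
                         q_range = c(0L, 40L)) {
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, "")
  quals <- vapply(lens, function(l) {
    intToUtf8(sample(q_range[1L]:q_range[2L], l, replace = TRUE) + 33L)
  }, "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, sprintf("r%05d", seq_len(n)))),
    Biostrings::PhredQuality(quals))
}

# uniform-quality read set
const_fastq <- function(seqs, q) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(vapply(nchar(seqs), function(l) {
      strrep(intToUtf8(q + 33L), l)
    }, "")))
}

# a tiny simulation configuration that keeps module tests fast
small_sim_config <- function(seed = 11L, reads = 1500L, error = 0, ...) {
  sim_config(seed = seed, reads_per_sample = reads, genome_len = 30000L,
             n_genome_genes = 20L, error_rate = error,
             fold_changes = c(FbFP = 4), ...)
}

toy_path <- function(f) system.file("extdata", f, package = "recordseq")
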