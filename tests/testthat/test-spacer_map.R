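make_refs <- function(seed = 47, glen = 6000, plen = 2000) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(genome = random_dna(1, glen),
                             plasmid = random_dna(1, plen)))
}

test_that("planted substrings map back with the documented conventions", {
  refs <- make_refs()
  plas <- as.character(refs[["plasmid"]])
  gen <- as.character(refs[["genome"]])

  exact <- map_spacer(substr(plas, 100, 129), refs)
  expect_equal(exact[c("ref_id", "start", "strand", "n_mismatch",
                       "mapq_proxy")],
               data.frame(ref_id = "plasmid", start = 100L, strand = "+",
                          n_mismatch = 0L, mapq_proxy = "unique",
                          stringsAsFactors = FALSE))

  rc <- oracle_revcomp(substr(gen, 501, 540))
  minus <- map_spacer(rc, refs)
  expect_equal(minus$strand, "-")
  expect_equal(minus$start, 501L)
  expect_equal(minus$ref_id, "genome")

  # strand consistency: reverse complementing flips strand, keeps coords
  plus_again <- map_spacer(oracle_revcomp(rc), refs)
  expect_equal(plus_again$strand, "+")
  expect_equal(plus_again$start, 501L)

  # a sequence present twice verbatim is flagged multi
  dupref <- Biostrings::DNAStringSet(c(
    chrA = paste0(substr(gen, 1, 200), substr(gen, 50, 90),
                  substr(gen, 300, 400))))
  m <- map_spacer(substr(gen, 50, 90), dupref)
  expect_equal(m$mapq_proxy, "multi")
  expect_equal(m$start, 50L)  # lexicographically smallest placement
  expect_gte(m$n_best, 2L)

  allN <- map_spacer(strrep("N", 30), refs)
  expect_equal(allN$mapq_proxy, "unmapped")
  expect_equal(allN$reason, "only_ambiguous_bases")
  expect_equal(map_spacer(random_dna(1, 40), refs)$mapq_proxy, "unmapped")
})

test_that("seeded search equals the full Hamming scan at budgets 0, 1, 2", {
  refs <- make_refs(seed = 57, glen = 8000, plen = 1500)
  gen <- as.character(refs[["genome"]])
  plas <- as.character(refs[["plasmid"]])
  set.seed(58)
  qs <- character(0)
  for (i in 1:25) {
    len <- sample(20:66, 1)
    pos <- sample(1:(8000 - len), 1)
    q <- substr(gen, pos, pos + len - 1)
    nmut <- sample(0:2, 1)
    if (nmut) q <- mutate_at(q, sample(len, nmut))
    if (runif(1) < 0.4) q <- oracle_revcomp(q)
    qs <- c(qs, q)
  }
  qs <- c(qs, substr(plas, 77, 100), random_dna(5, 30))
  for (budget in 0:2) {
    got <- map_spacers(qs, refs, max_mismatch = budget)
    for (i in seq_along(qs)) {
      want <- oracle_map(qs[i], refs, budget)
      expect_equal(got$ref_id[i], want$ref_id, info = paste(budget, i))
      expect_equal(got$start[i], want$start, info = paste(budget, i))
      expect_equal(got$strand[i], want$strand, info = paste(budget, i))
      expect_equal(got$n_mismatch[i], want$mm, info = paste(budget, i))
      expect_equal(got$n_best[i], want$n_best, info = paste(budget, i))
    }
  }
})

test_that("exact mapping equals a naive substring scan at budget 0", {
  refs <- make_refs(seed = 67, glen = 3000, plen = 800)
  gen <- as.character(refs[["genome"]])
  set.seed(68)
  qs <- vapply(1:20, function(i) {
    pos <- sample(1:(3000 - 24), 1)
    substr(gen, pos, pos + 23)
  }, "")
  got <- map_spacers(qs, refs, max_mismatch = 0L)
  for (i in seq_along(qs)) {
    naive <- as.integer(gregexpr(qs[i], gen, fixed = TRUE)[[1]])
    naive_rc <- as.integer(gregexpr(oracle_revcomp(qs[i]), gen,
                                    fixed = TRUE)[[1]])
    n_hits <- sum(naive > 0) + sum(naive_rc > 0)
    expect_equal(got$n_best[i], n_hits)
    expect_equal(got$start[i], min(naive[naive > 0], naive_rc[naive_rc > 0]))
    expect_equal(got$n_mismatch[i], 0L)
  }
})

test_that("duplicate placements collapse by position and sequence", {
  aln <- data.frame(
    spacer_id = c("a", "b", "c", "d"),
    seq = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
            "TTTTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"),
    ref_id = c("g", "g", "g", NA), start = c(10L, 10L, 10L, NA),
    strand = c("+", "+", "+", NA), n_mismatch = c(0L, 0L, 1L, NA),
    stringsAsFactors = FALSE)
  out <- remove_duplicates(aln)
  expect_equal(nrow(out), 3L)  # same (pos, seq) collapsed; unmapped kept
  expect_equal(attr(out, "n_removed"), 1L)
  expect_true("TTTTACGTACGTACGTACGTA" %in% out$seq)
  expect_true(any(is.na(out$ref_id)))
  empty <- remove_duplicates(aln[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("error-free simulated spacers map uniquely to their origin", {
  cfg <- small_sim_config(seed = 77L, reads = 1200L, error = 0)
  refs <- simulate_references(cfg)
  s <- simulate_reads(cfg, refs, "control", 1L)
  hits <- find_cassettes(fastq_to_fasta(s$reads))
  first <- hits[hits$cassette_index == 1L, ]
  tr <- s$truth[s$truth$cassette_index == 1L, ]
  aln <- map_spacers(setNames(first$spacer_seq, first$read_id),
                     c(refs$genome, refs$plasmid))
  m <- match(aln$spacer_id, tr$read_id)
  ok <- aln$mapq_proxy == "unique" &
    aln$ref_id == tr$origin_ref[m] &
    aln$start == tr$origin_start[m] &
    aln$strand == tr$origin_strand[m]
  expect_gte(mean(ok), 0.999)
})
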