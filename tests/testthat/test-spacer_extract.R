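test_that("hamming applies the N-policy and rejects unequal lengths", {
  expect_equal(hamming("GAATTGAAAC", "GAATTGAAAC"), 0L)
  expect_equal(hamming("GAATTGAAAC", "GAATTGAAAA"), 1L)
  expect_equal(hamming("ACGT", "ANGT"), 1L)
  expect_equal(hamming("ANGT", "ANGT"), 1L)  # N never matches, even N
  expect_error(hamming("ACG", "ACGT"), "equal-length")
})

test_that("flank mismatch budgets are inclusive and length bounds bite", {
  set.seed(7)
  spacer <- random_dna(1, 30)
  base <- planted_read(spacer)
  hit <- find_cassettes(base)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$spacer_seq, spacer)
  expect_equal(c(hit$mm_dr1, hit$mm_dr2), c(0L, 0L))

  # exactly 2 mismatches in DR1 and 3 in DR2 are still accepted
  worn <- base
  substr(worn, 11, 20) <- mutate_at(substr(worn, 11, 20), c(2, 5))
  substr(worn, 51, 60) <- mutate_at(substr(worn, 51, 60), c(1, 4, 8))
  hit2 <- find_cassettes(worn)
  expect_equal(nrow(hit2), 1L)
  expect_equal(c(hit2$mm_dr1, hit2$mm_dr2), c(2L, 3L))
  expect_equal(hit2$spacer_seq, spacer)

  # one mismatch beyond either budget rejects the cassette
  over1 <- base
  substr(over1, 11, 20) <- mutate_at(substr(over1, 11, 20), c(2, 5, 7))
  expect_equal(nrow(find_cassettes(over1)), 0L)
  over2 <- base
  substr(over2, 51, 60) <- mutate_at(substr(over2, 51, 60), c(1, 4, 8, 9))
  expect_equal(nrow(find_cassettes(over2)), 0L)

  # 19 nt spacers exist only in unrestricted mode
  short <- planted_read(random_dna(1, 19))
  expect_equal(nrow(find_cassettes(short)), 0L)
  expect_equal(nrow(find_cassettes(
    short, params = extraction_params("unrestricted"))), 1L)

  # two back-to-back cassettes are both found, in order
  double <- paste0(strrep("C", 5), "GAATTGAAAC", random_dna(1, 25),
                   "GTCGTACTTT", "GAATTGAAAC", random_dna(1, 22),
                   "GTCGTACTTT", strrep("C", 5))
  hits <- find_cassettes(double)
  expect_equal(hits$cassette_index, c(1L, 2L))
  expect_equal(nchar(hits$spacer_seq), c(25L, 22L))
})

test_that("the scanner agrees with brute-force enumeration on random reads", {
  set.seed(17)
  reads <- random_dna(200, 150)
  # plant a cassette in most reads so DR1 sites are guaranteed to occur
  plant <- seq_len(150)
  spacers <- random_dna(150, sample(20:66, 150, replace = TRUE))
  for (i in plant) {
    pos <- sample(1:(150 - 20 - nchar(spacers[i]) - 1), 1)
    substr(reads[i], pos, pos + 9) <- "GAATTGAAAC"
    dr2pos <- pos + 10 + nchar(spacers[i])
    if (dr2pos + 9 <= 150) {
      substr(reads[i], pos + 10, dr2pos - 1) <- spacers[i]
      substr(reads[i], dr2pos, dr2pos + 9) <- "GTCGTACTTT"
    }
  }
  for (mode in c("restricted", "unrestricted")) {
    params <- extraction_params(mode)
    got <- find_cassettes(reads, params = params)
    want <- do.call(rbind, lapply(seq_along(reads), function(i) {
      o <- oracle_find_cassettes(reads[i], params = params)
      if (is.null(o)) return(NULL)
      cbind(read_id = as.character(i), o)
    }))
    rownames(want) <- NULL
    expect_identical(
      got[c("read_id", "dr1_start", "dr2_start", "mm_dr1", "mm_dr2",
            "cassette_index", "spacer_seq")],
      want[c("read_id", "dr1_start", "dr2_start", "mm_dr1", "mm_dr2",
             "cassette_index", "spacer_seq")])
  }
})

test_that("widening the mismatch budgets never loses cassettes", {
  set.seed(27)
  reads <- random_dna(300, 150)
  n_prev <- -1L
  for (b in list(c(0, 0), c(1, 1), c(2, 3), c(3, 4))) {
    n <- nrow(find_cassettes(
      reads, dr_spec(max_mm_dr1 = b[1], max_mm_dr2 = b[2]),
      extraction_params("unrestricted")))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("uniqueness collapse follows the greedy multiplicity-first rule", {
  rep5 <- "ACGTACGTACGTACGTACGT"
  var1 <- mutate_at(rep5, 3)
  dd <- dedup_sample(c(rep(rep5, 5), rep(var1, 2)))
  expect_equal(nrow(dd$spacers), 1L)
  expect_equal(dd$spacers$spacer, rep5)
  expect_equal(dd$spacers$multiplicity, 7L)
  expect_equal(dd$clusters$representative[dd$clusters$member == var1], rep5)

  # two mismatches means unique: both survive
  var2 <- mutate_at(rep5, c(3, 7))
  dd2 <- dedup_sample(c(rep(rep5, 3), rep(var2, 2)))
  expect_equal(nrow(dd2$spacers), 2L)

  # different lengths are never merged
  dd3 <- dedup_sample(c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAA"))
  expect_equal(nrow(dd3$spacers), 2L)

  # equal multiplicity ties resolve lexicographically
  a <- "AAAAAAAAAAAAAAAAAAAA"
  b <- mutate_at(a, 1)  # "CAAA..." sorts after a
  dd4 <- dedup_sample(c(a, b))
  expect_equal(dd4$spacers$spacer, a)

  # retained representatives are pairwise unique at radius 1
  set.seed(37)
  pool <- random_dna(400, 21)
  noisy <- c(pool, vapply(sample(pool, 300, replace = TRUE), function(s) {
    mutate_at(s, sample(21, 1))
  }, ""))
  dd5 <- dedup_sample(noisy)
  reps <- dd5$spacers$spacer
  d <- outer(seq_along(reps), seq_along(reps), Vectorize(function(i, j) {
    if (i >= j) 99L else hamming(reps[i], reps[j])
  }))
  expect_true(all(d > 1L))
  expect_equal(sum(dd5$spacers$multiplicity), length(noisy))

  empty <- dedup_sample(character(0))
  expect_equal(nrow(empty$spacers), 0L)
})

test_that("spacer summaries report GC and length distributions", {
  s <- spacer_summaries(c("GGCC", "ATAT"))
  expect_equal(s$gc_mean, 0.5)
  expect_equal(range(s$gc_hist$breaks), c(0, 1))

  cfg <- small_sim_config(reads = 400L, error = 0)
  refs <- simulate_references(cfg)
  sam <- simulate_reads(cfg, refs, "control", 1L)
  hits <- find_cassettes(fastq_to_fasta(sam$reads))
  got <- table(nchar(hits$spacer_seq))
  want <- table(nchar(sam$truth$spacer_seq))
  expect_identical(got, want)
})
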