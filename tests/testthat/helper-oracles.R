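# Independent brute-force oracles. These re-derive expected answers from
# first principles (full enumeration, no seeding/early-exit shortcuts) and
# deliberately share no code with the package kernels.

# mismatch count of `pattern` at every 1-based offset of `seq`;
# any base outside ACGT differs from everything, including itself
oracle_mm_profile <- function(seq, pattern) {
  s <- utf8ToInt(seq)
  p <- utf8ToInt(pattern)
  k <- length(p)
  n <- length(s)
  if (n < k) return(integer(0))
  idx <- outer(0:(n - k), 1:k, "+")
  win <- matrix(s[idx], ncol = k)
  acgt <- utf8ToInt("ACGT")
  ok <- sweep(win, 2L, p, "==") & matrix(win %in% acgt, ncol = k)
  as.integer(k - rowSums(ok))
}

# exhaustive (i, j) enumeration of the cassette selection rule
oracle_find_cassettes <- function(seq, dr = dr_spec(),
                                  params = extraction_params()) {
  l1 <- nchar(dr$dr1)
  l2 <- nchar(dr$dr2)
  L <- nchar(seq)
  mm1 <- oracle_mm_profile(seq, dr$dr1)
  mm2 <- oracle_mm_profile(seq, dr$dr2)
  res <- list()
  i <- 1L
  ci <- 0L
  while (i <= L - l1 - l2) {
    if (mm1[i] <= dr$max_mm_dr1) {
      lo <- if (params$mode == "restricted") {
        i + l1 + params$spacer_len_min
      } else {
        i + l1 + 1L
      }
      hi <- if (params$mode == "restricted") {
        min(i + l1 + params$spacer_len_max, L - l2 + 1L)
      } else {
        L - l2 + 1L
      }
      js <- if (lo <= hi) seq.int(lo, hi) else integer(0)
      js <- js[mm2[js] <= dr$max_mm_dr2]
      if (length(js)) {
        tot <- mm1[i] + mm2[js]
        best <- js[order(tot, js)][1L]  # shorter spacer == smaller j
        ci <- ci + 1L
        res[[ci]] <- data.frame(
          dr1_start = i, dr2_start = best, mm_dr1 = mm1[i],
          mm_dr2 = mm2[best], cassette_index = ci,
          spacer_seq = substr(seq, i + l1, best - 1L),
          stringsAsFactors = FALSE)
        i <- best + l2
        next
      }
    }
    i <- i + 1L
  }
  if (ci) do.call(rbind, res) else NULL
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                ""))
}

# every placement of a spacer (both strands) by full Hamming scan, up to
# max_keep mismatches; reduce with oracle_reduce at any budget <= max_keep
oracle_map_hits <- function(spacer, references, max_keep = 2L) {
  refs <- as.character(references)
  names(refs) <- sub("\\s.*$", "", names(references))
  rows <- list()
  for (rn in names(refs)) {
    for (st in c("+", "-")) {
      q <- if (st == "+") spacer else oracle_revcomp(spacer)
      prof <- oracle_mm_profile(refs[[rn]], q)
      hit <- which(prof <= max_keep)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = rn, start = hit, strand = st, mm = prof[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# the reduction map_spacers applies: minimal mismatches, lexicographic
# (ref_id, start, strand) representative, count of tying placements
oracle_reduce <- function(hits, budget) {
  if (!is.null(hits)) hits <- hits[hits$mm <= budget, , drop = FALSE]
  if (is.null(hits) || !nrow(hits)) {
    return(list(ref_id = NA_character_, start = NA_integer_,
                strand = NA_character_, mm = NA_integer_, n_best = 0L))
  }
  h <- hits[order(hits$mm, hits$ref_id, hits$start, hits$strand,
                  method = "radix"), , drop = FALSE]
  list(ref_id = h$ref_id[1L], start = h$start[1L], strand = h$strand[1L],
       mm = h$mm[1L], n_best = sum(h$mm == h$mm[1L]))
}

oracle_map <- function(spacer, references, max_mm) {
  oracle_reduce(oracle_map_hits(spacer, references, max_mm), max_mm)
}

# classic BH step-up, spelled out
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    padj[o[i]] <- min(running, 1)
  }
  padj
}
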