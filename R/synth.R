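#' Configuration of a simulated recording experiment
#'
#' The defaults describe the experiment the analysis is built around: a
#' bacterial culture carrying a recording plasmid (RT-Cas1/Cas2 machinery
#' plus the FbFP sensor gene), grown either at 30 degrees C (control) or
#' under a 42 degrees C heat shock (treated), sequenced as 150 nt
#' single-end reads. Spacer origins are drawn from genome and plasmid
#' transcripts with probability proportional to expression times gene
#' length; the treated condition multiplies the expression of the genes in
#' `fold_changes`, which by default contains the plasmid sensor (FbFP x4)
#' and a six-gene genome heat-shock regulon (folds 8, 6, 6, 4, 4, 2,
#' emulating chaperone induction at 42 degrees C).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param genome_len,plasmid_len Reference lengths in bp.
#' @param n_genome_genes Number of genes tiled on the genome.
#' @param plasmid_genes Named integer vector of plasmid gene lengths; must
#'   include the sensor gene `FbFP`.
#' @param expr_logmean,expr_logsd Log-normal baseline expression parameters
#'   (natural log scale) for genome genes. Plasmid genes sit under defined
#'   promoters and get the deterministic log-normal mean instead of a draw.
#' @param fold_changes Named positive numeric vector of expression
#'   multipliers applied in the treated condition. `NULL` selects the
#'   default regulon described above (restricted to genes that exist).
#' @param n_samples_per_condition Replicates per condition.
#' @param reads_per_sample Reads simulated per sample.
#' @param read_len Read length in bp.
#' @param spacer_len_min,spacer_len_max Planted spacer length bounds (bp);
#'   lengths are uniform on this range.
#' @param cassette_prob_second Probability that a read carries a second
#'   cassette directly after the first.
#' @param error_rate Per-base substitution probability applied i.i.d. over
#'   the whole read.
#' @param dr1,dr2 Direct repeat sequences flanking each spacer.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_len = 100000L,
                       n_genome_genes = 80L,
                       plasmid_len = 8000L,
                       plasmid_genes = c(FbFP = 450L, cas1 = 1800L,
                                         cas2 = 300L),
                       expr_logmean = 1,
                       expr_logsd = 1,
                       fold_changes = NULL,
                       n_samples_per_condition = 3L,
                       reads_per_sample = 50000L,
                       read_len = 150L,
                       spacer_len_min = 20L,
                       spacer_len_max = 66L,
                       cassette_prob_second = 0.05,
                       error_rate = 0.005,
                       dr1 = "GAATTGAAAC",
                       dr2 = "GTCGTACTTT") {
  if (is.list(plasmid_genes)) plasmid_genes <- unlist(plasmid_genes)
  if (is.list(fold_changes)) fold_changes <- unlist(fold_changes)
  if (is.null(fold_changes)) {
    hs_idx <- c(5L, 17L, 23L, 41L, 58L, 66L)
    hs_fold <- c(8, 6, 6, 4, 4, 2)
    ok <- hs_idx <= n_genome_genes
    fold_changes <- c(setNames(hs_fold[ok], sprintf("g%03d", hs_idx[ok])),
                      FbFP = 4)
  }
  cfg <- list(seed = as.integer(seed), genome_len = as.integer(genome_len),
              n_genome_genes = as.integer(n_genome_genes),
              plasmid_len = as.integer(plasmid_len),
              plasmid_genes = plasmid_genes,
              expr_logmean = expr_logmean, expr_logsd = expr_logsd,
              fold_changes = fold_changes,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              reads_per_sample = as.integer(reads_per_sample),
              read_len = as.integer(read_len),
              spacer_len_min = as.integer(spacer_len_min),
              spacer_len_max = as.integer(spacer_len_max),
              cassette_prob_second = cassette_prob_second,
              error_rate = error_rate, dr1 = toupper(dr1), dr2 = toupper(dr2))
  with(cfg, {
    stopifnot(genome_len > 0, plasmid_len > 0, n_genome_genes > 0,
              read_len > 0, reads_per_sample > 0,
              n_samples_per_condition > 0,
              spacer_len_min >= 1, spacer_len_min <= spacer_len_max,
              cassette_prob_second >= 0, cassette_prob_second <= 1,
              error_rate >= 0, error_rate <= 1,
              all(fold_changes > 0), length(plasmid_genes) > 0,
              !is.null(names(plasmid_genes)),
              nchar(dr1) > 0, nchar(dr2) > 0)
  })
  if (!"FbFP" %in% names(cfg$plasmid_genes)) {
    stop("plasmid_genes must include the sensor gene 'FbFP'")
  }
  if (cfg$read_len <
      nchar(cfg$dr1) + cfg$spacer_len_max + nchar(cfg$dr2)) {
    stop("read_len too short to hold one maximal cassette")
  }
  if (any(cfg$plasmid_genes < cfg$spacer_len_max)) {
    stop("every plasmid gene must be at least spacer_len_max long")
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-sample RNG stream: ordinal 1..n for control, n+1..2n
# for treated samples
derive_seed <- function(seed, condition, sample_index, n_per_condition) {
  ordinal <- sample_index +
    (condition == "treated") * n_per_condition
  as.integer((as.numeric(seed) + 7919 * ordinal) %% 2147483647)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate reference sequences and annotation
#'
#' Generates a uniform-random genome and plasmid, tiles non-overlapping
#' genes with at least 50 bp intergenic gaps and alternating strands, and
#' draws per-gene baseline expression. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` and `plasmid`
#'   ([Biostrings::DNAStringSet] of one contig each), `annotation`
#'   ([GenomicRanges::GRanges] over both contigs), `expression` (named
#'   vector of baseline expression) and `config`.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("g%03d", seq_len(config$n_genome_genes))
    glen <- sample(max(300L, config$spacer_len_max):1200L,
                   config$n_genome_genes, replace = TRUE)
    slack <- config$genome_len - sum(glen) -
      50L * (config$n_genome_genes + 1L)
    if (slack < 0) {
      stop("genome_len too small to tile ", config$n_genome_genes,
           " genes with 50 bp gaps")
    }
    extra <- as.integer(stats::rmultinom(1, slack,
                                         rep(1, config$n_genome_genes + 1L)))
    gaps <- 50L + extra
    starts <- integer(config$n_genome_genes)
    pos <- 1L
    for (i in seq_len(config$n_genome_genes)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + glen[i]
    }
    ends <- starts + glen - 1L
    gstrand <- rep_len(c("+", "-"), config$n_genome_genes)

    pl_ids <- names(config$plasmid_genes)
    pl_len <- as.integer(config$plasmid_genes)
    pl_slack <- config$plasmid_len - sum(pl_len) -
      50L * (length(pl_len) + 1L)
    if (pl_slack < 0) stop("plasmid_len too small for plasmid_genes")
    pl_extra <- as.integer(stats::rmultinom(1, pl_slack,
                                            rep(1, length(pl_len) + 1L)))
    pl_gaps <- 50L + pl_extra
    pl_starts <- integer(length(pl_len))
    pos <- 1L
    for (i in seq_along(pl_len)) {
      pos <- pos + pl_gaps[i]
      pl_starts[i] <- pos
      pos <- pos + pl_len[i]
    }
    pl_ends <- pl_starts + pl_len - 1L
    pl_strand <- rep_len(c("+", "-"), length(pl_len))

    genome <- Biostrings::DNAStringSet(random_bases(config$genome_len))
    names(genome) <- "genome"
    plasmid <- Biostrings::DNAStringSet(random_bases(config$plasmid_len))
    names(plasmid) <- "plasmid"

    annotation <- GenomicRanges::GRanges(
      seqnames = c(rep("genome", config$n_genome_genes),
                   rep("plasmid", length(pl_len))),
      ranges = IRanges::IRanges(start = c(starts, pl_starts),
                                end = c(ends, pl_ends)),
      strand = c(gstrand, pl_strand),
      feature_id = c(gene_ids, pl_ids),
      type = "gene",
      seqlengths = c(genome = config$genome_len,
                     plasmid = config$plasmid_len))
    names(annotation) <- annotation$feature_id

    expression <- c(
      setNames(rlnorm(config$n_genome_genes, config$expr_logmean,
                      config$expr_logsd), gene_ids),
      setNames(rep(exp(config$expr_logmean + config$expr_logsd^2 / 2),
                   length(pl_len)), pl_ids))
    list(genome = genome, plasmid = plasmid, annotation = annotation,
         expression = expression, config = config)
  })
}

# draw one batch of cassette origins/spacers; returns a data.frame with one
# row per cassette plus the read index it belongs to
draw_cassettes <- function(n_cassettes, read_of, refs, weights, config,
                           contig_chars) {
  ann <- refs$annotation
  genes <- names(weights)
  origin <- sample(genes, n_cassettes, replace = TRUE, prob = weights)
  gi <- match(origin, ann$feature_id)
  gstart <- GenomicRanges::start(ann)[gi]
  gend <- GenomicRanges::end(ann)[gi]
  contig <- as.character(GenomicRanges::seqnames(ann))[gi]
  len <- sample(config$spacer_len_min:config$spacer_len_max, n_cassettes,
                replace = TRUE)
  start <- gstart + floor(runif(n_cassettes) * (gend - gstart - len + 2))
  strand <- ifelse(rbinom(n_cassettes, 1L, 0.5) == 1L, "-", "+")
  seqs <- substring(contig_chars[contig], start, start + len - 1L)
  rc <- strand == "-"
  if (any(rc)) {
    seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
  }
  data.frame(read = read_of, origin_gene = origin, origin_ref = contig,
             origin_start = start, origin_end = start + len - 1L,
             origin_strand = strand, spacer_seq = seqs,
             stringsAsFactors = FALSE)
}

#' Simulate recording reads for one sample
#'
#' Each read consists of a left pad, a DR1-spacer-DR2 cassette (optionally
#' followed by a second cassette), and a right pad, padded to `read_len`.
#' Pads are random sequence rejection-screened so that the assembled
#' pre-error read contains exactly the planted direct-repeat sites within
#' the default mismatch budgets; this mirrors the fixed amplicon backbone of
#' a real recording library, which does not resemble the repeats.
#' Substitution errors are then applied i.i.d. at `error_rate` over the
#' whole read; qualities are constant Q37. Minus-strand origins are
#' inserted as reverse complements. Deterministic given
#' `(config$seed, condition, sample_index)`.
#'
#' @param config A [sim_config()].
#' @param refs Output of [simulate_references()].
#' @param condition `"control"` or `"treated"`.
#' @param sample_index Replicate number within the condition.
#' @return A list with `reads` (a [Biostrings::QualityScaledDNAStringSet]),
#'   `truth` (data frame of planted cassettes: read id, cassette index,
#'   origin gene/interval/strand, pre-error spacer sequence, read offsets),
#'   `true_counts` (named per-gene planted cassette counts), `condition`
#'   and `sample_id`.
#' @export
simulate_reads <- function(config, refs, condition = c("control", "treated"),
                           sample_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  n <- config$reads_per_sample
  dr1 <- config$dr1
  dr2 <- config$dr2
  l1 <- nchar(dr1)
  l2 <- nchar(dr2)
  weights <- refs$expression *
    GenomicRanges::width(refs$annotation)[match(names(refs$expression),
                                                refs$annotation$feature_id)]
  if (condition == "treated") {
    fc <- config$fold_changes
    missing_fc <- setdiff(names(fc), names(weights))
    if (length(missing_fc)) {
      stop("fold_changes names absent from the annotation: ",
           paste(missing_fc, collapse = ", "))
    }
    weights[names(fc)] <- weights[names(fc)] * fc
  }
  contig_chars <- c(genome = as.character(refs$genome[[1L]]),
                    plasmid = as.character(refs$plasmid[[1L]]))
  sample_id <- sprintf("%s_%d", condition, sample_index)

  seed <- derive_seed(config$seed, condition, sample_index,
                      config$n_samples_per_condition)
  withr::with_seed(seed, {
    reads <- character(n)
    truth <- list()
    pending <- seq_len(n)
    tries <- 0L
    while (length(pending)) {
      tries <- tries + 1L
      if (tries > 50L) stop("read simulation failed to converge")
      m <- length(pending)
      cass1 <- draw_cassettes(m, pending, refs, weights, config,
                              contig_chars)
      has2 <- runif(m) < config$cassette_prob_second
      space <- config$read_len -
        (l1 + nchar(cass1$spacer_seq) + l2) - (l1 + l2)
      has2 <- has2 & space >= config$spacer_len_min
      cass2 <- NULL
      body <- paste0(dr1, cass1$spacer_seq, dr2)
      if (any(has2)) {
        cass2 <- draw_cassettes(sum(has2), pending[has2], refs, weights,
                                config, contig_chars)
        keep_len <- pmin(nchar(cass2$spacer_seq), space[has2])
        trim2 <- keep_len < nchar(cass2$spacer_seq)
        if (any(trim2)) {
          # shorten second spacers that would overflow the read
          cass2$spacer_seq[trim2] <- substr(cass2$spacer_seq[trim2], 1L,
                                            keep_len[trim2])
          plus2 <- cass2$origin_strand == "+"
          cass2$origin_end[trim2 & plus2] <-
            cass2$origin_start[trim2 & plus2] + keep_len[trim2 & plus2] - 1L
          cass2$origin_start[trim2 & !plus2] <-
            cass2$origin_end[trim2 & !plus2] - keep_len[trim2 & !plus2] + 1L
        }
        body[has2] <- paste0(body[has2], dr1, cass2$spacer_seq, dr2)
      }
      pad_total <- config$read_len - nchar(body)
      left <- floor(runif(m) * (pad_total + 1L))
      right <- pad_total - left
      pad_pool <- random_bases(sum(pad_total))
      offs <- cumsum(c(0L, (left + right)[-m]))
      lpad <- substring(pad_pool, offs + 1L, offs + left)
      rpad <- substring(pad_pool, offs + left + 1L, offs + left + right)
      cand <- paste0(lpad, body, rpad)

      # screen: the assembled read must contain exactly the planted sites
      hits <- scan_cassettes_cpp(cand, dr1, dr2, 2L, 3L, FALSE, 0L, 0L)
      n_found <- tabulate(hits$read, nbins = m)
      exp_n <- 1L + as.integer(has2)
      ok <- n_found == exp_n
      d1_exp1 <- left + 1L
      d2_exp1 <- left + l1 + nchar(cass1$spacer_seq) + 1L
      first <- hits[!duplicated(hits$read), , drop = FALSE]
      ok[first$read] <- ok[first$read] &
        first$dr1_start == d1_exp1[first$read] &
        first$dr2_start == d2_exp1[first$read]
      if (any(has2)) {
        second <- hits[hits$cassette_index == 2L, , drop = FALSE]
        d1_exp2 <- d2_exp1 + l2
        len2_of <- integer(m)
        len2_of[has2] <- nchar(cass2$spacer_seq)
        d2_exp2 <- d1_exp2 + l1 + len2_of
        sec_ok <- logical(m)
        sec_ok[second$read] <- second$dr1_start == d1_exp2[second$read] &
          second$dr2_start == d2_exp2[second$read]
        ok <- ok & (!has2 | sec_ok)
      }
      good <- which(ok)
      if (length(good)) {
        idx <- pending[good]
        reads[idx] <- cand[good]
        c1 <- cass1[good, , drop = FALSE]
        c1$cassette_index <- 1L
        c1$read_offset_dr1 <- left[good] + 1L
        truth[[length(truth) + 1L]] <- c1
        if (any(has2[good])) {
          g2 <- match(pending[good][has2[good]], cass2$read)
          c2 <- cass2[g2, , drop = FALSE]
          c2$cassette_index <- 2L
          c2$read_offset_dr1 <-
            (d2_exp1 + l2)[good][has2[good]]
          truth[[length(truth) + 1L]] <- c2
        }
      }
      pending <- pending[!ok]
    }

    # substitution errors over the whole read, uniform among alternatives
    if (config$error_rate > 0) {
      nb <- n * config$read_len
      hit <- which(runif(nb) < config$error_rate)
      if (length(hit)) {
        rd <- ((hit - 1L) %/% config$read_len) + 1L
        ps <- ((hit - 1L) %% config$read_len) + 1L
        shift <- sample(1:3, length(hit), replace = TRUE)
        bases <- c("A", "C", "G", "T")
        while (length(rd)) {
          fst <- !duplicated(rd)
          old <- substr(reads[rd[fst]], ps[fst], ps[fst])
          new <- bases[((match(old, bases) - 1L + shift[fst]) %% 4L) + 1L]
          new[is.na(match(old, bases))] <- "N"
          substr(reads[rd[fst]], ps[fst], ps[fst]) <- new
          rd <- rd[!fst]; ps <- ps[!fst]; shift <- shift[!fst]
        }
      }
    }

    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$read, truth$cassette_index), , drop = FALSE]
    read_ids <- sprintf("%s_r%06d", sample_id, seq_len(n))
    truth$read_id <- read_ids[truth$read]
    truth$read <- NULL
    rownames(truth) <- NULL
    true_counts <- table(factor(truth$origin_gene,
                                levels = refs$annotation$feature_id))
    stopifnot(sum(true_counts) == nrow(truth))

    seqs <- Biostrings::DNAStringSet(reads)
    names(seqs) <- read_ids
    qual <- Biostrings::PhredQuality(
      Biostrings::BStringSet(rep(strrep(rawToChar(as.raw(37L + 33L)),
                                        config$read_len), n)))
    out_reads <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    list(reads = out_reads, truth = truth,
         true_counts = setNames(as.integer(true_counts),
                                names(true_counts)),
         condition = condition, sample_id = sample_id)
  })
}

#' Simulate a complete recording experiment
#'
#' Runs [simulate_references()] once and [simulate_reads()] for every
#' sample of both conditions; optionally writes references (FASTA),
#' annotation (GFF3), per-sample FASTQ, the planted truth (TSV) and the
#' design table to `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return A list with `refs`, `samples` (list of [simulate_reads()]
#'   results) and `design` (data frame of sample_id, condition).
#' @export
simulate_experiment <- function(config = sim_config(), outdir = NULL) {
  refs <- simulate_references(config)
  design <- expand.grid(
    sample_index = seq_len(config$n_samples_per_condition),
    condition = c("control", "treated"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(design)), function(i) {
    simulate_reads(config, refs, design$condition[i],
                   design$sample_index[i])
  })
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  design <- data.frame(sample_id = names(samples),
                       condition = design$condition,
                       stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(c(refs$genome, refs$plasmid),
                file.path(outdir, "references.fasta"))
    write_gff3(refs$annotation, file.path(outdir, "annotation.gff3"))
    for (s in samples) {
      write_fastq(s$reads, file.path(outdir, paste0(s$sample_id, ".fastq")))
      write.table(s$truth, file.path(outdir, paste0(s$sample_id,
                                                    "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(design, file.path(outdir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(refs = refs, samples = samples, design = design)
}

#' Simulate a negative binomial count matrix
#'
#' Count-level generator used to study the operating characteristics of
#' [diff_acquisition()] directly: per-gene means are log-normal, the
#' dispersion follows the standard decreasing trend
#' `alpha(mu) = alpha0 + alpha1 / mu`, and the treated condition multiplies
#' the mean of `fold_changes` genes.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition.
#' @param mu_log_mean,mu_log_sd Log-normal parameters of per-gene means
#'   (natural log).
#' @param alpha0,alpha1 Dispersion trend coefficients.
#' @param fold_changes Named vector of mean multipliers for treated
#'   samples; names are `gene<i>` ids or integer indices.
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `condition` (factor) and `mu` (baseline means).
#' @export
simulate_count_matrix <- function(n_genes = 2000L, n_per_group = 3L,
                                  mu_log_mean = log(200), mu_log_sd = 1,
                                  alpha0 = 0.01, alpha1 = 2,
                                  fold_changes = NULL, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    mu <- rlnorm(n_genes, mu_log_mean, mu_log_sd)
    alpha <- alpha0 + alpha1 / mu
    fc <- rep(1, n_genes)
    if (!is.null(fold_changes)) {
      idx <- if (is.null(names(fold_changes))) {
        as.integer(seq_along(fold_changes))
      } else {
        match(names(fold_changes), gene_ids)
      }
      fc[idx] <- fold_changes
    }
    condition <- factor(rep(c("control", "treated"), each = n_per_group),
                        levels = c("control", "treated"))
    counts <- sapply(seq_along(condition), function(s) {
      m <- if (condition[s] == "treated") mu * fc else mu
      rnbinom(n_genes, mu = m, size = 1 / alpha)
    })
    dimnames(counts) <- list(gene_ids,
                             paste0(condition, "_",
                                    rep(seq_len(n_per_group), 2L)))
    storage.mode(counts) <- "integer"
    list(counts = counts, condition = condition, mu = mu)
  })
}
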