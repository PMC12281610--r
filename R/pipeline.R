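#' Assemble a full run configuration
#'
#' Collects every stage's parameter block with the documented defaults
#' (direct repeats and their 2/3 mismatch budgets, 20-66 nt spacer bounds,
#' trimming flags, minimum count 10), optionally overridden from a YAML
#' file and then by named arguments (arguments win over the file).
#'
#' @param yaml Optional path to a YAML file whose top-level keys mirror
#'   the configuration blocks.
#' @param ... Named overrides: `sim`, `trim`, `dr`, `extract`, `map`,
#'   `count`, `diff`, `seed`, `outdir`, `total_spacers`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(yaml = NULL, ...) {
  cfg <- list(
    seed = 1L,
    sim = sim_config(),
    trim = trim_params(),
    dr = dr_spec(),
    extract = extraction_params(),
    map = list(max_mismatch = 1L, unique_only = FALSE),
    count = list(min_total = 10L, plasmid_contig = "plasmid"),
    total_spacers = "dedup",
    outdir = NULL)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (k in intersect(names(y), names(cfg))) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(y[[k]])) {
        utils::modifyList(cfg[[k]], y[[k]])
      } else {
        y[[k]]
      }
    }
  }
  dots <- list(...)
  for (k in names(dots)) {
    if (!k %in% names(cfg)) stop("unknown configuration block: ", k)
    cfg[[k]] <- dots[[k]]
  }
  if (!is.null(cfg$seed) && !identical(cfg$seed, cfg$sim$seed) &&
      inherits(cfg$sim, "sim_config")) {
    cfg$sim$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full recording analysis pipeline
#'
#' Executes simulate (or ingest provided FASTQ files), preprocess,
#' extract, dedup, map, count, ordination and differential acquisition,
#' and writes result tables plus a machine-readable run manifest when an
#' output directory is set. All randomness derives from the configured
#' seed, so a repeated run is identical.
#'
#' @param config A [run_config()].
#' @param fastq Optional named list/vector of FASTQ paths (names are
#'   sample ids); requires `references`, `annotation` and `design`.
#' @param references,annotation Reference FASTA path (or DNAStringSet) and
#'   GFF3 path (or GRanges) when `fastq` is given.
#' @param design Data frame with `sample_id` and `condition` when `fastq`
#'   is given.
#' @return A result bundle: per-sample stage counts, count matrices,
#'   differential results, PCA, relative spacer counts, and the manifest.
#' @export
run_pipeline <- function(config = run_config(), fastq = NULL,
                         references = NULL, annotation = NULL,
                         design = NULL) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  checksums <- NULL

  if (is.null(fastq)) {
    sim <- stage("simulate", simulate_experiment(config$sim))
    refs_set <- c(sim$refs$genome, sim$refs$plasmid)
    annotation <- sim$refs$annotation
    design <- sim$design
    reads_by_sample <- lapply(sim$samples, `[[`, "reads")
  } else {
    if (is.null(references) || is.null(annotation) || is.null(design)) {
      stop("fastq input needs references, annotation and design")
    }
    for (f in unlist(fastq)) {
      if (!file.exists(f)) stop("missing input file: ", f)
    }
    refs_set <- if (is.character(references)) {
      stage("load_references", read_fasta(references))
    } else as_dna(references)
    if (is.character(annotation)) {
      annotation <- stage("load_annotation", read_gff3(annotation))
    }
    files <- c(unlist(fastq),
               if (is.character(references)) references)
    checksums <- tools::md5sum(files)
    reads_by_sample <- stage("load_fastq", lapply(fastq, read_fastq))
    names(reads_by_sample) <- design$sample_id
  }
  names(refs_set) <- record_ids(names(refs_set))
  samples <- design$sample_id
  condition <- setNames(design$condition, samples)

  per_sample <- lapply(samples, function(s) {
    reads <- reads_by_sample[[s]]
    trimmed <- stage("preprocess", trim_reads(reads, config$trim))
    fa <- fastq_to_fasta(trimmed)
    hits <- stage("extract", find_cassettes(fa, config$dr, config$extract))
    dd <- stage("dedup", dedup_sample(hits, config$extract))
    aln <- stage("map", map_spacers(
      setNames(dd$spacers$spacer, dd$spacers$spacer),
      refs_set, config$map$max_mismatch))
    if (isTRUE(config$map$unique_only)) {
      aln <- aln[aln$mapq_proxy != "multi", , drop = FALSE]
    }
    aln <- stage("map", remove_duplicates(aln))
    cnt <- stage("count", count_per_gene(aln, annotation))
    list(sample_id = s,
         n_reads = length(reads),
         n_retained = length(trimmed),
         n_cassettes = nrow(hits),
         n_unique_spacers = nrow(dd$spacers),
         n_raw_spacers = sum(dd$spacers$multiplicity),
         n_mapped = sum(!is.na(aln$ref_id)),
         n_dedup_alignments = sum(!is.na(aln$ref_id)),
         count_summary = cnt$summary,
         counts = cnt$counts,
         spacers = dd$spacers)
  })
  names(per_sample) <- samples

  counts <- sapply(per_sample, `[[`, "counts")
  rownames(counts) <- annotation$feature_id
  is_plasmid <- as.character(GenomicRanges::seqnames(annotation)) ==
    (config$count$plasmid_contig %||% "plasmid")
  genome_counts <- counts[!is_plasmid, , drop = FALSE]
  plasmid_counts <- counts[is_plasmid, , drop = FALSE]
  min_total <- config$count$min_total
  genome_f <- stage("count", filter_low_counts(genome_counts, min_total))
  plasmid_f <- stage("count", filter_low_counts(plasmid_counts, min_total))

  vstm <- stage("ordination", vst_counts(genome_f))
  pca <- stage("ordination", pca_samples(vstm))
  hc <- stage("ordination", hclust_samples(vstm))

  dres <- stage("diff", diff_acquisition(plasmid_f, condition[samples]))

  total_spacers <- vapply(per_sample, function(p) {
    if (identical(config$total_spacers, "raw")) p$n_raw_spacers else
      p$n_unique_spacers
  }, numeric(1))
  rel <- if ("FbFP" %in% rownames(plasmid_counts)) {
    stage("relative", relative_spacer_count(plasmid_counts, total_spacers))
  } else NULL

  stage_counts <- lapply(per_sample, function(p) {
    p[c("n_reads", "n_retained", "n_cassettes", "n_unique_spacers",
        "n_mapped", "n_dedup_alignments")]
  })
  manifest <- list(
    package = "recordseq",
    version = as.character(packageVersion("recordseq")),
    seed = config$seed,
    config = config_as_list(config),
    input_checksums = as.list(checksums),
    design = design,
    stage_counts = stage_counts,
    count_summaries = lapply(per_sample, `[[`, "count_summary"))

  if (!is.null(outdir)) {
    write_count_table(counts, file.path(outdir, "counts.tsv"))
    write.table(dres, file.path(outdir, "diff_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(pca$scores),
                           pca$scores[, seq_len(min(3L, ncol(pca$scores))),
                                      drop = FALSE],
                           check.names = FALSE),
                file.path(outdir, "pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(rel)) {
      write.table(data.frame(sample_id = names(rel),
                             relative_spacer_count = unname(rel)),
                  file.path(outdir, "relative_spacer_count.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  invisible(list(config = config, design = design,
                 counts = counts, genome_counts = genome_f,
                 plasmid_counts = plasmid_f, vst = vstm, pca = pca,
                 hclust = hc, diff = dres, relative_spacer_count = rel,
                 per_sample = per_sample, manifest = manifest))
}

# strip classes and turn named vectors into lists so the manifest
# serialises (and round trips) cleanly through JSON
config_as_list <- function(cfg) {
  if (is.list(cfg)) {
    lapply(unclass(cfg), config_as_list)
  } else if (is.atomic(cfg) && !is.null(names(cfg))) {
    as.list(cfg)
  } else {
    cfg
  }
}
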